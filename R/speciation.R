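#' Ionic strength of a solution
#'
#' \eqn{I = \frac{1}{2}\sum_i c_i z_i^2} over the supplied molarities, using
#' the registered ionic charges.
#'
#' @param conc Named numeric vector of molarities (mol/L), names being
#'   registered species ids. Neutral species contribute nothing.
#' @return Ionic strength in mol/L.
#' @export
#' @examples
#' ionic_strength(c(Na = 0.01, Cl = 0.01))   # 0.01
#' ionic_strength(c(Ca = 0.001, SO4 = 0.001))  # 0.004
ionic_strength <- function(conc) {
  if (!length(conc)) return(0)
  stopifnot(all(conc >= 0, na.rm = TRUE))
  z <- .species_row(names(conc))$charge
  0.5 * sum(conc * z^2, na.rm = TRUE)
}

# Debye-Huckel A parameter, interpolated through tabulated anchors so that
# A(25 degC) = 0.5085 exactly.
davies_A <- function(temperature = 25) {
  stats::approx(x = c(0, 25, 50), y = c(0.4918, 0.5085, 0.5319),
                xout = temperature, rule = 2)$y
}

#' Davies-equation activity coefficient
#'
#' \eqn{\log_{10}\gamma = -A z^2 (\sqrt{I}/(1+\sqrt{I}) - b I)} with the
#' linear-fit temperature dependence of A (0.5085 at 25 degC) and b = 0.3.
#' Valid to roughly I = 0.7 mol/L; beyond that a warning is issued and the
#' value still returned.
#'
#' @param z Integer charge of the ion.
#' @param I Ionic strength, mol/L (non-negative).
#' @param temperature Temperature in degC.
#' @param b Davies linear term, default 0.3.
#' @return Activity coefficient (dimensionless); 1 at infinite dilution.
#' @export
#' @examples
#' activity_coefficient(1, 0.01)  # ~0.902
activity_coefficient <- function(z, I, temperature = 25, b = 0.3) {
  stopifnot(all(I >= 0))
  if (any(I > 0.7)) {
    warning("ionic strength ", paste(signif(I[I > 0.7], 3), collapse = ", "),
            " mol/L exceeds the Davies validity limit (~0.7 mol/L)",
            call. = FALSE)
  }
  A <- davies_A(temperature)
  10^(-A * z^2 * (sqrt(I) / (1 + sqrt(I)) - b * I))
}

#' Dissolved H2 activity
#'
#' The pipeline needs a hydrogen activity for the CO2-reduction and
#' SO4-reduction quotients; dissolved H2 is rarely measured in field
#' campaigns, so three modes are offered. `"assumed_constant"` returns a
#' configured nanomolar value (default 1e-9 mol/L, typical of
#' sulfate-reducing zones); `"measured"` passes a supplied molarity through;
#' `"redox_couple"` solves for the a(H2) that places the sulfate-reduction
#' reaction exactly at a configured Gibbs free energy threshold (default 0,
#' i.e. equilibrium) given the sample's SO4, HS and H+ activities.
#'
#' @param mode One of `"assumed_constant"`, `"measured"`, `"redox_couple"`.
#' @param value_molL Dissolved H2 molarity for the first two modes.
#' @param activities Named activity vector with `SO4`, `HS`, `H` (needed by
#'   `"redox_couple"`).
#' @param temperature degC (needed by `"redox_couple"`).
#' @param dg_threshold kJ/mol; the in-situ ΔG of sulfate reduction at which
#'   a(H2) is pinned in `"redox_couple"` mode.
#' @return Dimensionless H2 activity (equal to molarity: neutral species).
#' @export
h2_activity <- function(mode = c("assumed_constant", "measured", "redox_couple"),
                        value_molL = 1e-9, activities = NULL,
                        temperature = 25, dg_threshold = 0) {
  mode <- match.arg(mode)
  if (mode == "assumed_constant") return(value_molL)
  if (mode == "measured") {
    if (is.null(value_molL) || is.na(value_molL)) {
      stop("h2 mode 'measured' requires a dissolved H2 molarity", call. = FALSE)
    }
    return(value_molL)
  }
  need <- c("SO4", "HS", "H")
  if (is.null(activities) || !all(need %in% names(activities)) ||
      anyNA(activities[need])) {
    stop("h2 mode 'redox_couple' requires SO4, HS and H activities",
         call. = FALSE)
  }
  rxn <- shipped_reactions()$SO4_REDUCTION
  T_K <- temperature + 273.15
  ln_q <- (dg_threshold - delta_g0_T(rxn, temperature)) / (.R_GAS * T_K)
  # ln Q = ln aHS - ln aSO4 - ln aH - 4 ln aH2  =>  solve for aH2
  exp((log(activities[["HS"]]) - log(activities[["SO4"]]) -
         log(activities[["H"]]) - ln_q) / 4)
}

#' H2 configuration for the pipeline
#' @inheritParams h2_activity
#' @export
h2_config <- function(mode = c("assumed_constant", "measured", "redox_couple"),
                      value_molL = 1e-9, dg_threshold = 0) {
  mode <- match.arg(mode)
  structure(list(mode = mode, value_molL = value_molL,
                 dg_threshold = dg_threshold), class = "h2_config")
}

#' Thermodynamic activities of the reaction species
#'
#' Per-sample activities on the molal standard state: a(H+) = 10^-pH; ionic
#' species get a Davies activity coefficient times molarity; neutral
#' dissolved gases (CH4, H2) take unit activity coefficient (activity =
#' molarity); a(H2O) is fixed at exactly 1. Ionic strength is computed from
#' all measured major/minor ions.
#'
#' @param samples An imputed `water_samples` tibble (no censored flags may
#'   remain among HCO3, SO4, HS; run [impute_below_dl()] first).
#' @param h2 An [h2_config()].
#' @return A tibble, one row per sample: `sample_id`, `ionic_strength`,
#'   `a_H`, `a_H2`, `a_H2O`, `a_CH4` (NA when CH4 is absent, in which case
#'   CH4-dependent reactions are skipped downstream), and `a_<ion>` for each
#'   measured ion.
#' @export
species_activities <- function(samples, h2 = h2_config()) {
  stopifnot(inherits(samples, "water_samples"))
  if (any(is.na(samples$pH))) {
    stop("missing pH for sample(s): ",
         paste(samples$sample_id[is.na(samples$pH)], collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(samples$HCO3))) {
    stop("missing HCO3 for sample(s): ",
         paste(samples$sample_id[is.na(samples$HCO3)], collapse = ", "),
         call. = FALSE)
  }
  for (sp in c("HCO3", "SO4", "HS")) {
    if (any(samples[[paste0(sp, "_cens")]], na.rm = TRUE)) {
      stop(sp, " still has censored values; run impute_below_dl() first",
           call. = FALSE)
    }
  }
  ions <- ion_species()
  n <- nrow(samples)
  molar <- sapply(ions, function(sp) {
    v <- mgL_to_molL(samples[[sp]], sp)
    ifelse(is.na(v), 0, v)   # absent ions contribute nothing to I
  })
  if (is.null(dim(molar))) molar <- matrix(molar, nrow = n, dimnames = list(NULL, ions))
  z <- .species_row(ions)$charge
  I <- 0.5 * as.vector(molar %*% (z^2))

  out <- tibble::tibble(sample_id = samples$sample_id, ionic_strength = I,
                        a_H = 10^(-samples$pH), a_H2O = 1)
  for (sp in ions) {
    gamma <- activity_coefficient(z[match(sp, ions)], I, samples$temperature)
    a <- gamma * mgL_to_molL(samples[[sp]], sp)
    out[[paste0("a_", sp)]] <- a
  }
  out$a_CH4 <- mgL_to_molL(samples$CH4, "CH4")   # neutral gas: gamma = 1
  out$a_H2 <- vapply(seq_len(n), function(i) {
    act <- c(SO4 = out$a_SO4[i], HS = out$a_HS[i], H = out$a_H[i])
    tryCatch(h2_activity(h2$mode, h2$value_molL, act,
                         samples$temperature[i], h2$dg_threshold),
             error = function(e) NA_real_)
  }, numeric(1))
  out
}

#' Gypsum saturation index
#'
#' \eqn{SI = \log_{10}(a_{Ca} a_{SO4} / K_{sp})} with
#' \eqn{K_{sp} = 10^{-4.58}} at 25 degC (temperature dependence of Ksp
#' neglected). Zero at equilibrium with gypsum.
#'
#' @param a_Ca,a_SO4 Activities of Ca2+ and SO4 2-.
#' @return Saturation index (log10 units); NA where either activity is
#'   missing.
#' @export
#' @examples
#' gypsum_si(1e-2, 1e-2)   # 0.58
gypsum_si <- function(a_Ca, a_SO4) {
  log10(a_Ca * a_SO4) + 4.58
}
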