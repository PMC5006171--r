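#' Isotope fractionation factor
#'
#' \eqn{\alpha = (1000 + \delta_X) / (1000 + \delta_{CH4})}, where
#' \eqn{\delta_X} is the source pool (d13C-DIC for carbon, d2H-H2O for
#' hydrogen) and \eqn{\delta_{CH4}} the methane. Values of ~1.07 (C) and
#' ~1.2 (H) are typical of CO2-reduction methanogenesis; ~1.04 (C) and ~1.4
#' (H) of acetoclastic methanogenesis or an oxidation pathway.
#'
#' @param delta_X Source delta, per mil (> -1000).
#' @param delta_CH4 Methane delta, per mil (> -1000).
#' @return Fractionation factor (dimensionless). Vectorised.
#' @export
#' @examples
#' fractionation_factor(16, -53.5)    # ~1.07
#' fractionation_factor(-38.6, -204)  # ~1.2
fractionation_factor <- function(delta_X, delta_CH4) {
  if (any(delta_CH4 <= -1000, na.rm = TRUE)) {
    stop("delta_CH4 = -1000 per mil makes the fractionation factor undefined",
         call. = FALSE)
  }
  alpha <- (1000 + delta_X) / (1000 + delta_CH4)
  out_of_range <- !is.na(alpha) & (alpha < 0.8 | alpha > 1.8)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " fractionation factor(s) outside the natural C/H sanity band ",
            "(0.8, 1.8)", call. = FALSE)
  }
  alpha
}

#' Rayleigh fractionation curve
#'
#' \eqn{R = R_i f^{(1-\alpha)}} for the carbon orientation and
#' \eqn{R = R_i f^{(\alpha-1)}} for the hydrogen orientation: as the
#' residual CH4 reservoir f shrinks, carbon and hydrogen isotope ratios
#' respond reciprocally. Exposed for curve generation only; no sample is
#' force-fit to a Rayleigh model.
#'
#' @param R_i Initial ratio (> 0).
#' @param f Residual reservoir fraction in (0, 1]; f = 0 is a plotting
#'   limit, not an evaluable point.
#' @param alpha Fractionation factor.
#' @param orientation `"carbon"` or `"hydrogen"`.
#' @return Ratio R. Vectorised over `f`.
#' @export
rayleigh <- function(R_i, f, alpha, orientation = c("carbon", "hydrogen")) {
  orientation <- match.arg(orientation)
  stopifnot(all(R_i > 0))
  if (any(f <= 0 | f > 1)) {
    stop("f must lie in (0, 1]; f = 0 is the minimum-CH4 plotting limit",
         call. = FALSE)
  }
  expo <- if (orientation == "carbon") 1 - alpha else alpha - 1
  R_i * f^expo
}

#' Pathway-classification thresholds
#'
#' Half-widths and cutoffs are configuration, not code: the defaults
#' reproduce the classic field interpretation (alpha_DIC-CH4 1.07 +/- 0.02
#' with alpha_H2O-CH4 1.2 +/- 0.05 for CO2 reduction; alpha_C <= 1.05 or
#' alpha_H >= 1.35 or d2H-CH4 <= -310 per mil for acetoclastic
#' methanogenesis or oxidation).
#'
#' @param alpha_C_center,alpha_C_tol Carbon band for CO2 reduction.
#' @param alpha_H_center,alpha_H_tol Hydrogen band for CO2 reduction.
#' @param alpha_C_aceto_max Carbon cutoff for the acetoclastic/oxidation rule.
#' @param alpha_C_aceto_min Lower sanity floor on the carbon factor for that
#'   rule: below it (default 1.02) carbon fractionation is too weak to
#'   indicate any methanogenic pathway, so the rule stays silent.
#' @param alpha_H_aceto_min Hydrogen cutoff for the acetoclastic/oxidation rule.
#' @param d2H_aceto_max d2H-CH4 cutoff (per mil) for the acetoclastic rule.
#' @return A `pathway_thresholds` list.
#' @export
pathway_thresholds <- function(alpha_C_center = 1.07, alpha_C_tol = 0.02,
                               alpha_H_center = 1.20, alpha_H_tol = 0.05,
                               alpha_C_aceto_max = 1.05,
                               alpha_C_aceto_min = 1.02,
                               alpha_H_aceto_min = 1.35,
                               d2H_aceto_max = -310) {
  structure(list(alpha_C_center = alpha_C_center, alpha_C_tol = alpha_C_tol,
                 alpha_H_center = alpha_H_center, alpha_H_tol = alpha_H_tol,
                 alpha_C_aceto_max = alpha_C_aceto_max,
                 alpha_C_aceto_min = alpha_C_aceto_min,
                 alpha_H_aceto_min = alpha_H_aceto_min,
                 d2H_aceto_max = d2H_aceto_max),
            class = "pathway_thresholds")
}

#' Classify the methanogenic pathway of one sample
#'
#' Deterministic, order-independent rule set. The CO2-reduction rule
#' requires both fractionation factors inside their bands; the
#' acetoclastic/oxidation rule fires on a depleted carbon factor, an
#' elevated hydrogen factor, or strongly depleted d2H-CH4. Conflicting
#' rules give `MIXED`; no rule gives `INDETERMINATE`. Sulfate (meq/L) is
#' recorded as context evidence but is never decisive on its own. Missing
#' inputs narrow the rule set rather than erroring.
#'
#' @param alpha_C alpha_DIC-CH4 (NA when unavailable).
#' @param alpha_H alpha_H2O-CH4 (NA when unavailable).
#' @param d2H_CH4 per mil (NA when unavailable).
#' @param SO4_meq Sulfate in meq/L, context only.
#' @param thresholds A [pathway_thresholds()].
#' @return List with `call` (one of `"CO2_REDUCTION"`,
#'   `"ACETOCLASTIC_OR_OXIDATION"`, `"MIXED"`, `"INDETERMINATE"`) and
#'   `evidence` (character vector of fired rules; empty only for
#'   `INDETERMINATE`).
#' @export
classify_pathway <- function(alpha_C = NA, alpha_H = NA, d2H_CH4 = NA,
                             SO4_meq = NA,
                             thresholds = pathway_thresholds()) {
  th <- thresholds
  eps <- 1e-9   # boundary-inclusive guard against floating-point ties
  ev <- character()
  co2 <- !is.na(alpha_C) && !is.na(alpha_H) &&
    abs(alpha_C - th$alpha_C_center) <= th$alpha_C_tol + eps &&
    abs(alpha_H - th$alpha_H_center) <= th$alpha_H_tol + eps
  if (co2) {
    ev <- c(ev, sprintf(
      "alpha_C %.3f within %.2f+/-%.2f and alpha_H %.3f within %.2f+/-%.2f",
      alpha_C, th$alpha_C_center, th$alpha_C_tol,
      alpha_H, th$alpha_H_center, th$alpha_H_tol))
  }
  aceto <- FALSE
  if (!is.na(alpha_C) && alpha_C <= th$alpha_C_aceto_max &&
      alpha_C >= th$alpha_C_aceto_min) {
    aceto <- TRUE
    ev <- c(ev, sprintf("alpha_C %.3f <= %.2f", alpha_C, th$alpha_C_aceto_max))
  }
  if (!is.na(alpha_H) && alpha_H >= th$alpha_H_aceto_min) {
    aceto <- TRUE
    ev <- c(ev, sprintf("alpha_H %.3f >= %.2f", alpha_H, th$alpha_H_aceto_min))
  }
  if (!is.na(d2H_CH4) && d2H_CH4 <= th$d2H_aceto_max) {
    aceto <- TRUE
    ev <- c(ev, sprintf("d2H-CH4 %.1f <= %.0f per mil", d2H_CH4,
                        th$d2H_aceto_max))
  }
  if (!is.na(SO4_meq)) {
    ev <- c(ev, sprintf("context: SO4 = %.3g meq/L", SO4_meq))
  }
  call <- if (co2 && aceto) "MIXED"
  else if (co2) "CO2_REDUCTION"
  else if (aceto) "ACETOCLASTIC_OR_OXIDATION"
  else "INDETERMINATE"
  list(call = call, evidence = ev)
}

#' Mixing-line intercept of 1/CH4 against d13C-CH4
#'
#' Ordinary least squares of d13C-CH4 on the reciprocal methane
#' concentration; the y-axis intercept is the inferred source end-member
#' d13C-CH4 of a two-component mixture.
#'
#' @param ch4 Methane concentrations (> 0), at least 3 distinct values.
#' @param d13C d13C-CH4, per mil, same length.
#' @return List with `slope`, `intercept` (per mil) and `r_squared`.
#' @export
mixing_line_intercept <- function(ch4, d13C) {
  stopifnot(length(ch4) == length(d13C))
  if (length(ch4) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(ch4 <= 0)) stop("CH4 concentrations must be > 0", call. = FALSE)
  x <- 1 / ch4
  if (stats::var(x) == 0) {
    stop("zero variance in 1/CH4: degenerate design", call. = FALSE)
  }
  fit <- stats::lm(d13C ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d13C - mean(d13C))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}
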