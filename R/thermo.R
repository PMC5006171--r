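# Universal gas constant, kJ/(mol K).
.R_GAS <- 8.314e-3

.thermo_env <- new.env(parent = emptyenv())

#' Standard-state aqueous thermodynamic constants
#'
#' Per-species standard formation Gibbs free energies and enthalpies
#' (kJ/mol, 25 degC, aqueous standard states; H2O as liquid), shipped as a
#' plain-text constants file (`extdata/thermo_species.csv`). Users may point
#' to their own file with the same schema.
#'
#' @param path Optional path to a constants CSV
#'   (`species,dGf_kJmol,dHf_kJmol,charge,formula`).
#' @return A data frame of species constants.
#' @export
thermo_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.thermo_env$constants)) {
      path <- system.file("extdata", "thermo_species.csv", package = "ch4path",
                          mustWork = TRUE)
      .thermo_env$constants <- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    return(.thermo_env$constants)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.parse_formula <- function(f) {
  m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1
  stats::setNames(n, el)
}

# Conventional oxidation states used for electron accounting.
.ox_states <- list(
  H2 = c(H = 0), H = c(H = 1), H2O = c(H = 1, O = -2),
  CH4 = c(C = -4, H = 1), HCO3 = c(C = 4, H = 1, O = -2),
  SO4 = c(S = 6, O = -2), HS = c(S = -2, H = 1))

# Electrons transferred: total increase in oxidation number summed over
# elements from the reactant to the product side (4 H2 => 8 e-; AOM's
# C(-IV) -> C(+IV) => 8 e-).
.n_electrons <- function(stoich) {
  elements <- unique(unlist(lapply(.ox_states[names(stoich)], names)))
  gain <- 0
  for (el in elements) {
    tot <- 0
    for (sp in names(stoich)) {
      ox <- .ox_states[[sp]]
      cnt <- .parse_formula(thermo_constants()$formula[
        match(sp, thermo_constants()$species)])
      if (el %in% names(ox)) tot <- tot + stoich[[sp]] * cnt[[el]] * ox[[el]]
    }
    if (tot > 1e-9) gain <- gain + tot
  }
  as.integer(round(gain))
}

#' Define a microbial reaction
#'
#' Builds a reaction specification from a signed stoichiometry (products
#' positive, reactants negative) over species present in the thermodynamic
#' constants table. Charge and element balance are checked at load; the
#' electron count is derived from oxidation-state bookkeeping; the reaction
#' enthalpy is the stoichiometric sum of formation enthalpies and the
#' reaction entropy is derived as (ΔH° − ΔG°(298.15 K)) / 298.15 K so the
#' temperature correction is exactly anchored to the 25 degC free energy.
#'
#' @param name Reaction name.
#' @param stoichiometry Named numeric vector of signed coefficients.
#' @param constants Species constants table from [thermo_constants()].
#' @return A `reaction_spec` list with fields `name`, `stoichiometry`,
#'   `n_electrons`, `delta_H0` (kJ/mol), `delta_S0` (kJ/(mol K)).
#' @export
reaction_spec <- function(name, stoichiometry, constants = thermo_constants()) {
  sp <- names(stoichiometry)
  i <- match(sp, constants$species)
  if (anyNA(i)) {
    stop("species missing from constants table: ",
         paste(sp[is.na(i)], collapse = ", "), call. = FALSE)
  }
  q <- sum(stoichiometry * constants$charge[i])
  if (abs(q) > 1e-9) {
    stop("reaction ", name, " is not charge balanced (net ", q, ")",
         call. = FALSE)
  }
  counts <- lapply(constants$formula[i], .parse_formula)
  elements <- unique(unlist(lapply(counts, names)))
  for (el in elements) {
    tot <- sum(vapply(seq_along(sp), function(k) {
      stoichiometry[[k]] * (counts[[k]][el] %||% 0)
    }, numeric(1)))
    if (abs(tot) > 1e-9) {
      stop("reaction ", name, " is not balanced in element ", el, call. = FALSE)
    }
  }
  dH <- sum(stoichiometry * constants$dHf_kJmol[i])
  dG298 <- sum(stoichiometry * constants$dGf_kJmol[i])
  structure(list(name = name, stoichiometry = stoichiometry,
                 n_electrons = .n_electrons(stoichiometry),
                 delta_H0 = dH, delta_S0 = (dH - dG298) / 298.15),
            class = "reaction_spec")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' The three shipped microbial reactions
#'
#' CO2 reduction (hydrogenotrophic methanogenesis)
#' \eqn{HCO_3^- + 4H_2 + H^+ \rightarrow CH_4 + 3H_2O}; sulfate reduction
#' \eqn{SO_4^{2-} + 4H_2 + H^+ \rightarrow HS^- + 4H_2O}; anaerobic
#' oxidation of methane (AOM)
#' \eqn{CH_4 + SO_4^{2-} \rightarrow HCO_3^- + HS^- + H_2O}. All transfer
#' 8 electrons.
#'
#' @return Named list of `reaction_spec` objects.
#' @export
shipped_reactions <- function() {
  if (is.null(.thermo_env$reactions)) {
    .thermo_env$reactions <- list(
      CO2_REDUCTION = reaction_spec("CO2_REDUCTION",
        c(HCO3 = -1, H2 = -4, H = -1, CH4 = 1, H2O = 3)),
      SO4_REDUCTION = reaction_spec("SO4_REDUCTION",
        c(SO4 = -1, H2 = -4, H = -1, HS = 1, H2O = 4)),
      AOM = reaction_spec("AOM",
        c(CH4 = -1, SO4 = -1, HCO3 = 1, HS = 1, H2O = 1)))
  }
  .thermo_env$reactions
}

#' Temperature-corrected standard Gibbs free energy
#'
#' \eqn{\Delta G^\circ_T = \Delta H^\circ - T_K \Delta S^\circ} with
#' \eqn{T_K = T + 273.15}.
#'
#' @param reaction A `reaction_spec`.
#' @param temperature degC, in (0, 60).
#' @return kJ/mol.
#' @export
#' @examples
#' delta_g0_T(shipped_reactions()$CO2_REDUCTION, 25)  # ~ -229
delta_g0_T <- function(reaction, temperature) {
  stopifnot(inherits(reaction, "reaction_spec"),
            all(temperature > 0 & temperature < 60))
  reaction$delta_H0 - (temperature + 273.15) * reaction$delta_S0
}

#' Reaction quotient from activities
#'
#' \eqn{Q = \prod_i a_i^{\nu_i}} over the reaction's species; H2O is exempt
#' (activity fixed at 1). Returned together with its natural log, which is
#' the numerically safe representation.
#'
#' @param reaction A `reaction_spec`.
#' @param activities Named numeric vector of activities covering every
#'   species with nonzero coefficient (H2O optional).
#' @return List with elements `Q` and `lnQ`.
#' @export
reaction_quotient <- function(reaction, activities) {
  stoich <- reaction$stoichiometry
  stoich <- stoich[names(stoich) != "H2O"]
  missing_sp <- setdiff(names(stoich), names(activities))
  a <- activities[names(stoich)]
  if (length(missing_sp) || anyNA(a)) {
    bad <- union(missing_sp, names(stoich)[is.na(a)])
    stop("missing activities for reaction ", reaction$name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(a <= 0)) stop("activities must be strictly positive", call. = FALSE)
  lnq <- sum(stoich * log(a))
  list(Q = exp(lnq), lnQ = lnq)
}

#' In-situ Gibbs free energy
#'
#' \eqn{\Delta G = \Delta G^\circ_T + R T_K \ln Q} with R = 8.314 J/(mol K),
#' returned in kJ/mol.
#'
#' @inheritParams delta_g0_T
#' @param Q Reaction quotient (> 0); alternatively supply `lnQ`.
#' @param lnQ Natural log of the reaction quotient.
#' @return kJ/mol.
#' @export
delta_g <- function(reaction, temperature, Q = NULL, lnQ = NULL) {
  if (is.null(lnQ)) {
    stopifnot(!is.null(Q), Q > 0)
    lnQ <- log(Q)
  }
  delta_g0_T(reaction, temperature) +
    .R_GAS * (temperature + 273.15) * lnQ
}

#' Gibbs free energy per electron transferred
#'
#' Normalizes a reaction free energy by its electron count (8 for the three
#' shipped reactions), enabling cross-reaction comparison.
#'
#' @param dg Free energy, kJ/mol.
#' @param reaction A `reaction_spec`.
#' @return kJ/(mol e-).
#' @export
delta_g_per_electron <- function(dg, reaction) {
  stopifnot(reaction$n_electrons > 0)
  dg / reaction$n_electrons
}
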