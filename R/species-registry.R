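#' @title Registered solute species
#' @description Molar masses (g/mol) and signed ionic charges for the solutes
#'   handled by the pipeline. The S2 entry is carried with an equivalent weight
#'   of 64.13 g/mol and unit charge, which reproduces the meq/L convention used
#'   for field sulfide data (0.1 mg/L = 1.56e-03 meq/L).
#' @keywords internal
.species_registry <- data.frame(
  species    = c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "Br", "SO4", "NO3",
                 "S2", "HS", "Fe", "Mn", "CH4", "H", "H2"),
  molar_mass = c(22.990, 39.098, 40.078, 24.305, 61.016, 35.453, 79.904,
                 96.06, 62.004, 64.13, 33.073, 55.845, 54.938, 16.043,
                 1.008, 2.016),
  charge     = c(1L, 1L, 2L, 2L, -1L, -1L, -1L, -2L, -1L,
                 -1L, -1L, 2L, 2L, 0L, 1L, 0L),
  stringsAsFactors = FALSE
)

#' Species registry
#'
#' Returns the table of registered solute species with their molar masses
#' (g/mol) and signed ionic charges. Dissolved CH4 is neutral and, by package
#' convention, carried in ug/L everywhere (all other species in mg/L).
#'
#' @return A data frame with columns `species`, `molar_mass`, `charge`.
#' @export
#' @examples
#' species_registry()
species_registry <- function() {
  tibble::as_tibble(.species_registry)
}

.species_row <- function(species) {
  i <- match(species, .species_registry$species)
  if (anyNA(i)) {
    stop("unknown species: ",
         paste(unique(species[is.na(i)]), collapse = ", "),
         " (see species_registry() for registered species)", call. = FALSE)
  }
  .species_registry[i, , drop = FALSE]
}

#' Convert mg/L to meq/L
#'
#' Concentration in mg/L divided by the species molar mass and multiplied by
#' the magnitude of its ionic charge. Exact and deterministic; linear in the
#' concentration.
#'
#' @param conc Concentration in mg/L (non-negative, vectorised).
#' @param species Registered species id (e.g. `"Cl"`, `"SO4"`); length 1 or
#'   the length of `conc`.
#' @return Concentration in meq/L.
#' @export
#' @examples
#' mgL_to_meqL(4500, "Cl")   # ~127
#' mgL_to_meqL(488, "SO4")   # ~10
mgL_to_meqL <- function(conc, species) {
  stopifnot(all(conc >= 0, na.rm = TRUE))
  row <- .species_row(species)
  if (any(row$charge == 0L)) {
    stop("species ", paste(unique(row$species[row$charge == 0L]), collapse = ", "),
         " carries no ionic charge; meq/L is undefined", call. = FALSE)
  }
  conc / row$molar_mass * abs(row$charge)
}

#' Convert mg/L (or ug/L for dissolved gases) to mol/L
#'
#' Ionic species are read in mg/L and divided by 1000 x molar mass. Dissolved
#' CH4 follows the package convention of ug/L and is divided by 1e6 x molar
#' mass.
#'
#' @inheritParams mgL_to_meqL
#' @return Molarity in mol/L.
#' @export
#' @examples
#' mgL_to_molL(35.453, "Cl")   # 1e-3
#' mgL_to_molL(16043, "CH4")   # 1e-3 (input in ug/L)
mgL_to_molL <- function(conc, species) {
  stopifnot(all(conc >= 0, na.rm = TRUE))
  row <- .species_row(species)
  scale <- ifelse(row$species == "CH4", 1e6, 1e3)
  conc / (scale * row$molar_mass)
}
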