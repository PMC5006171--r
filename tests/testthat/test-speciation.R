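test_that("ionic strength follows I = half the sum of c z^2", {
  expect_equal(ionic_strength(c(Na = 0.01, Cl = 0.01)), 0.01)
  expect_equal(ionic_strength(c(Ca = 0.001, SO4 = 0.001)), 0.004)
  expect_equal(ionic_strength(numeric(0)), 0)
  expect_error(ionic_strength(c(Zz = 0.1)), "unknown species")
})

test_that("Davies coefficients match hand evaluation and z^2 scaling", {
  expect_equal(activity_coefficient(1, 0), 1)
  expect_equal(activity_coefficient(3, 0), 1)
  # log10 gamma = -0.5085 * (sqrt(.01)/1.1 - 0.003) at 25 degC
  g1 <- 10^(-0.5085 * (0.1 / 1.1 - 0.003))
  expect_equal(activity_coefficient(1, 0.01), g1, tolerance = 1e-12)
  expect_equal(round(activity_coefficient(1, 0.01), 3), 0.902)
  expect_equal(activity_coefficient(2, 0.01), g1^4, tolerance = 1e-12)
  expect_warning(activity_coefficient(1, 0.9), "Davies validity")
})

test_that("gamma decreases monotonically in I on [0, 0.3]", {
  I_grid <- seq(0, 0.3, length.out = 50)
  for (z in 1:2) {
    g <- activity_coefficient(z, I_grid)
    expect_true(all(diff(g) < 0))
    expect_true(all(g > 0 & g <= 1))
  }
})

test_that("species activities follow the molal conventions", {
  df <- tibble::tibble(
    sample_id = "A", aquifer_group = "ALLUVIUM", temperature = 25, pH = 7,
    HCO3 = 61.016, CH4 = 16043, Na = 1e-4, Cl = 1e-4)
  act <- species_activities(water_samples(df))
  expect_equal(act$a_H, 1e-7)
  expect_equal(act$a_H2O, 1)
  expect_equal(act$a_CH4, 1e-3)          # neutral gas: gamma = 1
  # near-infinite dilution: activity -> molarity
  expect_equal(act$a_HCO3, 1e-3, tolerance = 1e-3)
  expect_true(act$a_HCO3 < 1e-3)          # gamma strictly < 1 at I > 0
  expect_equal(act$a_H2, 1e-9)            # default assumed-constant mode
})

test_that("activities converge to molarities as the solution dilutes", {
  make <- function(scale) water_samples(tibble::tibble(
    sample_id = "A", aquifer_group = "ALLUVIUM", temperature = 25, pH = 7,
    Na = 2300 * scale, Cl = 3545 * scale, HCO3 = 610 * scale,
    SO4 = 96 * scale, SO4_cens = FALSE))
  for (sp in c("Na", "Cl", "HCO3", "SO4")) {
    ratios <- vapply(c(1, 1e-4, 1e-8), function(k) {
      s <- make(k)
      species_activities(s)[[paste0("a_", sp)]] / mgL_to_molL(s[[sp]], sp)
    }, numeric(1))
    expect_true(all(diff(ratios) > 0))         # gamma rises toward 1
    expect_equal(ratios[3], 1, tolerance = 1e-3)
  }
})

test_that("speciation demands pH, HCO3 and prior imputation", {
  base <- tibble::tibble(sample_id = "A", aquifer_group = "ALLUVIUM",
                         temperature = 25, pH = 7, HCO3 = 400)
  bad <- base; bad$pH <- NA
  expect_error(species_activities(water_samples(bad)), "missing pH")
  bad <- base; bad$HCO3 <- NA
  expect_error(species_activities(water_samples(bad)), "missing HCO3")
  bad <- base; bad$SO4 <- NA; bad$SO4_cens <- TRUE
  expect_error(species_activities(water_samples(bad)), "impute_below_dl")
})

test_that("H2 modes pass through or solve the sulfate-reduction couple", {
  expect_equal(h2_activity("assumed_constant", 1e-9), 1e-9)
  expect_equal(h2_activity("measured", 5e-9), 5e-9)
  expect_error(h2_activity("measured", NA), "requires")
  act <- c(SO4 = 1e-4, HS = 1e-7, H = 1e-8)
  a_h2 <- h2_activity("redox_couple", activities = act, temperature = 25,
                      dg_threshold = 0)
  # substituting back must put sulfate reduction exactly at equilibrium
  rxn <- shipped_reactions()$SO4_REDUCTION
  q <- reaction_quotient(rxn, c(act, H2 = a_h2))
  expect_equal(delta_g(rxn, 25, lnQ = q$lnQ), 0, tolerance = 1e-9)
  # and a nonzero threshold is honoured the same way
  a_h2b <- h2_activity("redox_couple", activities = act, temperature = 25,
                       dg_threshold = -10)
  qb <- reaction_quotient(rxn, c(act, H2 = a_h2b))
  expect_equal(delta_g(rxn, 25, lnQ = qb$lnQ), -10, tolerance = 1e-9)
})

test_that("gypsum saturation index is anchored to its Ksp", {
  expect_equal(gypsum_si(10^-2.29, 10^-2.29), 0)
  expect_equal(gypsum_si(1e-2, 1e-2), 0.58)
  expect_equal(gypsum_si(1e-4, 1e-4), -3.42)
  expect_true(is.na(gypsum_si(NA, 1e-3)))
})
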