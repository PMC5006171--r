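test_that("fractionation factors use (1000 + delta), not delta ratios", {
  expect_equal(fractionation_factor(-50, -50), 1)
  expect_equal(fractionation_factor(16, -53.5), 1016 / 946.5)
  expect_equal(round(fractionation_factor(16, -53.5), 2), 1.07)
  expect_equal(round(fractionation_factor(-38.6, -204), 1), 1.2)
  # a delta-ratio implementation would return 16 / -53.5, far from 1.07
  expect_false(isTRUE(all.equal(fractionation_factor(16, -53.5),
                                16 / -53.5)))
  # invariance under a common offset holds only at offset 0
  a0 <- fractionation_factor(16, -53.5)
  expect_false(isTRUE(all.equal(fractionation_factor(16 + 50, -53.5 + 50), a0)))
  expect_error(fractionation_factor(0, -1000), "undefined")
  expect_warning(fractionation_factor(900, -100), "sanity band")
})

test_that("Rayleigh curves follow their orientation conventions", {
  expect_equal(rayleigh(1, 1, 1.07, "carbon"), 1)
  expect_equal(rayleigh(2, 0.3, 1, "hydrogen"), 2)
  expect_equal(rayleigh(1, 0.5, 1.07, "carbon"), 0.5^(-0.07))
  expect_equal(round(rayleigh(1, 0.5, 1.07, "carbon"), 4), 1.0497)
  expect_equal(rayleigh(1, 0.5, 1.07, "hydrogen"), 0.5^(0.07))
  expect_error(rayleigh(1, 0, 1.07, "carbon"), "plotting limit")
  expect_error(rayleigh(-1, 0.5, 1.07, "carbon"))
})

test_that("carbon and hydrogen orientations are reciprocal", {
  set.seed(3)
  for (i in 1:25) {
    R_i <- exp(rnorm(1))
    f <- runif(1, 0.01, 1)
    alpha <- runif(1, 1.01, 1.5)
    rc <- rayleigh(R_i, f, alpha, "carbon")
    rh <- rayleigh(R_i, f, alpha, "hydrogen")
    expect_equal(rc * rh, R_i^2, tolerance = 1e-12)
  }
})

test_that("pathway classification reproduces the reference assignments", {
  # gas-reservoir style: both factors inside the CO2-reduction bands
  co2 <- classify_pathway(1.07, 1.20, d2H_CH4 = -204, SO4_meq = 0.01)
  expect_equal(co2$call, "CO2_REDUCTION")
  expect_true(length(co2$evidence) > 0)
  # brackish acetoclastic sample: depleted carbon factor, high hydrogen
  # factor, strongly depleted d2H-CH4
  ac <- classify_pathway(1.04, 1.42, d2H_CH4 = -315, SO4_meq = 3)
  expect_equal(ac$call, "ACETOCLASTIC_OR_OXIDATION")
  expect_gte(length(ac$evidence), 3)
  # no rule fires
  ind <- classify_pathway(1.00, 1.00)
  expect_equal(ind$call, "INDETERMINATE")
  # conflicting rules give MIXED (boundary value fires both)
  mx <- classify_pathway(1.05, 1.20)
  expect_equal(mx$call, "MIXED")
  # missing inputs narrow the rule set instead of erroring
  expect_equal(classify_pathway(NA, NA, d2H_CH4 = -320)$call,
               "ACETOCLASTIC_OR_OXIDATION")
  expect_equal(classify_pathway(NA, NA)$call, "INDETERMINATE")
  # SO4 is context evidence, never decisive
  expect_equal(classify_pathway(NA, NA, SO4_meq = 50)$call, "INDETERMINATE")
})

test_that("classification is deterministic and configurable", {
  for (i in 1:5) {
    expect_identical(classify_pathway(1.06, 1.22, -200, 1),
                     classify_pathway(1.06, 1.22, -200, 1))
  }
  th <- pathway_thresholds(alpha_C_aceto_max = 1.065)
  expect_equal(classify_pathway(1.06, 1.22, thresholds = th)$call, "MIXED")
})

test_that("mixing-line intercept recovers the source end member", {
  # perfect-line recovery
  ch4 <- c(20, 50, 100, 400, 1000)
  d13 <- 100 * (1 / ch4) - 55.9
  fit <- mixing_line_intercept(ch4, d13)
  expect_equal(fit$intercept, -55.9, tolerance = 1e-9)
  expect_equal(fit$slope, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # degenerate designs are rejected
  expect_error(mixing_line_intercept(c(10, 10, 10), c(-50, -51, -52)),
               "zero variance")
  expect_error(mixing_line_intercept(c(10, 20), c(-50, -51)), "3 points")
  expect_error(mixing_line_intercept(c(-1, 10, 20), c(-50, -51, -52)), "> 0")
})

test_that("two-end-member mass balance lands on the source intercept", {
  # Keeling construction: a fixed background reservoir (c_bg, d_bg) receives
  # varying additions from a source with delta d_src; the observed delta is
  # the concentration-weighted mass balance.  The y-intercept of delta
  # against 1/CH4 must recover the source end member exactly.
  c_bg <- 2; d_bg <- -47
  d_src <- -55.9
  added <- c(5, 20, 100, 600, 4000)
  conc <- c_bg + added
  delta <- (c_bg * d_bg + added * d_src) / conc
  fit <- mixing_line_intercept(conc, delta)
  expect_equal(fit$intercept, d_src, tolerance = 1e-6)
})
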