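test_that("default profiles encode the published per-aquifer bounds", {
  pr <- default_profiles()
  expect_equal(pr$GAS_RESERVOIR$ranges$CH4[2], 25000)
  expect_equal(pr$GAS_RESERVOIR$ranges$Cl, c(1000, 4500))
  expect_equal(pr$GAS_RESERVOIR$ranges$d13C_DIC, c(9, 23))
  expect_equal(pr$ALLUVIUM$ch4_detect, 5 / 23)
  expect_equal(pr$ALLUVIUM$ranges$CH4, c(10, 535))
  expect_equal(pr$SHALLOW_COAL_MEASURES$ranges$d13C_DIC, c(-15.9, -3.5))
  expect_equal(pr$SHALLOW_COAL_MEASURES$ch4_detect, 7 / 14)
  for (p in pr) {
    expect_s3_class(p, "aquifer_profile")
    expect_equal(sum(p$weights), 1)
    for (r in p$ranges) expect_lte(r[1], r[2])
  }
  expect_error(aquifer_profile(list(Cl = c(5, 1)), 0.5,
                               c(CO2_REDUCTION = 1)), "ordered")
  expect_error(aquifer_profile(list(Cl = c(1, 5)), 0.5,
                               c(CO2_REDUCTION = 0.6)), "sum to 1")
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_catchment(seed = 4L)
  b <- generate_catchment(seed = 4L)
  expect_identical(a$samples, b$samples)
  expect_identical(a$labels, b$labels)
  c2 <- generate_catchment(seed = 5L)
  expect_false(identical(a$samples, c2$samples))
})

test_that("generated values respect their profile bounds pre-noise", {
  sim <- generate_catchment(seed = 9L, delta_noise = 0)
  pr <- default_profiles()
  for (grp in unique(sim$samples$aquifer_group)) {
    sub <- sim$samples[sim$samples$aquifer_group == grp, ]
    rg <- pr[[grp]]$ranges
    in_range <- function(v, r) all(v >= r[1] & v <= r[2], na.rm = TRUE)
    expect_true(in_range(sub$temperature, rg$temperature), label = grp)
    expect_true(in_range(sub$pH, rg$pH), label = grp)
    expect_true(in_range(sub$screen_depth, rg$depth), label = grp)
    expect_true(in_range(sub$Cl, rg$Cl), label = grp)
    expect_true(in_range(sub$SO4, rg$SO4), label = grp)
    expect_true(in_range(sub$CH4, rg$CH4), label = grp)
    expect_true(in_range(sub$d13C_DIC, rg$d13C_DIC), label = grp)
    expect_true(in_range(sub$d2H_H2O, rg$d2H_H2O), label = grp)
    expect_true(in_range(sub$d18O_H2O, rg$d18O_H2O), label = grp)
  }
})

test_that("gas-reservoir sulfate is censored like production water", {
  sim <- generate_catchment(n_per_aquifer = c(GAS_RESERVOIR = 50), seed = 2L)
  expect_gte(mean(sim$samples$SO4_cens), 0.9)
})

test_that("methane varies inversely with sulfate in the shallow aquifers", {
  sim <- generate_catchment(n_per_aquifer = c(ALLUVIUM = 200,
                                              SHALLOW_COAL_MEASURES = 200),
                            seed = 11L)
  s <- sim$samples
  for (grp in c("ALLUVIUM", "SHALLOW_COAL_MEASURES")) {
    sub <- s[s$aquifer_group == grp, ]
    so4 <- ifelse(sub$SO4_cens, sub$SO4_dl / 2, sub$SO4)
    ch4 <- ifelse(sub$CH4_cens, sub$CH4_dl / 2, sub$CH4)
    expect_lt(cor(so4, ch4, method = "spearman"), 0, label = grp)
  }
})

test_that("noise-free generation allows exact latent-pathway recovery", {
  sim <- generate_catchment(n_per_aquifer = c(ALLUVIUM = 60,
                                              SHALLOW_COAL_MEASURES = 60),
                            seed = 3L, delta_noise = 0,
                            ch4_detect = "always")
  s <- sim$samples
  calls <- vapply(seq_len(nrow(s)), function(i) {
    classify_pathway(
      fractionation_factor(s$d13C_DIC[i], s$d13C_CH4[i]),
      fractionation_factor(s$d2H_H2O[i], s$d2H_CH4[i]),
      s$d2H_CH4[i])$call
  }, character(1))
  truth <- ifelse(sim$labels$pathway == "ACETOCLASTIC",
                  "ACETOCLASTIC_OR_OXIDATION", "CO2_REDUCTION")
  expect_identical(calls, truth)
})

test_that("latent labels stay in a separate table from the samples", {
  sim <- generate_catchment(seed = 1L)
  expect_false("pathway" %in% names(sim$samples))
  expect_setequal(names(sim$labels), c("sample_id", "aquifer_group", "pathway"))
  expect_identical(sim$labels$sample_id, sim$samples$sample_id)
})
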