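test_that("balance coefficients follow sqrt(rs/(r+s))", {
  expect_equal(balance_coefficient(1, 1), sqrt(1 / 2), tolerance = 1e-12)
  expect_equal(round(balance_coefficient(1, 1), 4), 0.7071)
  expect_equal(round(balance_coefficient(1, 3), 4), 0.8660)
  expect_equal(balance_coefficient(2, 2), 1)
  expect_error(balance_coefficient(0, 1))
})

test_that("the shipped pathway partitions validate; malformed ones do not", {
  for (nm in names(shipped_sbps())) {
    expect_true(validate_sbp(shipped_sbps()[[nm]])$valid, label = nm)
  }
  # a row of all +1 has no -1 part
  v <- validate_sbp(list(parts = letters[1:3],
                         codes = rbind(c(1, 1, 1), c(1, -1, 0))))
  expect_false(v$valid)
  expect_match(v$issues, "at least one", all = FALSE)
  # a duplicated row breaks the hierarchy
  v2 <- validate_sbp(list(parts = letters[1:4],
                          codes = rbind(c(1, 1, -1, -1), c(1, 1, -1, -1),
                                        c(0, 0, -1, 1))))
  expect_false(v2$valid)
  # wrong row count
  v3 <- validate_sbp(list(parts = letters[1:4],
                          codes = rbind(c(1, -1, -1, -1))))
  expect_false(v3$valid)
})

test_that("ilr balances reproduce hand-evaluated cases", {
  b4 <- sbp(paste0("x", 1:4),
            matrix(c(1, 1, -1, -1,
                     1, -1, 0, 0,
                     0, 0, -1, 1), 3, byrow = TRUE,
                   dimnames = list(paste0("z", 1:3), NULL)))
  expect_equal(unname(ilr_transform(c(1, 1, 1, 1), b4)), c(0, 0, 0))
  expect_equal(unname(ilr_transform(c(4, 1, 1, 1), b4)[1]), log(2),
               tolerance = 1e-12)
  # pathway balance, first coordinate: sqrt(3)/2 * ln(a_CH4 / g(reactants))
  a <- c(H = 1e-7, H2 = 1e-9, HCO3 = 1e-3, CH4 = 1e-4)
  expected1 <- sqrt(3) / 2 * (log(1e-4) - mean(log(c(1e-7, 1e-9, 1e-3))))
  got <- pathway_ilr(c(a, SO4 = 1, HS = 1), "CO2")
  expect_equal(unname(got[1]), expected1, tolerance = 1e-12)
  expect_equal(unname(got[1]), 4.652893, tolerance = 1e-6)
  expect_named(got, paste0("CO2_ilr.", 1:3))
  # all-equal activities collapse every balance to zero
  eq <- c(H = 2, H2 = 2, HCO3 = 2, CH4 = 2, SO4 = 2, HS = 2)
  for (pw in c("CO2", "SO4", "AOM")) {
    expect_equal(unname(pathway_ilr(eq, pw)), c(0, 0, 0))
  }
  expect_error(pathway_ilr(c(H = 1e-7, H2 = 1e-9, HCO3 = 1e-3), "CO2"),
               "missing activities")
  expect_error(ilr_transform(c(1, 0, 1, 1), b4), "nonpositive")
})

test_that("ilr is scale invariant", {
  set.seed(1)
  b <- shipped_sbps()$CO2
  for (i in 1:50) {
    x <- stats::setNames(exp(rnorm(4, 0, 3)), b$parts)
    k <- exp(rnorm(1, 0, 2))
    expect_equal(ilr_transform(k * x, b), ilr_transform(x, b),
                 tolerance = 1e-10)
  }
})

test_that("ilr distance equals brute-force Aitchison distance (isometry)", {
  set.seed(2)
  b <- shipped_sbps()$AOM
  for (i in 1:1000) {
    x <- stats::setNames(exp(rnorm(4, 0, 2)), b$parts)
    y <- stats::setNames(exp(rnorm(4, 0, 2)), b$parts)
    d_ilr <- sqrt(sum((ilr_transform(x, b) - ilr_transform(y, b))^2))
    expect_equal(d_ilr, aitchison_dist(x, y), tolerance = 1e-10)
  }
})

test_that("each pathway's ilr.1 tracks its reaction quotient", {
  sim <- generate_catchment(n_per_aquifer = c(ALLUVIUM = 100,
                                              SHALLOW_COAL_MEASURES = 100),
                            seed = 11)
  res <- run_pipeline(run_config(sim$samples))
  ps <- res$per_sample
  for (pw in c("CO2", "SO4", "AOM")) {
    rho <- cor(ps[[paste0(pw, "_ilr.1")]], ps[[paste0(pw, "_lnQ")]],
               method = "spearman", use = "complete.obs")
    expect_gt(rho, 0)
  }
})

test_that("SBPs round-trip through their plain-text format", {
  b <- shipped_sbps()$SO4
  f <- tempfile(fileext = ".csv")
  write_sbp(b, f)
  b2 <- read_sbp(f)
  expect_equal(b2$parts, b$parts)
  expect_equal(unname(b2$codes), unname(b$codes))
  # the shipped extdata copies load and validate too
  for (f in c("sbp_co2.csv", "sbp_so4.csv", "sbp_aom.csv")) {
    p <- system.file("extdata", f, package = "ch4path")
    expect_true(validate_sbp(read_sbp(p))$valid, label = f)
  }
})
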