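# Shared fixtures, all built in code at test time.

# A 3-row sample CSV exercising both censoring conventions and missingness.
write_fixture_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    paste0("sample_id,aquifer_group,screen_depth,temperature,pH,DO,",
           "Na,Cl,HCO3,Ca,Mg,SO4,SO4_dl,SO4_cens,NO3,CH4,",
           "d13C_CH4,d2H_CH4,d13C_DIC,d2H_H2O,d37Cl"),
    "W1,ALLUVIUM,45,22.5,7.1,0.4,120,350,420,55,30,88,1,FALSE,0.4,120,-70.2,-230.1,-12.5,-33,0.2",
    "W2,SHALLOW_COAL_MEASURES,150,24,8.2,0.1,800,1775,900,20,15,<1,,,0.02,9500,-58,-210,-8,-31,",
    "W3,GAS_RESERVOIR,320,30,8.6,0.05,1500,4200,1100,10,8,1,1,TRUE,<0.01,24000,-52,-200,15,-40,-1.2"),
    path)
  path
}

# Samples with known sub-DL truths: SO4 drawn log-uniformly across the DL,
# with correlated covariates so conditional imputation has signal. Returns
# the censored table plus the hidden true values of the censored cells.
make_censored_truth <- function(n = 250, dl = 1, seed = 42) {
  set.seed(seed)
  log_so4 <- runif(n, log(0.1 * dl), log(10 * dl))
  so4 <- exp(log_so4)
  noise <- function(s) exp(rnorm(n, 0, s))
  df <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    aquifer_group = "ALLUVIUM",
    temperature = 22, pH = 7.5,
    Na = 80 * so4^0.6 * noise(0.15),
    K = 5 * so4^0.4 * noise(0.2),
    Ca = 40 * so4^0.7 * noise(0.15),
    Mg = 25 * so4^0.7 * noise(0.15),
    HCO3 = 400 * so4^0.2 * noise(0.1),
    Cl = 300 * so4^0.8 * noise(0.15),
    SO4 = so4, SO4_dl = dl, SO4_cens = so4 < dl)
  truth <- so4[df$SO4_cens]
  df$SO4[df$SO4_cens] <- NA
  list(samples = water_samples(df), truth = truth)
}

# Brute-force Aitchison distance via the clr transform.
aitchison_dist <- function(x, y) {
  clr <- function(v) log(v) - mean(log(v))
  sqrt(sum((clr(x) - clr(y))^2))
}
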