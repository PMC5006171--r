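#' Imputation configuration for below-detection-limit values
#'
#' @param method `"multiplicative"` (deterministic replacement at
#'   `dl_fraction` x DL, the default) or `"lrda"` (seeded log-ratio
#'   data-augmentation chain conditional on the uncensored covariance of the
#'   major ions).
#' @param dl_fraction Fraction of the detection limit used by multiplicative
#'   replacement; must lie strictly in (0, 1). Default 0.65.
#' @param n_chains Number of data-augmentation sweeps for the `"lrda"` method.
#' @param seed Integer seed; recorded in the imputation report.
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(method = c("multiplicative", "lrda"),
                              dl_fraction = 0.65, n_chains = 50L,
                              seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(dl_fraction) || length(dl_fraction) != 1 ||
      dl_fraction <= 0 || dl_fraction >= 1) {
    stop("dl_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(method = method, dl_fraction = dl_fraction,
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "imputation_config")
}

# Major-ion covariates conditioning the lrda chain.
.lrda_covariates <- c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "SO4")

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# One truncated-normal draw on the log scale, bounded above at log(DL).
.rtnorm_below <- function(n, mean, sd, upper) {
  u <- stats::runif(n)
  p <- stats::pnorm((upper - mean) / sd)
  q <- stats::qnorm(pmin(pmax(u * p, 1e-12), 1 - 1e-12))
  pmin(mean + sd * q, upper - 1e-9)
}

#' Impute below-detection-limit concentrations
#'
#' Replaces every censored concentration by a strictly positive value below
#' its detection limit, leaving uncensored values untouched. Imputation is
#' performed per aquifer group, since the groups occupy distinct compositional
#' ranges. The deterministic default multiplies the detection limit by
#' `dl_fraction`; the `"lrda"` method runs a seeded Gaussian
#' data-augmentation chain on log concentrations, drawing each censored cell
#' from its conditional normal given the sample's uncensored major ions,
#' truncated above at the detection limit. A species with no uncensored
#' observations in a group falls back to multiplicative replacement with a
#' warning.
#'
#' Re-running on already-imputed data is a no-op (no censored flags remain).
#'
#' @param samples A `water_samples` tibble.
#' @param config An [imputation_config()].
#' @return The imputed `water_samples` tibble, with an `imputation_report`
#'   attribute (tibble: species, n_censored, method, seed, min/max imputed).
#' @export
impute_below_dl <- function(samples, config = imputation_config()) {
  stopifnot(inherits(samples, "water_samples"))
  report <- list()
  out <- samples
  with_seed(config$seed, {
    for (grp in unique(out$aquifer_group)) {
      rows <- which(out$aquifer_group == grp)
      out[rows, ] <- .impute_group(out[rows, ], config)
    }
  })
  for (sp in censorable_species()) {
    cens <- samples[[paste0(sp, "_cens")]]
    n <- sum(cens)
    imp <- out[[sp]][cens]
    report[[sp]] <- tibble::tibble(
      species = sp, n_censored = n,
      method = if (n) config$method else NA_character_,
      seed = config$seed,
      min_imputed = if (n) min(imp) else NA_real_,
      max_imputed = if (n) max(imp) else NA_real_)
  }
  attr(out, "imputation_report") <- do.call(rbind, unname(report))
  out
}

.impute_group <- function(g, config) {
  for (sp in censorable_species()) {
    cens <- g[[paste0(sp, "_cens")]]
    if (!any(cens)) next
    dl <- g[[paste0(sp, "_dl")]][cens]
    vals <- NULL
    if (config$method == "lrda") {
      vals <- .lrda_impute(g, sp, cens, config)
      if (is.null(vals)) {
        warning("species ", sp, " has no usable uncensored values in group ",
                g$aquifer_group[1],
                "; falling back to multiplicative replacement", call. = FALSE)
      }
    }
    if (is.null(vals)) vals <- config$dl_fraction * dl
    g[[sp]][cens] <- vals
    g[[paste0(sp, "_cens")]][cens] <- FALSE
  }
  g
}

# Conditional-normal DA draws for one species within one aquifer group.
# Returns NULL when the species has no uncensored observations to anchor it.
.lrda_impute <- function(g, sp, cens, config) {
  obs <- g[[sp]][!cens]
  obs <- obs[!is.na(obs) & obs > 0]
  if (length(obs) < 1) return(NULL)
  log_dl <- log(g[[paste0(sp, "_dl")]][cens])
  mu_sp <- mean(log(obs))
  sd_sp <- if (length(obs) >= 3) stats::sd(log(obs)) else 1
  if (!is.finite(sd_sp) || sd_sp <= 0) sd_sp <- 1

  covs <- setdiff(.lrda_covariates, sp)
  X <- sapply(covs, function(cv) {
    v <- g[[cv]]
    v[g[[paste0(cv, "_cens")]]] <- NA
    log(v)
  })
  if (is.null(dim(X))) X <- matrix(X, nrow = nrow(g))
  keep <- apply(X, 2, function(col) all(is.finite(col)))
  X <- X[, keep, drop = FALSE]
  y0 <- log(g[[sp]])

  can_condition <- ncol(X) >= 1 && sum(!cens & !is.na(g[[sp]])) >= ncol(X) + 2
  draws <- .rtnorm_below(sum(cens), mu_sp, sd_sp, log_dl)
  if (!can_condition) return(exp(draws))

  y <- y0
  y[cens] <- draws
  use <- !is.na(y)                      # rows where the species was measured
  Z <- cbind(1, X)
  for (it in seq_len(config$n_chains)) {
    fit <- stats::lm.fit(Z[use, , drop = FALSE], y[use])
    res_sd <- sqrt(sum(fit$residuals^2) / max(fit$df.residual, 1))
    if (!is.finite(res_sd) || res_sd <= 0) res_sd <- sd_sp
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    mu_cond <- (Z %*% beta)[cens]
    y[cens] <- .rtnorm_below(sum(cens), mu_cond, res_sd, log_dl)
  }
  exp(y[cens])
}
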