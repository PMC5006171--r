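#' Pipeline run configuration
#'
#' Bundles every tunable of a pipeline run; the full configuration, seed
#' included, is echoed into the output directory so any run can be
#' reproduced byte-for-byte.
#'
#' @param input Path to a sample CSV (see [read_samples()]), or a
#'   `water_samples` tibble.
#' @param out_dir Output directory for result tables; `NULL` to return
#'   tables without writing.
#' @param imputation An [imputation_config()].
#' @param h2 An [h2_config()].
#' @param thresholds A [pathway_thresholds()].
#' @param seed Integer seed for the imputation chain.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir = NULL,
                       imputation = imputation_config(),
                       h2 = h2_config(),
                       thresholds = pathway_thresholds(),
                       seed = 1L, log_level = "info") {
  imputation$seed <- as.integer(seed)
  structure(list(input = input, out_dir = out_dir, imputation = imputation,
                 h2 = h2, thresholds = thresholds, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Run the full attribution pipeline
#'
#' Orchestrates imputation, speciation, thermodynamics, pathway balances and
#' isotope classification over a sample table: unit conversions (meq/L,
#' Br/Cl molar ratio), below-DL imputation per aquifer group, ionic
#' strength and Davies activities, Q / ln Q / ΔG°_T / ΔG / ΔG per electron
#' for the three microbial reactions, the nine pathway balances
#' (CO2/SO4/AOM ilr.1-3), both fractionation factors, the gypsum saturation
#' index and a categorical pathway call per sample. Per-sample failures
#' (e.g. a well without CH4) never abort the run; the affected columns are
#' left absent and the reason logged.
#'
#' @param config A [run_config()], or a path / `water_samples` tibble which
#'   is wrapped in one with defaults.
#' @return List with `per_sample` (tibble), `summary` (per-aquifer
#'   min/median/max of every numeric column, long), `imputation_report`,
#'   `log` (character), and `config`. When `config$out_dir` is set, writes
#'   `per_sample.csv`, `summary.csv`, `imputation_report.csv`, `log.txt`
#'   and `run_config.yaml` there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  samples <- config$input
  if (is.character(samples)) samples <- read_samples(samples)
  stopifnot(inherits(samples, "water_samples"))
  if (!nrow(samples)) stop("empty input: no samples to process", call. = FALSE)
  note("samples read: ", nrow(samples))

  imputed <- impute_below_dl(samples, config$imputation)
  rep_imp <- attr(imputed, "imputation_report")
  note("imputation: method=", config$imputation$method,
       " seed=", config$imputation$seed,
       " cells=", sum(rep_imp$n_censored))

  act <- species_activities(imputed, config$h2)
  high_i <- act$ionic_strength > 0.7
  if (any(high_i)) {
    note("Davies validity warning (I > 0.7 mol/L) for: ",
         paste(act$sample_id[high_i], collapse = ", "))
  }

  out <- tibble::tibble(
    sample_id = imputed$sample_id,
    aquifer_group = imputed$aquifer_group,
    screen_depth = imputed$screen_depth,
    temperature = imputed$temperature,
    pH = imputed$pH)
  for (sp in c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "Br", "SO4", "NO3")) {
    out[[paste0(sp, "_meq")]] <- mgL_to_meqL(imputed[[sp]], sp)
  }
  out$Br_Cl_molar <- mgL_to_molL(imputed$Br, "Br") /
    mgL_to_molL(imputed$Cl, "Cl")
  out$ionic_strength <- act$ionic_strength
  for (col in c("a_H", "a_H2", "a_HCO3", "a_CH4", "a_SO4", "a_HS", "a_Ca")) {
    out[[col]] <- act[[col]]
  }

  rxns <- shipped_reactions()
  n <- nrow(imputed)
  act_names <- c("H", "H2", "HCO3", "CH4", "SO4", "HS")
  for (rx in names(rxns)) {
    short <- c(CO2_REDUCTION = "CO2", SO4_REDUCTION = "SO4", AOM = "AOM")[[rx]]
    out[[paste0(short, "_dG0T")]] <- delta_g0_T(rxns[[rx]], imputed$temperature)
    lnq <- dg <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      a <- stats::setNames(as.numeric(
        act[i, paste0("a_", act_names)]), act_names)
      q <- tryCatch(reaction_quotient(rxns[[rx]], a), error = function(e) {
        note("sample ", imputed$sample_id[i], ": skipped ", rx, " (",
             conditionMessage(e), ")")
        NULL
      })
      if (is.null(q)) next
      lnq[i] <- q$lnQ
      dg[i] <- delta_g(rxns[[rx]], imputed$temperature[i], lnQ = q$lnQ)
    }
    out[[paste0(short, "_lnQ")]] <- lnq
    out[[paste0(short, "_dG")]] <- dg
    out[[paste0(short, "_dG_per_e")]] <- delta_g_per_electron(dg, rxns[[rx]])
  }

  for (pw in c("CO2", "SO4", "AOM")) {
    bal <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, paste0(pw, "_ilr.", 1:3)))
    for (i in seq_len(n)) {
      a <- stats::setNames(as.numeric(
        act[i, paste0("a_", act_names)]), act_names)
      b <- tryCatch(pathway_ilr(a, pw), error = function(e) {
        note("sample ", imputed$sample_id[i], ": skipped ", pw, " balances (",
             conditionMessage(e), ")")
        NULL
      })
      if (!is.null(b)) bal[i, ] <- b
    }
    for (j in 1:3) out[[colnames(bal)[j]]] <- bal[, j]
  }

  out$alpha_DIC_CH4 <- suppressWarnings(
    fractionation_factor(imputed$d13C_DIC, imputed$d13C_CH4))
  out$alpha_H2O_CH4 <- suppressWarnings(
    fractionation_factor(imputed$d2H_H2O, imputed$d2H_CH4))
  bad_a <- which(pmin(out$alpha_DIC_CH4, out$alpha_H2O_CH4) < 0.8 |
                   pmax(out$alpha_DIC_CH4, out$alpha_H2O_CH4) > 1.8)
  if (length(bad_a)) {
    note("fractionation factor outside (0.8, 1.8) sanity band for: ",
         paste(out$sample_id[bad_a], collapse = ", "))
  }
  out$gypsum_SI <- gypsum_si(act$a_Ca, act$a_SO4)
  na_si <- is.na(out$gypsum_SI)
  if (any(na_si)) {
    note("gypsum SI absent (missing Ca or SO4) for: ",
         paste(out$sample_id[na_si], collapse = ", "))
  }

  calls <- lapply(seq_len(n), function(i) {
    classify_pathway(out$alpha_DIC_CH4[i], out$alpha_H2O_CH4[i],
                     imputed$d2H_CH4[i], out$SO4_meq[i], config$thresholds)
  })
  out$pathway_call <- vapply(calls, `[[`, character(1), "call")
  out$pathway_evidence <- vapply(calls, function(cl) {
    paste(cl$evidence, collapse = " | ")
  }, character(1))

  summary_tbl <- .aquifer_summary(out)
  result <- list(per_sample = out, summary = summary_tbl,
                 imputation_report = rep_imp, log = log_lines,
                 config = config)
  if (!is.null(config$out_dir)) .write_outputs(result, config)
  result
}

.aquifer_summary <- function(per_sample) {
  num_cols <- names(per_sample)[vapply(per_sample, is.numeric, logical(1))]
  rows <- list()
  for (grp in unique(per_sample$aquifer_group)) {
    sub <- per_sample[per_sample$aquifer_group == grp, ]
    for (col in num_cols) {
      v <- sub[[col]]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1]] <- tibble::tibble(
        aquifer_group = grp, variable = col, n = length(v),
        min = if (length(v)) min(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

.write_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(result$per_sample, p("per_sample.csv"), row.names = FALSE)
  utils::write.csv(result$summary, p("summary.csv"), row.names = FALSE)
  utils::write.csv(result$imputation_report, p("imputation_report.csv"),
                   row.names = FALSE)
  writeLines(result$log, p("log.txt"))
  cfg <- config
  cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory table>"
  cfg$thresholds <- unclass(cfg$thresholds)
  cfg$imputation <- unclass(cfg$imputation)
  cfg$h2 <- unclass(cfg$h2)
  yaml::write_yaml(unclass(cfg), p("run_config.yaml"))
  invisible(NULL)
}
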