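#' @title Groundwater sample tables
#' @description One row per well/sample. Censorable concentrations are carried
#'   as value/detection-limit/flag column triples so that below-detection
#'   values stay distinguishable from genuinely missing ones.
#' @name sample_model
NULL

#' Aquifer groups recognised by the pipeline
#' @export
aquifer_groups <- function() {
  c("ALLUVIUM", "SHALLOW_COAL_MEASURES", "GAS_RESERVOIR", "KUMBARILLA")
}

#' Censorable ion species carried on a sample table (mg/L)
#' @export
ion_species <- function() {
  c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "Br", "SO4", "NO3",
    "S2", "HS", "Fe", "Mn")
}

# All censorable concentration columns: ions (mg/L) plus dissolved CH4 (ug/L).
censorable_species <- function() c(ion_species(), "CH4")

isotope_columns <- function() {
  c("d13C_CH4", "d2H_CH4", "d13C_DIC", "d2H_H2O", "d18O_H2O", "d37Cl")
}

#' Default analytical detection limits
#'
#' mg/L for ions, ug/L for CH4, TU for tritium. Used when a table supplies no
#' per-cell detection limit.
#'
#' @return Named numeric vector.
#' @export
default_detection_limits <- function() {
  c(Na = 1, K = 1, Ca = 1, Mg = 1, HCO3 = 1, Cl = 1, Br = 0.01,
    SO4 = 1, NO3 = 0.01, S2 = 0.1, HS = 0.1, Fe = 0.05, Mn = 0.001,
    CH4 = 10)
}

.sample_columns <- function() {
  sp <- censorable_species()
  c("sample_id", "aquifer_group", "screen_depth", "temperature", "pH", "DO",
    as.vector(rbind(sp, paste0(sp, "_dl"), paste0(sp, "_cens"))),
    "DOC", "tritium", isotope_columns())
}

#' Construct and validate a groundwater sample table
#'
#' Checks physical invariants: temperature in (0, 60) degC, pH in (2, 12),
#' isotope deltas in (-1000, 1000) per mil, concentrations non-negative,
#' detection limits positive, and censored cells consistent with their
#' detection limit. Missing optional fields are NA, never zero.
#'
#' @param df A data frame with at least `sample_id`, `aquifer_group`,
#'   `temperature`, `pH`. Censorable species may be supplied as plain value
#'   columns; `<species>_dl` and `<species>_cens` columns are filled in.
#' @return A `water_samples` tibble with the full column set.
#' @export
water_samples <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "aquifer_group", "temperature", "pH")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_grp <- setdiff(unique(df$aquifer_group), aquifer_groups())
  if (length(bad_grp)) {
    stop("unknown aquifer_group: ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  }
  dls <- default_detection_limits()
  for (sp in censorable_species()) {
    if (!sp %in% names(df)) df[[sp]] <- NA_real_
    dl_col <- paste0(sp, "_dl"); cs_col <- paste0(sp, "_cens")
    if (!dl_col %in% names(df)) df[[dl_col]] <- unname(dls[sp])
    if (!cs_col %in% names(df)) df[[cs_col]] <- FALSE
    df[[sp]] <- as.numeric(df[[sp]])
    df[[dl_col]] <- as.numeric(df[[dl_col]])
    df[[dl_col]][is.na(df[[dl_col]])] <- unname(dls[sp])
    df[[cs_col]] <- isTRUE_vec(df[[cs_col]])
  }
  for (col in setdiff(.sample_columns(), names(df))) df[[col]] <- NA_real_
  df <- df[, .sample_columns()]

  chk <- function(ok, what) {
    if (!all(ok, na.rm = TRUE)) {
      stop("invalid ", what, " for sample(s): ",
           paste(df$sample_id[which(!ok)], collapse = ", "), call. = FALSE)
    }
  }
  chk(df$temperature > 0 & df$temperature < 60, "temperature (must be in (0, 60) degC)")
  chk(df$pH > 2 & df$pH < 12, "pH (must be in (2, 12))")
  for (col in isotope_columns()) {
    chk(df[[col]] > -1000 & df[[col]] < 1000,
        paste0(col, " (must be in (-1000, 1000) per mil)"))
  }
  for (sp in censorable_species()) {
    chk(df[[sp]] >= 0, paste0(sp, " (negative concentration)"))
    chk(df[[paste0(sp, "_dl")]] > 0, paste0(sp, " detection limit (must be > 0)"))
    cens <- df[[paste0(sp, "_cens")]]
    val <- df[[sp]]
    ok <- !cens | is.na(val) | val <= df[[paste0(sp, "_dl")]]
    chk(ok, paste0(sp, " (censored value exceeds its detection limit)"))
  }
  class(df) <- c("water_samples", class(df))
  df
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "y")
}

#' Read a groundwater sample table from CSV
#'
#' Comma-separated, UTF-8, "." decimal separator. Two censoring conventions
#' are accepted and may be mixed: a `"<DL"` prefix in a concentration cell
#' (e.g. `"<1"`), or a paired `<species>_cens` flag column alongside a
#' `<species>_dl` detection-limit column. Empty cells become NA (absent),
#' never zero.
#'
#' @param path Path to a CSV file with a header row; required columns
#'   `sample_id`, `aquifer_group`, `temperature`, `pH`.
#' @return A validated `water_samples` tibble.
#' @export
read_samples <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", na.strings = c("", "NA"))
  required <- c("sample_id", "aquifer_group", "temperature", "pH")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("input file ", path, " is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("unparseable number in column '", col, "' at data row(s) ",
           paste(bad, collapse = ", "), " of ", path, call. = FALSE)
    }
    out
  }
  df <- tibble::tibble(sample_id = raw$sample_id,
                       aquifer_group = raw$aquifer_group)
  for (col in c("screen_depth", "temperature", "pH", "DO", "DOC", "tritium",
                isotope_columns())) {
    df[[col]] <- if (col %in% names(raw)) num(raw[[col]], col) else NA_real_
  }
  dls <- default_detection_limits()
  for (sp in censorable_species()) {
    dl_col <- paste0(sp, "_dl"); cs_col <- paste0(sp, "_cens")
    cells <- if (sp %in% names(raw)) raw[[sp]] else rep(NA_character_, nrow(raw))
    cells <- trimws(cells)
    prefixed <- !is.na(cells) & startsWith(cells, "<")
    dl <- if (dl_col %in% names(raw)) num(raw[[dl_col]], dl_col) else
      rep(NA_real_, nrow(raw))
    cens <- if (cs_col %in% names(raw)) isTRUE_vec(raw[[cs_col]]) else
      rep(FALSE, nrow(raw))
    val <- cells
    val[prefixed] <- NA_character_
    val <- num(val, sp)
    # "<x" cells carry their own detection limit; flagged cells keep the
    # numeric cell as the DL when no _dl column is given.
    dl[prefixed] <- num(sub("^<", "", cells[prefixed]), sp)
    take <- cens & is.na(dl) & !is.na(val)
    dl[take] <- val[take]
    dl[is.na(dl)] <- unname(dls[sp])
    val[cens] <- NA_real_
    df[[sp]] <- val
    df[[dl_col]] <- dl
    df[[cs_col]] <- cens | prefixed
  }
  water_samples(df)
}

#' Write a groundwater sample table to CSV
#'
#' Censored cells are rendered with the `"<DL"` prefix convention; numeric
#' fields are written with full (round-trip) precision.
#'
#' @param x A `water_samples` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(x, path) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(sample_id = x$sample_id, aquifer_group = x$aquifer_group,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("screen_depth", "temperature", "pH", "DO")) out[[col]] <- fmt(x[[col]])
  for (sp in censorable_species()) {
    cens <- x[[paste0(sp, "_cens")]]
    cell <- fmt(x[[sp]])
    cell[cens] <- paste0("<", sprintf("%.17g", x[[paste0(sp, "_dl")]][cens]))
    out[[sp]] <- cell
    out[[paste0(sp, "_dl")]] <- fmt(x[[paste0(sp, "_dl")]])
  }
  for (col in c("DOC", "tritium", isotope_columns())) out[[col]] <- fmt(x[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
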