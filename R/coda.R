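#' Sequential binary partition
#'
#' An SBP defines an orthonormal isometric-log-ratio basis over D named
#' parts through D-1 rows of codes in {+1, -1, 0}: each row splits one group
#' of parts (kept together by all previous rows) into a +1 and a -1 subset.
#'
#' @param parts Ordered character vector of part names.
#' @param codes Numeric matrix with D-1 rows and D columns of codes in
#'   {+1, -1, 0}; row names become balance names.
#' @param validate Check SBP validity (default TRUE).
#' @return An `sbp` object.
#' @export
sbp <- function(parts, codes, validate = TRUE) {
  codes <- as.matrix(codes)
  colnames(codes) <- parts
  obj <- structure(list(parts = parts, codes = codes), class = "sbp")
  if (validate) {
    v <- validate_sbp(obj)
    if (!v$valid) {
      stop("invalid SBP: ", paste(v$issues, collapse = "; "), call. = FALSE)
    }
  }
  obj
}

#' Validate a sequential binary partition
#'
#' Checks the row count (D-1 rows for D parts), that codes are in
#' {+1, -1, 0}, that every row has at least one +1 and one -1, and that the
#' rows form a valid hierarchy: the nonzero parts of each row must exactly
#' cover one group kept together by all previous rows, which the row then
#' splits into its +1 and -1 subsets.
#'
#' @param x An `sbp` object or a bare list with `parts` and `codes`.
#' @return List with `valid` (logical) and `issues` (character vector
#'   naming each offending row).
#' @export
validate_sbp <- function(x) {
  parts <- x$parts
  codes <- as.matrix(x$codes)
  issues <- character()
  D <- length(parts)
  if (nrow(codes) != D - 1) {
    issues <- c(issues, sprintf("expected %d rows for %d parts, found %d",
                                D - 1, D, nrow(codes)))
  }
  if (ncol(codes) != D) {
    issues <- c(issues, "code matrix column count does not match parts")
    return(list(valid = FALSE, issues = issues))
  }
  if (!all(codes %in% c(-1, 0, 1))) {
    issues <- c(issues, "codes must be in {+1, -1, 0}")
  }
  groups <- list(seq_len(D))
  for (r in seq_len(nrow(codes))) {
    row <- codes[r, ]
    plus <- which(row == 1); minus <- which(row == -1)
    rname <- rownames(codes)[r] %||na% paste0("row ", r)
    if (!length(plus) || !length(minus)) {
      issues <- c(issues, paste0(rname, ": needs at least one +1 and one -1"))
      next
    }
    nz <- unname(sort(c(plus, minus)))
    hit <- which(vapply(groups, function(g) {
      identical(unname(sort(as.integer(g))), as.integer(nz))
    }, logical(1)))
    if (!length(hit)) {
      issues <- c(issues, paste0(
        rname, ": does not split a group kept together by previous rows"))
      next
    }
    groups <- c(groups[-hit[1]],
                if (length(plus) > 1) list(plus),
                if (length(minus) > 1) list(minus))
  }
  list(valid = length(issues) == 0, issues = issues)
}

`%||na%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Balance normalising coefficient
#'
#' \eqn{\sqrt{rs/(r+s)}} for a balance with r parts coded +1 and s parts
#' coded -1.
#'
#' @param r,s Positive part counts.
#' @return Unitless coefficient.
#' @export
#' @examples
#' balance_coefficient(1, 1)  # 0.7071
#' balance_coefficient(1, 3)  # 0.8660
balance_coefficient <- function(r, s) {
  stopifnot(all(r >= 1), all(s >= 1))
  sqrt(r * s / (r + s))
}

#' Isometric log-ratio transform
#'
#' For each balance, \eqn{\sqrt{r_i s_i/(r_i+s_i)} \,
#' \ln(g(x_+)/g(x_-))} where g is the geometric mean over the +1-coded and
#' -1-coded parts. Balances are scale invariant, so x need not be closed to
#' a constant sum; activities are used directly.
#'
#' @param x Strictly positive numeric vector over the SBP's parts (named or
#'   in part order).
#' @param basis An `sbp` object.
#' @return Named vector of D-1 balances.
#' @export
ilr_transform <- function(x, basis) {
  stopifnot(inherits(basis, "sbp"))
  if (!is.null(names(x))) {
    missing_parts <- setdiff(basis$parts, names(x))
    if (length(missing_parts)) {
      stop("missing parts: ", paste(missing_parts, collapse = ", "),
           call. = FALSE)
    }
    x <- x[basis$parts]
  }
  if (length(x) != length(basis$parts)) {
    stop("x must have one entry per part", call. = FALSE)
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop("nonpositive composition part(s): ",
         paste(basis$parts[bad], collapse = ", "),
         " (imputation upstream must leave all parts strictly positive)",
         call. = FALSE)
  }
  lx <- log(x)
  out <- apply(basis$codes, 1, function(row) {
    r <- sum(row == 1); s <- sum(row == -1)
    balance_coefficient(r, s) *
      (mean(lx[row == 1]) - mean(lx[row == -1]))
  })
  stats::setNames(out, rownames(basis$codes))
}

#' Shipped SBPs for the three reaction pathways
#'
#' One four-part SBP per reaction, the first balance separating the reaction
#' product from the reactants (so pathway ilr.1 tracks the reaction
#' quotient) and the remaining balances partitioning the reactants into
#' subcompositions. Part order follows the reaction's species table; blank
#' cells are coded 0.
#'
#' @return Named list of `sbp` objects (`CO2`, `SO4`, `AOM`).
#' @export
shipped_sbps <- function() {
  list(
    CO2 = sbp(c("H", "H2", "HCO3", "CH4"), matrix(
      c(-1, -1, -1,  1,
        -1,  1, -1,  0,
        -1,  0,  1,  0), nrow = 3, byrow = TRUE,
      dimnames = list(paste0("CO2_ilr.", 1:3), NULL))),
    SO4 = sbp(c("SO4", "H2", "H", "HS"), matrix(
      c(-1, -1, -1,  1,
        -1,  1, -1,  0,
         1,  0, -1,  0), nrow = 3, byrow = TRUE,
      dimnames = list(paste0("SO4_ilr.", 1:3), NULL))),
    AOM = sbp(c("HCO3", "CH4", "SO4", "HS"), matrix(
      c( 1, -1, -1,  1,
         1,  0,  0, -1,
         0,  1, -1,  0), nrow = 3, byrow = TRUE,
      dimnames = list(paste0("AOM_ilr.", 1:3), NULL))))
}

#' Read / write an SBP as a plain-text file
#'
#' CSV with part names as header and one row of {+1, -1, 0} codes per
#' balance; row names in the first column. Lets users define new pathways.
#'
#' @param path File path.
#' @return `read_sbp`: an `sbp` object. `write_sbp`: `path`, invisibly.
#' @export
read_sbp <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  sbp(colnames(df), as.matrix(df))
}

#' @rdname read_sbp
#' @param x An `sbp` object.
#' @export
write_sbp <- function(x, path) {
  df <- as.data.frame(x$codes)
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Pathway balances for one sample's activities
#'
#' Applies the reaction's shipped SBP to the sample's activity vector,
#' ordered as in the reaction's partition table.
#'
#' @param activities Named activities including the reaction's four parts
#'   (names `H`, `H2`, `HCO3`, `CH4`, `SO4`, `HS` as relevant).
#' @param reaction One of `"CO2"`, `"SO4"`, `"AOM"`.
#' @return Named vector of three balances (e.g. `CO2_ilr.1..3`), or an
#'   error when a needed activity is missing.
#' @export
pathway_ilr <- function(activities, reaction = c("CO2", "SO4", "AOM")) {
  reaction <- match.arg(reaction)
  basis <- shipped_sbps()[[reaction]]
  a <- activities[basis$parts]
  if (anyNA(a)) {
    stop("missing activities for pathway ", reaction, ": ",
         paste(basis$parts[is.na(a)], collapse = ", "), call. = FALSE)
  }
  ilr_transform(stats::setNames(as.numeric(a), basis$parts), basis)
}
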