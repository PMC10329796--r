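#' Construct a family-level count table
#'
#' The central container: one row per family with the number of native
#' species (`n_total`, the interval denominator) and the number of those
#' with a recorded use (`x_used`). Flora-wide totals are carried as
#' attributes `N_total` and `X_total` and always recomputed from the rows.
#'
#' @param family character vector of family names (unique).
#' @param n_total integer vector, `n_total >= 1`.
#' @param x_used integer vector, `0 <= x_used <= n_total`.
#' @return A data frame of class `flora_table` with attributes `N_total`
#'   and `X_total`.
#' @export
#' @examples
#' flora_table(c("Arecaceae", "Poaceae"), c(300, 1297), c(27, 2))
flora_table <- function(family, n_total, x_used) {
  family <- as.character(family)
  n_total <- as.integer(n_total)
  x_used <- as.integer(x_used)
  if (length(family) == 0) stop("flora_table: at least one family required")
  if (length(n_total) != length(family) || length(x_used) != length(family)) {
    stop("flora_table: family, n_total, x_used must have equal length")
  }
  if (anyNA(family) || any(!nzchar(family))) stop("flora_table: family names must be non-empty")
  dup <- family[duplicated(family)]
  if (length(dup)) stop("flora_table: duplicate family name(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(n_total) || anyNA(x_used)) stop("flora_table: counts must not be NA")
  if (any(n_total < 1)) stop("flora_table: n_total must be >= 1 for every family")
  if (any(x_used < 0)) {
    stop("flora_table: negative x_used for family ", family[which(x_used < 0)[1]])
  }
  bad <- which(x_used > n_total)
  if (length(bad)) {
    stop("flora_table: x_used exceeds n_total for family ", family[bad[1]])
  }
  out <- data.frame(family = family, n_total = n_total, x_used = x_used,
                    stringsAsFactors = FALSE)
  attr(out, "N_total") <- sum(n_total)
  attr(out, "X_total") <- sum(x_used)
  class(out) <- c("flora_table", "data.frame")
  out
}

as_flora_table <- function(x) {
  if (inherits(x, "flora_table")) return(x)
  if (is.data.frame(x) && all(c("family", "n_total", "x_used") %in% names(x))) {
    return(flora_table(x$family, x$n_total, x$x_used))
  }
  stop("cannot interpret input as a flora_table")
}

#' @export
print.flora_table <- function(x, ...) {
  cat(sprintf("<flora_table> %d families, N = %d native species, X = %d used\n",
              nrow(x), attr(x, "N_total"), attr(x, "X_total")))
  print(as.data.frame(utils::head(x, 10)), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more families\n")
  invisible(x)
}

#' Validate a count table
#'
#' Checks the structural invariants of a family count table without
#' modifying it and returns the violations as findings rather than raising
#' errors, so a whole file can be audited in one pass.
#'
#' @param table a `flora_table` or a data frame with columns `family`,
#'   `n_total`, `x_used` (and optionally stored totals as attributes).
#' @return A data frame with columns `code`, `family`, `message`; zero rows
#'   means the table is valid. Codes: `duplicate_family`, `bad_n`,
#'   `x_exceeds_n`, `negative_count`, `total_mismatch`.
#' @export
validate_table <- function(table) {
  findings <- data.frame(code = character(), family = character(),
                         message = character(), stringsAsFactors = FALSE)
  add <- function(code, family, message) {
    rbind(findings, data.frame(code = code, family = family, message = message,
                               stringsAsFactors = FALSE))
  }
  df <- as.data.frame(table)
  if (!all(c("family", "n_total", "x_used") %in% names(df))) {
    return(add("schema", NA_character_, "missing one of family, n_total, x_used"))
  }
  for (fam in unique(df$family[duplicated(df$family)])) {
    findings <- add("duplicate_family", fam, sprintf("family '%s' appears more than once", fam))
  }
  for (i in which(df$n_total < 1)) {
    findings <- add("bad_n", df$family[i], sprintf("family '%s' has n_total < 1", df$family[i]))
  }
  for (i in which(df$x_used < 0 | df$n_total < 0)) {
    findings <- add("negative_count", df$family[i], sprintf("family '%s' has a negative count", df$family[i]))
  }
  for (i in which(df$x_used > df$n_total)) {
    findings <- add("x_exceeds_n", df$family[i],
                    sprintf("family '%s' has x_used (%d) > n_total (%d)",
                            df$family[i], df$x_used[i], df$n_total[i]))
  }
  Ns <- attr(table, "N_total"); Xs <- attr(table, "X_total")
  if (!is.null(Ns) && Ns != sum(df$n_total)) {
    findings <- add("total_mismatch", NA_character_,
                    sprintf("stored N_total (%d) != sum of n_total (%d)", Ns, sum(df$n_total)))
  }
  if (!is.null(Xs) && Xs != sum(df$x_used)) {
    findings <- add("total_mismatch", NA_character_,
                    sprintf("stored X_total (%d) != sum of x_used (%d)", Xs, sum(df$x_used)))
  }
  findings
}

#' Read a family count table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row and columns
#' `family`, `n_total`, `x_used`. Totals are recomputed; invariant
#' violations are errors naming the offending family.
#'
#' @param path path to the CSV file.
#' @return A [flora_table()].
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("read_counts_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("family", "n_total", "x_used")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_counts_csv: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("read_counts_csv: no families in ", path)
  flora_table(df$family, df$n_total, df$x_used)
}

#' Write a family count table to CSV
#'
#' @param table a [flora_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(table, path) {
  table <- as_flora_table(table)
  utils::write.csv(as.data.frame(table)[, c("family", "n_total", "x_used")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

reference_path <- function() {
  system.file("extdata", "brazil_flora_reference.csv", package = "florabias",
              mustWork = TRUE)
}

#' Bundled reference dataset: wild food plants of the Brazilian flora
#'
#' Family-level counts of native angiosperm species and of species recorded
#' as wild food plants across 230 Brazilian families, together with the
#' published 7-decimal interval bounds and overuse/underuse status calls
#' for both models. The counts were compiled from a systematic review of
#' ethnobotanical checklists screened against the national flora; the
#' printed bounds were produced with a spreadsheet inverse-beta routine and
#' are reproduced verbatim, including a few taxonomically implausible
#' count rows, so that recomputation can be checked against them exactly.
#'
#' @param full if `FALSE` (default for [load_reference_counts()]) return
#'   only the counts; if `TRUE` also return the printed bounds and statuses
#'   (columns `bayes_lower`, `bayes_upper`, `status_bayes`, `idm_lower`,
#'   `idm_upper`, `status_idm`).
#' @return `load_reference_counts()`: a [flora_table()] with 230 families,
#'   N = 32740, X = 254. `load_reference_table()`: the same rows as a data
#'   frame including the printed reference columns.
#' @export
load_reference_counts <- function() {
  df <- utils::read.csv(reference_path(), stringsAsFactors = FALSE)
  flora_table(df$family, df$n_total, df$x_used)
}

#' @rdname load_reference_counts
#' @export
load_reference_table <- function(full = TRUE) {
  df <- utils::read.csv(reference_path(), stringsAsFactors = FALSE,
                        colClasses = c(bayes_lower = "character", bayes_upper = "character",
                                       idm_lower = "character", idm_upper = "character"))
  for (col in c("bayes_lower", "bayes_upper", "idm_lower", "idm_upper")) {
    df[[paste0(col, "_num")]] <- as.numeric(df[[col]])
  }
  df
}
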