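#' Classify family intervals against the overall-flora interval
#'
#' A family is overused when the lower bound of its interval strictly
#' exceeds the global upper bound, underused when its upper bound is
#' strictly below the global lower bound, and `ns` (not significant)
#' whenever the two intervals overlap, including exact ties. Comparisons
#' use the full-precision computed bounds.
#'
#' @param family_iv a [proportion_interval()] with one row per family.
#' @param global_iv a one-row [proportion_interval()] for the whole flora.
#' @return Character vector in `c("overused", "underused", "ns")`, one
#'   element per row of `family_iv`.
#' @export
classify_family <- function(family_iv, global_iv) {
  stopifnot(inherits(family_iv, "proportion_interval"),
            inherits(global_iv, "proportion_interval"),
            nrow(global_iv) == 1)
  if (!isTRUE(all.equal(attr(family_iv, "level"), attr(global_iv, "level")))) {
    stop("classify_family: family and global intervals must share the same level")
  }
  status <- rep("ns", nrow(family_iv))
  status[family_iv$lower > global_iv$upper] <- "overused"
  status[family_iv$upper < global_iv$lower] <- "underused"
  status
}

#' Analyze a flora for taxonomic selection bias
#'
#' Runs the full per-family analysis: computes both interval constructions
#' for every family, the overall-flora interval(s) under the configured
#' convention, and the over/under/ns status per model.
#'
#' @param table a [flora_table()] (or a data frame coercible to one).
#' @param config a [model_config()].
#' @return An object of class `flora_analysis`: a list with elements
#'   `results` (data frame: family, counts, bounds and status per model),
#'   `global_bayes` and `global_idm` (the comparison intervals),
#'   `summary` (per-model counts of overused/underused/ns) and `config`.
#' @export
#' @examples
#' fit <- analyze_flora(load_reference_counts())
#' fit$summary
analyze_flora <- function(table, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  table <- as_flora_table(table)
  findings <- validate_table(table)
  if (nrow(findings)) {
    stop("analyze_flora: invalid table: ", paste(findings$message, collapse = "; "))
  }
  biv <- bayes_interval(table$x_used, table$n_total,
                        level = config$level, scheme = config$bayes_scheme)
  iiv <- idm_interval(table$x_used, table$n_total,
                      s = config$idm_s, level = config$level)
  gb <- global_interval(table, "bayes", config)
  gi <- global_interval(table, "idm", config)
  results <- data.frame(
    family = table$family, n_total = table$n_total, x_used = table$x_used,
    bayes_lower = biv$lower, bayes_upper = biv$upper,
    status_bayes = classify_family(biv, gb),
    idm_lower = iiv$lower, idm_upper = iiv$upper,
    status_idm = classify_family(iiv, gi),
    stringsAsFactors = FALSE)
  lv <- c("overused", "underused", "ns")
  summary <- data.frame(
    model = c("bayes", "idm"),
    overused = c(sum(results$status_bayes == "overused"), sum(results$status_idm == "overused")),
    underused = c(sum(results$status_bayes == "underused"), sum(results$status_idm == "underused")),
    ns = c(sum(results$status_bayes == "ns"), sum(results$status_idm == "ns")),
    stringsAsFactors = FALSE)
  stopifnot(all(rowSums(summary[, lv[c(1, 2)]]) + summary$ns == nrow(results)))
  structure(list(results = results, global_bayes = gb, global_idm = gi,
                 summary = summary, config = config),
            class = "flora_analysis")
}

#' @export
print.flora_analysis <- function(x, ...) {
  cfg <- x$config
  cat("Taxonomic selection-bias analysis\n")
  cat(sprintf("  families: %d   level: %.3g   idm_s: %d   global convention: %s\n",
              nrow(x$results), cfg$level, cfg$idm_s, cfg$global_convention))
  if (cfg$global_convention == "per_model") {
    cat("  note: per-model global intervals in use; classifications near the\n")
    cat("  global bound may differ from the shared-interval convention\n")
  }
  cat(sprintf("  global interval (bayes column): [%.7f, %.7f]\n",
              x$global_bayes$lower, x$global_bayes$upper))
  cat(sprintf("  global interval (idm column):   [%.7f, %.7f]\n",
              x$global_idm$lower, x$global_idm$upper))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' List families on which the two models disagree
#'
#' @param results a `flora_analysis` or its `results` data frame.
#' @return Data frame with columns `family`, `status_bayes`, `status_idm`,
#'   one row per discordant family (zero rows when the models agree).
#' @export
compare_models <- function(results) {
  if (inherits(results, "flora_analysis")) results <- results$results
  stopifnot(all(c("family", "status_bayes", "status_idm") %in% names(results)))
  disc <- results[results$status_bayes != results$status_idm,
                  c("family", "status_bayes", "status_idm"), drop = FALSE]
  rownames(disc) <- NULL
  disc
}

# round-half-up at 7 decimals, matching the reference table's formatting
format_bound <- function(x) {
  sprintf("%.7f", floor(x * 1e7 + 0.5 + 1e-9) / 1e7)
}

#' Write analysis results to CSV
#'
#' Serializes the per-family results with bounds printed at 7 decimals
#' (round-half-up), mirroring the reference table layout.
#'
#' @param analysis a `flora_analysis` (or its `results` data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(analysis, path) {
  res <- if (inherits(analysis, "flora_analysis")) analysis$results else analysis
  out <- res
  for (col in c("bayes_lower", "bayes_upper", "idm_lower", "idm_upper")) {
    out[[col]] <- format_bound(res[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
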