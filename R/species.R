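#' Read a species-level checklist from CSV
#'
#' Schema (header mandatory): `scientific_name,family,origin,is_food_use,
#' source_ref`. `source_ref` may be absent and defaults to the empty
#' string. `origin` strings are lower-cased and mapped onto the controlled
#' vocabulary `native`, `naturalized`, `exotic`, `cultivated`; anything
#' else becomes `unknown`. `is_food_use` accepts TRUE/FALSE, 1/0, yes/no
#' (case-insensitive); anything else is an error reporting the row number.
#'
#' @param path path to the CSV file.
#' @return A data frame of species records with the five schema columns.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("read_species_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  need <- c("scientific_name", "family", "origin", "is_food_use")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_species_csv: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"source_ref" %in% names(df)) df$source_ref <- ""
  if (nrow(df) == 0) stop("read_species_csv: no records in ", path)
  bad_name <- which(!nzchar(trimws(df$scientific_name)) | !nzchar(trimws(df$family)))
  if (length(bad_name)) {
    stop("read_species_csv: empty scientific_name or family at data row ", bad_name[1])
  }
  origin <- tolower(trimws(df$origin))
  known <- c("native", "naturalized", "exotic", "cultivated")
  origin[!origin %in% known] <- "unknown"
  food_raw <- tolower(trimws(df$is_food_use))
  food <- rep(NA, nrow(df))
  food[food_raw %in% c("true", "t", "1", "yes", "y")] <- TRUE
  food[food_raw %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(food)) {
    stop("read_species_csv: unreadable is_food_use value at data row ", which(is.na(food))[1])
  }
  data.frame(scientific_name = df$scientific_name, family = df$family,
             origin = origin, is_food_use = food,
             source_ref = df$source_ref, stringsAsFactors = FALSE)
}

#' Write species records to CSV
#'
#' @param records data frame in the [read_species_csv()] schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(records, path) {
  need <- c("scientific_name", "family", "origin", "is_food_use", "source_ref")
  stopifnot(all(need %in% names(records)))
  utils::write.csv(records[, need], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

squeeze <- function(x) gsub("[[:space:]]+", " ", trimws(x))

title_case <- function(x) {
  x <- tolower(squeeze(x))
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Aggregate a species checklist into family counts
#'
#' Filters the checklist down to native species (naturalized, exotic,
#' cultivated and unknown-origin records are dropped), deduplicates on the
#' whitespace- and case-normalized scientific name, and counts per family
#' the distinct retained species and the distinct species flagged as used.
#' A species reported both with and without the food-use flag counts as
#' used: any positive report is taken as evidence of use. Family names are
#' compared case-insensitively after trimming and stored in title case.
#'
#' @param records a data frame of species records ([read_species_csv()]).
#' @return A [flora_table()], families in alphabetical order.
#' @export
aggregate_species <- function(records) {
  need <- c("scientific_name", "family", "origin", "is_food_use")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("aggregate_species: records must contain ", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0) stop("aggregate_species: empty record set")
  native <- records[records$origin == "native", , drop = FALSE]
  if (nrow(native) == 0) stop("aggregate_species: no native records after filtering")
  key <- tolower(squeeze(native$scientific_name))
  fam <- title_case(native$family)
  # per-species rollup: family of first mention, food flag = any mention
  used <- tapply(native$is_food_use, key, any)
  fam_of <- tapply(fam, key, function(f) f[1])
  species <- names(used)
  per_family_n <- table(fam_of[species])
  per_family_x <- tapply(as.logical(used[species]), fam_of[species], sum)
  fams <- sort(names(per_family_n))
  flora_table(fams,
              as.integer(per_family_n[fams]),
              as.integer(per_family_x[fams]))
}

#' Expand a count table back into one record per counted species
#'
#' Inverse of [aggregate_species()] up to synthetic species names: each
#' family contributes `n_total` native records of which the first `x_used`
#' carry the food-use flag. Useful for round-trip checks of the
#' aggregation semantics.
#'
#' @param table a [flora_table()].
#' @return A data frame of species records.
#' @export
expand_counts <- function(table) {
  table <- as_flora_table(table)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    n <- table$n_total[i]; x <- table$x_used[i]
    data.frame(scientific_name = sprintf("%s sp%d", tolower(table$family[i]), seq_len(n)),
               family = table$family[i], origin = "native",
               is_food_use = seq_len(n) <= x, source_ref = "synthetic",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
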