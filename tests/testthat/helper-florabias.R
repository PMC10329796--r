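# Independent oracle for beta quantiles: bisection over a numerically
# integrated beta density. Deliberately avoids qbeta/pbeta so it can serve
# as a cross-check of the package's quantile path.
oracle_beta_cdf <- function(q, a, b) {
  if (q <= 0) return(0)
  if (q >= 1) return(1)
  dens <- function(t) exp((a - 1) * log(t) + (b - 1) * log1p(-t) - lbeta(a, b))
  stats::integrate(dens, 0, q, rel.tol = 1e-13, abs.tol = 1e-13,
                   subdivisions = 2000L)$value
}

oracle_beta_quantile <- function(p, a, b, tol = 1e-12) {
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (oracle_beta_cdf(mid, a, b) < p) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Brute-force set-based recount of a species checklist (aggregation oracle)
oracle_aggregate <- function(records) {
  nat <- records[records$origin == "native", ]
  key <- tolower(gsub("[[:space:]]+", " ", trimws(nat$scientific_name)))
  fam_raw <- tolower(gsub("[[:space:]]+", " ", trimws(nat$family)))
  fam <- paste0(toupper(substr(fam_raw, 1, 1)), substr(fam_raw, 2, nchar(fam_raw)))
  species <- unique(key)
  out_fam <- character(); out_n <- integer(); out_x <- integer()
  for (f in sort(unique(fam[match(species, key)]))) {
    sp_f <- species[fam[match(species, key)] == f]
    used <- vapply(sp_f, function(s) any(nat$is_food_use[key == s]), NA)
    out_fam <- c(out_fam, f); out_n <- c(out_n, length(sp_f)); out_x <- c(out_x, sum(used))
  }
  data.frame(family = out_fam, n_total = out_n, x_used = out_x,
             stringsAsFactors = FALSE)
}

random_species_records <- function(n, n_families = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- paste0("Fam", seq_len(n_families), "aceae")
  data.frame(
    scientific_name = sprintf("Genus%d species%d",
                              sample(1:8, n, TRUE), sample(1:12, n, TRUE)),
    family = sample(fams, n, TRUE),
    origin = sample(c("native", "native", "native", "exotic", "cultivated",
                      "naturalized", "unknown"), n, TRUE),
    is_food_use = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.3, 0.7)),
    source_ref = sample(c("", "ref1", "ref2"), n, TRUE),
    stringsAsFactors = FALSE)
}

random_flora_table <- function(n_families = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- pmax(1L, as.integer(rlnorm(n_families, 2.5, 1.5)))
  x <- rbinom(n_families, n, runif(n_families, 0, 0.2))
  flora_table(sprintf("Fam%03d", seq_len(n_families)), n, x)
}

# independent 7-decimal round-half-up formatter for output checks
format_bound_chk <- function(x) sprintf("%.7f", floor(x * 1e7 + 0.5 + 1e-9) / 1e7)
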