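#' Configuration for synthetic floras
#'
#' Describes a generative model for floras with a known degree of
#' taxonomic selection bias. Family sizes follow a heavy-tailed
#' distribution (discrete power law by default, mimicking real floras
#' where a few families hold thousands of species and many are
#' monotypic). Each family is independently labelled over/under/neutral;
#' its true use proportion is `theta_base` times the corresponding effect
#' multiplier, and the used-species count is a binomial draw.
#'
#' @param n_families number of families.
#' @param size_dist `"zipf"` (discrete power law on `size_min:size_cap`)
#'   or `"lognormal"`.
#' @param zipf_exponent power-law exponent (default 1.5).
#' @param size_cap maximum family size (default 3000).
#' @param size_min minimum family size (default 1).
#' @param lnorm_mu,lnorm_sigma log-scale parameters for the lognormal
#'   alternative (defaults 2 and 1.5; sizes are rounded up and clamped to
#'   `[size_min, size_cap]`).
#' @param theta_base baseline use proportion (default 0.008, the order of
#'   magnitude seen in national-flora food-use data).
#' @param frac_over,frac_under expected fractions of over- and
#'   under-selected families (defaults 0.05 each).
#' @param effect_over multiplier > 1 applied to `theta_base` for
#'   over-selected families (default 10).
#' @param effect_under multiplier in `[0, 1)` for under-selected families
#'   (default 0).
#' @param seed master seed; every family uses its own substream derived
#'   from `(seed, family index)` so that growing `n_families` leaves the
#'   draws of existing families unchanged.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 200,
                              size_dist = c("zipf", "lognormal"),
                              zipf_exponent = 1.5, size_cap = 3000, size_min = 1,
                              lnorm_mu = 2, lnorm_sigma = 1.5,
                              theta_base = 0.008,
                              frac_over = 0.05, frac_under = 0.05,
                              effect_over = 10, effect_under = 0,
                              seed = 1) {
  size_dist <- match.arg(size_dist)
  if (n_families < 1) stop("simulation_config: n_families must be >= 1")
  if (zipf_exponent <= 0) stop("simulation_config: zipf_exponent must be positive")
  if (size_min < 1 || size_cap < size_min) {
    stop("simulation_config: require 1 <= size_min <= size_cap")
  }
  if (lnorm_sigma <= 0) stop("simulation_config: lnorm_sigma must be positive")
  if (theta_base <= 0 || theta_base >= 1) stop("simulation_config: theta_base must be in (0, 1)")
  if (frac_over < 0 || frac_under < 0 || frac_over + frac_under > 1) {
    stop("simulation_config: require frac_over + frac_under <= 1")
  }
  if (effect_over < 1) stop("simulation_config: effect_over must be >= 1")
  if (effect_under < 0 || effect_under >= 1) stop("simulation_config: effect_under must be in [0, 1)")
  if (theta_base * effect_over > 1) stop("simulation_config: theta_base * effect_over must be <= 1")
  structure(list(n_families = as.integer(n_families), size_dist = size_dist,
                 zipf_exponent = zipf_exponent, size_cap = as.integer(size_cap),
                 size_min = as.integer(size_min),
                 lnorm_mu = lnorm_mu, lnorm_sigma = lnorm_sigma,
                 theta_base = theta_base, frac_over = frac_over,
                 frac_under = frac_under, effect_over = effect_over,
                 effect_under = effect_under, seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic 32-bit substream seed for family i under master seed
substream_seed <- function(seed, i) {
  (as.double(seed %% 1000003L) * 2654435.0 + as.double(i) * 97.0) %% 2147483629
}

draw_size <- function(config) {
  if (config$size_dist == "zipf") {
    support <- config$size_min:config$size_cap
    sample(support, 1, prob = support^(-config$zipf_exponent))
  } else {
    sz <- ceiling(stats::rlnorm(1, config$lnorm_mu, config$lnorm_sigma))
    min(max(sz, config$size_min), config$size_cap)
  }
}

#' Simulate a flora with known selection bias
#'
#' @param config a [simulation_config()].
#' @return A list with elements `table` (a [flora_table()]) and `truth`
#'   (data frame: `family`, `n_total`, `theta_true`,
#'   `label` in over/under/neutral).
#' @export
#' @examples
#' sim <- simulate_flora(simulation_config(n_families = 50, seed = 42))
#' sim$table
simulate_flora <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_families
  fam <- sprintf("Fam%04d", seq_len(k))
  n <- integer(k); x <- integer(k)
  theta <- numeric(k); label <- character(k)
  for (i in seq_len(k)) {
    set.seed(substream_seed(config$seed, i))
    n[i] <- draw_size(config)
    u <- stats::runif(1)
    label[i] <- if (u < config$frac_over) "over"
      else if (u < config$frac_over + config$frac_under) "under"
      else "neutral"
    theta[i] <- config$theta_base * switch(label[i],
                                           over = config$effect_over,
                                           under = config$effect_under,
                                           neutral = 1)
    x[i] <- stats::rbinom(1, n[i], theta[i])
  }
  list(table = flora_table(fam, n, x),
       truth = data.frame(family = fam, n_total = n, theta_true = theta,
                          label = label, stringsAsFactors = FALSE))
}

#' Detection metrics against simulation ground truth
#'
#' Cross-tabulates the classifier's calls with the generative labels.
#' Sensitivity is computed within the truly over- (resp. under-) selected
#' families; the false positive rate is the fraction of neutral families
#' flagged in either direction. Rates whose denominator is zero are
#' reported as `NA`.
#'
#' @param results a `flora_analysis` or its `results` data frame.
#' @param truth the `truth` component of [simulate_flora()].
#' @return Data frame with one row per model and columns
#'   `sensitivity_over`, `sensitivity_under`, `false_positive_rate`,
#'   `n_over`, `n_under`, `n_neutral`.
#' @export
detection_metrics <- function(results, truth) {
  if (inherits(results, "flora_analysis")) results <- results$results
  if (!setequal(results$family, truth$family) ||
      nrow(results) != nrow(truth)) {
    stop("detection_metrics: results and truth must cover the same family set")
  }
  truth <- truth[match(results$family, truth$family), ]
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  one_model <- function(status) {
    over <- truth$label == "over"; under <- truth$label == "under"
    neutral <- truth$label == "neutral"
    data.frame(
      sensitivity_over = rate(sum(status[over] == "overused"), sum(over)),
      sensitivity_under = rate(sum(status[under] == "underused"), sum(under)),
      false_positive_rate = rate(sum(status[neutral] != "ns"), sum(neutral)),
      n_over = sum(over), n_under = sum(under), n_neutral = sum(neutral))
  }
  out <- rbind(one_model(results$status_bayes), one_model(results$status_idm))
  cbind(model = c("bayes", "idm"), out, stringsAsFactors = FALSE)
}

#' Empirical coverage of the interval constructions
#'
#' Repeatedly draws `x ~ Binomial(n, theta)` and records how often each
#' model's interval contains `theta`. The exceedance-pair construction is
#' exact-conservative, so its empirical coverage should sit at or above
#' the nominal level; the IDM interval nests it and can only do better.
#'
#' @param n number of species per replicate.
#' @param theta true use proportion.
#' @param reps number of replicates (>= 1000 recommended).
#' @param level two-sided level.
#' @param idm_s IDM imprecision parameter.
#' @param seed RNG seed.
#' @return Named numeric vector with elements `bayes` and `idm`.
#' @export
coverage_experiment <- function(n, theta, reps = 10000, level = 0.95,
                                idm_s = 4, seed = 1) {
  if (reps < 1) stop("coverage_experiment: reps must be >= 1")
  set.seed(seed)
  x <- stats::rbinom(reps, n, theta)
  biv <- bayes_interval(x, n, level = level)
  iiv <- idm_interval(x, n, s = idm_s, level = level)
  c(bayes = mean(biv$lower <= theta & theta <= biv$upper),
    idm = mean(iiv$lower <= theta & theta <= iiv$upper))
}

#' Read a simulation configuration from a key = value file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys are the
#' arguments of [simulation_config()]; unknown keys are an error.
#'
#' @param path path to the config file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("read_simulation_config: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")), "")
  allowed <- names(formals(simulation_config))
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("read_simulation_config: unknown key(s): ", paste(bad, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- setdiff(allowed, "size_dist")
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  do.call(simulation_config, args)
}
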