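#' Beta distribution quantile with point-mass conventions
#'
#' Inverse of the regularized incomplete beta function, extended to the
#' degenerate shapes that arise when a binomial count sits on the boundary
#' of its support: `a = 0` is treated as a point mass at 0 (quantile 0) and
#' `b = 0` as a point mass at 1 (quantile 1). This mirrors the convention
#' spreadsheets use when tabulating exceedance bounds for x = 0 or x = n.
#'
#' @param p probability (or vector of probabilities), strictly inside (0, 1).
#' @param a,b non-negative shape parameters; not both zero. Recycled against
#'   `p` in the usual way.
#' @return Numeric vector of quantiles in \[0, 1\].
#' @seealso [bayes_interval()], [idm_interval()]
#' @export
#' @examples
#' beta_quantile(0.975, 1, 1)   # uniform: 0.975
#' beta_quantile(0.025, 2, 1)   # sqrt(0.025)
#' beta_quantile(0.5, 0, 3)     # point mass at 0
beta_quantile <- function(p, a, b) {
  if (!is.numeric(p) || !is.numeric(a) || !is.numeric(b)) {
    stop("beta_quantile: p, a, b must be numeric")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("beta_quantile: p must lie strictly in (0, 1)")
  }
  if (any(a < 0) || any(b < 0)) {
    stop("beta_quantile: shape parameters must be non-negative")
  }
  n <- max(length(p), length(a), length(b))
  p <- rep_len(p, n); a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(a == 0 & b == 0)) {
    stop("beta_quantile: a and b cannot both be zero")
  }
  out <- numeric(n)
  zero <- a == 0
  one <- b == 0
  reg <- !zero & !one
  out[zero] <- 0
  out[one] <- 1
  out[reg] <- stats::qbeta(p[reg], a[reg], b[reg])
  out
}

#' Construct a proportion interval object
#'
#' A thin data-frame wrapper holding lower/upper bounds for one or more use
#' proportions, together with the two-sided level and the model that
#' produced them.
#'
#' @param lower,upper numeric vectors of bounds in \[0, 1\].
#' @param level two-sided credibility/confidence level in (0, 1).
#' @param model `"bayes"` or `"idm"`.
#' @return A data frame of class `proportion_interval` with columns
#'   `lower` and `upper` and attributes `level` and `model`.
#' @export
proportion_interval <- function(lower, upper, level, model = c("bayes", "idm")) {
  model <- match.arg(model)
  if (length(lower) != length(upper)) {
    stop("proportion_interval: lower and upper must have equal length")
  }
  if (any(lower < -1e-12) || any(upper > 1 + 1e-12) || any(lower > upper + 1e-12)) {
    stop("proportion_interval: require 0 <= lower <= upper <= 1")
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("proportion_interval: level must be a single probability in (0, 1)")
  }
  out <- data.frame(lower = pmin(pmax(lower, 0), 1),
                    upper = pmin(pmax(upper, 0), 1))
  attr(out, "level") <- level
  attr(out, "model") <- model
  class(out) <- c("proportion_interval", "data.frame")
  out
}

#' @export
print.proportion_interval <- function(x, ...) {
  cat(sprintf("<proportion_interval> model=%s level=%.3g\n",
              attr(x, "model"), attr(x, "level")))
  print(data.frame(lower = x$lower, upper = x$upper), ...)
  invisible(x)
}

#' Exceedance-pair ("Bayesian") interval for a use proportion
#'
#' Two-sided interval for the proportion underlying `x` uses out of `n`
#' species. The default `scheme = "exceedance"` takes the lower bound from
#' the quantile of Beta(x, n - x + 1) and the upper bound from
#' Beta(x + 1, n - x) — the pair of posteriors whose tail probabilities
#' bracket the observed count, algebraically identical to the exact
#' Clopper–Pearson construction. `scheme = "posterior"` instead takes both
#' bounds from the single flat-prior posterior Beta(x + 1, n - x + 1); it is
#' offered for methodological comparison and is not used by the reference
#' analysis.
#'
#' Boundary counts give exact degenerate bounds: `x = 0` has lower bound 0
#' and `x = n` has upper bound 1.
#'
#' @param x number of used species (vectorized).
#' @param n number of species (vectorized, recycled against `x`).
#' @param level two-sided level; bounds are the (1-level)/2 and (1+level)/2
#'   quantiles. Default 0.95.
#' @param scheme `"exceedance"` (default) or `"posterior"`.
#' @return A [proportion_interval()] with `model = "bayes"`.
#' @export
#' @examples
#' bayes_interval(27, 300)          # a well-sampled family
#' bayes_interval(0, 1)             # upper bound 0.975
bayes_interval <- function(x, n, level = 0.95, scheme = c("exceedance", "posterior")) {
  scheme <- match.arg(scheme)
  check_counts(x, n)
  m <- max(length(x), length(n))
  x <- rep_len(x, m); n <- rep_len(n, m)
  a1 <- (1 - level) / 2
  if (scheme == "exceedance") {
    lower <- beta_quantile(a1, x, n - x + 1)
    upper <- beta_quantile(1 - a1, x + 1, n - x)
  } else {
    lower <- beta_quantile(a1, x + 1, n - x + 1)
    upper <- beta_quantile(1 - a1, x + 1, n - x + 1)
  }
  proportion_interval(lower, upper, level, "bayes")
}

#' Imprecise Dirichlet Model interval for a use proportion
#'
#' Widens the exceedance-pair construction by the IDM imprecision parameter
#' `s`: the lower bound comes from Beta(x, n - x + s) and the upper from
#' Beta(x + s, n - x). At `s = 1` this coincides with [bayes_interval()];
#' larger `s` expresses more prior imprecision (here about both the used
#' and the total count) and yields strictly nested, more conservative
#' intervals. The reference analysis uses `s = 4`.
#'
#' @inheritParams bayes_interval
#' @param s positive integer imprecision parameter (default 4).
#' @return A [proportion_interval()] with `model = "idm"`.
#' @export
#' @examples
#' idm_interval(2, 3)               # wider than bayes_interval(2, 3)
#' all.equal(unclass(idm_interval(5, 40, s = 1)),
#'           unclass(bayes_interval(5, 40)), check.attributes = FALSE)
idm_interval <- function(x, n, s = 4, level = 0.95) {
  if (!is.numeric(s) || length(s) != 1 || s < 1 || s != round(s)) {
    stop("idm_interval: s must be a positive integer")
  }
  check_counts(x, n)
  m <- max(length(x), length(n))
  x <- rep_len(x, m); n <- rep_len(n, m)
  a1 <- (1 - level) / 2
  lower <- beta_quantile(a1, x, n - x + s)
  upper <- beta_quantile(1 - a1, x + s, n - x)
  proportion_interval(lower, upper, level, "idm")
}

check_counts <- function(x, n) {
  if (any(!is.finite(x)) || any(!is.finite(n))) stop("counts must be finite")
  if (any(x != round(x)) || any(n != round(n))) stop("counts must be integers")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(x < 0)) stop("x must be >= 0")
  if (any(x > n)) stop("x must not exceed n")
  invisible(TRUE)
}

#' Model configuration
#'
#' Bundles the tunable parameters of the analysis: the two-sided level, the
#' IDM imprecision parameter, the convention for the overall-flora interval
#' and the Bayesian bound scheme.
#'
#' `global_convention = "shared"` (the default) computes one overall-flora
#' interval with the IDM form at `idm_s` and compares both model columns
#' against it; this reproduces the reference table, whose printed total row
#' is identical for both models. `"per_model"` computes each model's own
#' global interval, which is the more principled choice but changes the
#' classification of families sitting very close to the global bound.
#'
#' @param level two-sided level in (0, 1); default 0.95.
#' @param idm_s positive integer IDM imprecision parameter; default 4.
#' @param global_convention `"shared"` or `"per_model"`.
#' @param bayes_scheme passed to [bayes_interval()].
#' @return A list of class `model_config`.
#' @export
model_config <- function(level = 0.95, idm_s = 4,
                         global_convention = c("shared", "per_model"),
                         bayes_scheme = c("exceedance", "posterior")) {
  global_convention <- match.arg(global_convention)
  bayes_scheme <- match.arg(bayes_scheme)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("model_config: level must be in (0, 1)")
  }
  if (!is.numeric(idm_s) || length(idm_s) != 1 || idm_s < 1 || idm_s != round(idm_s)) {
    stop("model_config: idm_s must be a positive integer")
  }
  structure(list(level = level, idm_s = as.integer(idm_s),
                 global_convention = global_convention,
                 bayes_scheme = bayes_scheme),
            class = "model_config")
}

#' Overall-flora interval
#'
#' Interval for the flora-wide use proportion built from the table totals
#' (X used species out of N), under the convention in `config` (see
#' [model_config()]).
#'
#' @param table a [flora_table()].
#' @param model `"bayes"` or `"idm"` — which model column the interval will
#'   be compared against.
#' @param config a [model_config()].
#' @return A one-row [proportion_interval()].
#' @export
global_interval <- function(table, model = c("bayes", "idm"), config = model_config()) {
  model <- match.arg(model)
  stopifnot(inherits(config, "model_config"))
  table <- as_flora_table(table)
  X <- attr(table, "X_total"); N <- attr(table, "N_total")
  if (config$global_convention == "shared" || model == "idm") {
    iv <- idm_interval(X, N, s = config$idm_s, level = config$level)
  } else {
    iv <- bayes_interval(X, N, level = config$level, scheme = config$bayes_scheme)
  }
  attr(iv, "model") <- model
  iv
}
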