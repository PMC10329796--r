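test_that("simulation_config validates its parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(frac_over = 0.7, frac_under = 0.5), "<= 1")
  expect_error(simulation_config(effect_over = 200, theta_base = 0.008), "<= 1")
  expect_error(simulation_config(effect_under = 1), "effect_under")
  expect_error(simulation_config(size_min = 10, size_cap = 5), "size_min")
})

test_that("simulate_flora is reproducible and respects its bounds", {
  cfg <- simulation_config(n_families = 80, seed = 42)
  a <- simulate_flora(cfg)
  b <- simulate_flora(cfg)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth, b$truth)
  expect_true(all(a$table$n_total >= 1 & a$table$n_total <= cfg$size_cap))
  expect_true(all(a$table$x_used <= a$table$n_total))
  expect_true(all(a$truth$label %in% c("over", "under", "neutral")))
  neutral <- a$truth$label == "neutral"
  expect_true(all(a$truth$theta_true[neutral] == cfg$theta_base))
})

test_that("per-family substreams survive growing the flora", {
  small <- simulate_flora(simulation_config(n_families = 40, seed = 9))
  big <- simulate_flora(simulation_config(n_families = 60, seed = 9))
  expect_identical(big$table$family[1:40], small$table$family)
  expect_identical(big$table$n_total[1:40], small$table$n_total)
  expect_identical(big$table$x_used[1:40], small$table$x_used)
  expect_identical(big$truth[1:40, ], small$truth)
})

test_that("null flora realizes the baseline proportion", {
  cfg <- simulation_config(n_families = 200, frac_over = 0, frac_under = 0,
                           theta_base = 0.008, seed = 5)
  sim <- simulate_flora(cfg)
  N <- attr(sim$table, "N_total"); X <- attr(sim$table, "X_total")
  se <- sqrt(0.008 * 0.992 / N)
  expect_lt(abs(X / N - 0.008), 3 * se)
  expect_true(all(sim$truth$label == "neutral"))
})

test_that("detection_metrics matches a hand-computed confusion table", {
  results <- data.frame(
    family = c("A", "B", "C", "D"),
    status_bayes = c("overused", "ns", "underused", "overused"),
    status_idm = c("ns", "ns", "ns", "overused"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    family = c("A", "B", "C", "D"),
    theta_true = c(0.1, 0.008, 0.001, 0.1),
    label = c("over", "neutral", "neutral", "over"),
    stringsAsFactors = FALSE)
  m <- detection_metrics(results, truth)
  expect_equal(m$sensitivity_over, c(1, 0.5))
  expect_true(all(is.na(m$sensitivity_under)))
  expect_equal(m$false_positive_rate, c(0.5, 0))

  expect_error(detection_metrics(results, truth[1:3, ]), "family set")
})

test_that("all-neutral truth with all-ns results gives zero FPR", {
  results <- data.frame(family = c("A", "B"), status_bayes = "ns",
                        status_idm = "ns", stringsAsFactors = FALSE)
  truth <- data.frame(family = c("A", "B"), theta_true = 0.008,
                      label = "neutral", stringsAsFactors = FALSE)
  m <- detection_metrics(results, truth)
  expect_equal(m$false_positive_rate, c(0, 0))
  expect_true(all(is.na(m$sensitivity_over)))
})

test_that("interval midpoints recover theta for very large families", {
  cfg <- simulation_config(n_families = 30, size_min = 20000, size_cap = 30000,
                           theta_base = 0.01, frac_over = 0.2, frac_under = 0.2,
                           effect_over = 3, effect_under = 0.2, seed = 77)
  sim <- simulate_flora(cfg)
  fit <- analyze_flora(sim$table)
  mid <- (fit$results$bayes_lower + fit$results$bayes_upper) / 2
  expect_true(all(abs(mid - sim$truth$theta_true) < 0.005))
})

test_that("coverage is exactly 1 when theta = 0", {
  cov <- coverage_experiment(n = 40, theta = 0, reps = 1000, seed = 3)
  expect_equal(cov[["bayes"]], 1)
  expect_equal(cov[["idm"]], 1)
})

test_that("power grows with effect size and family size", {
  # common random numbers across the grid; a large neutral backdrop so the
  # over-selected block cannot dominate the flora-wide interval
  set.seed(321)
  theta0 <- 0.008
  u_back <- runif(200)
  backdrop <- flora_table(sprintf("Neut%03d", 1:200), rep(2000L, 200),
                          qbinom(u_back, 2000, theta0))
  u <- runif(20)
  effects <- c(3, 10, 30); sizes <- c(50, 300, 1500)
  sens <- matrix(NA_real_, 3, 3)
  for (i in seq_along(effects)) for (j in seq_along(sizes)) {
    x <- qbinom(u, sizes[j], theta0 * effects[i])
    tab <- flora_table(c(backdrop$family, sprintf("Over%02d", seq_along(u))),
                       c(backdrop$n_total, rep(sizes[j], length(u))),
                       c(backdrop$x_used, x))
    fit <- analyze_flora(tab)
    st <- fit$results$status_bayes[grepl("^Over", fit$results$family)]
    sens[i, j] <- mean(st == "overused")
  }
  for (j in 1:3) expect_true(all(diff(sens[, j]) >= -1e-12))
  for (i in 1:3) expect_true(all(diff(sens[i, ]) >= -1e-12))
  expect_gt(sens[3, 3], 0.9)
})

test_that("simulation config files round-trip through the key = value format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# power run", "n_families = 60", "size_dist = zipf",
               "theta_base = 0.008", "frac_over = 0.1", "effect_over = 15",
               "size_min = 300", "seed = 4"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_families, 60L)
  expect_equal(cfg$effect_over, 15)
  expect_equal(cfg$size_min, 300L)

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("nonsense = 3", bad)
  expect_error(read_simulation_config(bad), "unknown key")
})
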