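test_that("interval F1 matches its definition on the canonical cases", {
  expect_equal(f1_interval(c(5, 75), c(5, 75)), 1)
  expect_equal(f1_interval(c(0, 10), c(20, 30)), 0)
  # half-overlap: TP = FP = FN = 50
  expect_equal(f1_interval(c(50, 150), c(0, 100)), 0.5)
  expect_error(f1_interval(c(0, 10), c(5, 5)), "zero-length")
})

test_that("interval F1 is symmetric, translation-invariant and peaks at identity", {
  withr::with_seed(17, {
    for (i in 1:25) {
      a <- sort(runif(2, 0, 300)); b <- sort(runif(2, 0, 300))
      if (diff(a) == 0 || diff(b) == 0) next
      expect_equal(f1_interval(a, b), f1_interval(b, a))
      sh <- runif(1, -100, 100)
      expect_equal(f1_interval(a + sh, b + sh), f1_interval(a, b))
      expect_lte(f1_interval(a, b), 1)
      expect_equal(f1_interval(b, b), 1)
    }
  })
  # F1 strictly decreases as a fixed-length window slides away from truth
  f1s <- vapply(seq(0, 60, by = 10),
                function(s) f1_interval(c(10, 90) + s, c(10, 90)), numeric(1))
  expect_true(all(diff(f1s) < 0))
})

test_that("profile correlation reproduces the Pearson formula", {
  x <- c(0.1, 0.5, 0.9, 0.4, 0.2)
  y <- c(0.15, 0.42, 1.1, 0.38, 0.33)
  # textbook product-moment formula, computed directly
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(profile_correlation(x, y), r_hand, tolerance = 1e-12)
  expect_equal(profile_correlation(x, x), 1)
  expect_equal(profile_correlation(x, -2 * x + 1), -1)
  expect_error(profile_correlation(x, rep(1, 5)), "constant")
  expect_error(profile_correlation(x[1:2], y[1:2]), "at least 3")
})

test_that("profile correlation interpolates curves onto a common grid", {
  fine <- tibble::tibble(isi = seq(0, 100, 1),
                         mep = exp(-(seq(0, 100, 1) - 50)^2 / 400))
  coarse <- tibble::tibble(isi = seq(0, 100, 10),
                           mep = exp(-(seq(0, 100, 10) - 50)^2 / 400))
  expect_equal(profile_correlation(fine, coarse), 1, tolerance = 1e-6)
})

test_that("the Shapiro-Wilk wrapper reproduces reference values", {
  # reference (W, p) computed with an independent implementation
  x <- c(4.1, 5.2, 6.3, 4.8, 5.9, 5.1, 4.4, 6.8, 5.5, 5.0, 4.7, 6.1)
  res <- shapiro_wilk(x)
  expect_equal(round(res$statistic, 3), 0.973)
  expect_equal(round(res$p_value, 3), 0.942)
  expect_true(res$normal)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("the normality screen keeps its nominal type-I behaviour", {
  withr::with_seed(33, {
    keep <- vapply(1:100, function(i) shapiro_wilk(rnorm(5000))$normal, logical(1))
  })
  expect_gte(mean(keep), 0.9)
})

test_that("convergence percentage is a plain flag average", {
  expect_equal(convergence_percentage(c(TRUE, TRUE, TRUE)), 100)
  expect_equal(convergence_percentage(c(TRUE, TRUE, TRUE, FALSE)), 75)
  fake <- list(list(converged = TRUE), list(converged = FALSE))
  expect_equal(convergence_percentage(fake), 50)
  expect_error(convergence_percentage(logical(0)), "empty")
})

test_that("a noiseless population benchmarks at F1 ~ 1 with full convergence", {
  rep <- run_benchmark(population_params(noise_cv = 0), methods = "NR",
                       n_ini_values = 7, accelerometer = TRUE,
                       n_subjects = 3, seed = 2)
  expect_equal(nrow(rep), 1)
  expect_gte(rep$mean_f1, 0.97)
  expect_equal(rep$convergence_pct, 100)
})

test_that("benchmark reports are reproducible and flag unavailable NR cells", {
  pop <- population_params()
  r1 <- run_benchmark(pop, methods = c("NR", "SVMR"), n_ini_values = c(3, 7),
                      accelerometer = TRUE, n_subjects = 2, seed = 5)
  r2 <- run_benchmark(pop, methods = c("NR", "SVMR"), n_ini_values = c(3, 7),
                      accelerometer = TRUE, n_subjects = 2, seed = 5)
  expect_equal(tibble::as_tibble(unclass(r1)), tibble::as_tibble(unclass(r2)))
  nr3 <- dplyr::filter(r1, method == "NR", n_ini == 3)
  expect_false(nr3$available)
  expect_true(all(dplyr::filter(r1, method == "SVMR")$available))
  # convergence column equals a recount of the per-run flags
  r3 <- run_benchmark(pop, methods = "SVMR", n_ini_values = 7,
                      accelerometer = TRUE, n_subjects = 4, seed = 6,
                      keep_runs = TRUE)
  runs <- attr(r3, "runs")[[1]]
  expect_equal(r3$convergence_pct,
               100 * mean(vapply(runs, function(r) r$converged, logical(1))))
})

test_that("narrowing the search range does not inflate the observation budget", {
  # accelerometer mode (range starts at the impact) vs valve-referenced mode:
  # the trend over a population, mirroring the reported reduction direction
  pop <- population_params()
  subs <- lapply(1:50, function(i) sample_subject(pop, 500 + i))
  nobs <- vapply(seq_along(subs), function(i) {
    acc <- estimate_isi_window(
      subs[[i]], quick_config("NR", n_ini = 6, seed = 700 + i))$n_observations
    valve <- estimate_isi_window(
      subs[[i]], estimator_config("NR", n_ini = 6,
                                  search_lower = -subs[[i]]$t_delay,
                                  search_upper = 304.5, seed = 700 + i),
      valve_referenced = TRUE)$n_observations
    c(acc, valve)
  }, numeric(2))
  expect_lte(mean(nobs[1, ]), mean(nobs[2, ]))
})

test_that("GPR window-end errors stay within two grid steps on noisy subjects", {
  pop <- population_params()
  errs <- unlist(lapply(1:50, function(i) {
    s <- sample_subject(pop, 500 + i)
    est <- estimate_isi_window(s, quick_config("GPR", n_ini = 7, seed = 600 + i))
    c(abs(est$window$lower - s$true_window$lower),
      abs(est$window$upper - s$true_window$upper))
  }))
  expect_lte(median(errs), 10)
})
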