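test_that("the stopping rule fires on stable ends and on the iteration cap", {
  cfg <- quick_config("NR", n_ini = 4)
  hist0 <- tibble::tibble(iteration = 1:5, lower = rep(30, 5), upper = rep(100, 5))
  expect_true(check_stopping(hist0, cfg))
  # drifting lower ends: sample variance 1000 >= 50
  hist1 <- tibble::tibble(iteration = 1:5, lower = c(0, 20, 40, 60, 80),
                          upper = rep(100, 5))
  expect_equal(var(c(0, 20, 40, 60, 80)), 1000)
  expect_false(check_stopping(hist1, cfg, iteration = 5))
  # too little history
  hist2 <- tibble::tibble(iteration = 1:4, lower = rep(30, 4), upper = rep(100, 4))
  expect_false(check_stopping(hist2, cfg, iteration = 4))
  # iteration cap dominates regardless of history
  expect_true(check_stopping(hist2, cfg, iteration = cfg$max_iterations))
})

test_that("boundary-refining acquisition alternates the window ends", {
  cfg <- quick_config("NR", n_ini = 4)
  state <- list(window = isiw_window(30, 90),
                observations = tibble::tibble(isi = c(0, 100, 200, 300)),
                last_end = "lower", gp = NULL)
  acq <- acquire_next_isi(state, cfg)
  expect_equal(acq$isi, 90)
  expect_equal(acq$last_end, "upper")
  acq2 <- acquire_next_isi(modifyList(state, list(last_end = "upper")), cfg)
  expect_equal(acq2$isi, 30)
  # ends are snapped to the grid and clipped to the range
  state3 <- modifyList(state, list(window = isiw_window(-20, 92.6),
                                   last_end = "lower"))
  expect_equal(acquire_next_isi(state3, cfg)$isi, 95)
})

test_that("acquisition falls back to the least-explored grid ISI without a window", {
  cfg <- quick_config("SVMR", n_ini = 2)
  state <- list(window = NULL,
                observations = tibble::tibble(isi = c(0, 304.5)),
                last_end = NA, gp = NULL)
  isi <- acquire_next_isi(state, cfg)$isi
  grid <- seq(0, 304.5, by = 5)
  d <- vapply(grid, function(g) min(abs(g - c(0, 304.5))), numeric(1))
  expect_equal(isi, grid[which.max(d)])
})

test_that("particle weights are normalised and flat likelihoods stay uniform", {
  cfg <- quick_config("PF")
  particles <- list(positions = seq(0, 300, length.out = 30),
                    weights = rep(1 / 30, 30))
  withr::with_seed(2, {
    # equal observations: the systematic resample of uniform weights keeps
    # every particle exactly once (positions move only by the jitter)
    out <- pf_step(particles, rep(0.4, 30), cfg)
    expect_equal(sum(out$weights), 1, tolerance = 1e-12)
    expect_equal(out$weights, rep(1 / 30, 30))
    expect_true(all(abs(sort(out$positions) - particles$positions) < 6 * cfg$grid_step))
    # all-zero observations: the floor dominates and weights revert to uniform
    out0 <- pf_step(particles, rep(0, 30), cfg, floor_ref = 0)
    expect_equal(sum(out0$weights), 1, tolerance = 1e-12)
    expect_true(all(out0$positions >= cfg$search_lower &
                      out0$positions <= cfg$search_upper))
  })
})

test_that("particles concentrate near the profile centre on a noiseless subject", {
  s <- canonical_subject(noise_cv = 0)
  cfg <- quick_config("PF")
  particles <- list(positions = seq(0, 304.5, length.out = 30),
                    weights = rep(1 / 30, 30))
  withr::with_seed(8, {
    for (i in 1:10) {
      mep <- measure_mep(s, particles$positions) - s$baseline_mep
      particles <- pf_step(particles, mep, cfg)
    }
  })
  expect_lt(abs(mean(particles$positions) - 40), 17.5)
})

test_that("every method recovers a noiseless subject within one grid step", {
  s <- canonical_subject(noise_cv = 0)
  for (m in c("NR", "SVMR", "GPR", "PF")) {
    est <- estimate_isi_window(s, quick_config(m, n_ini = 7, seed = 1))
    expect_lte(max_end_error(est$window, c(5, 75)), 5)
    expect_gte(f1_interval(est$window, c(5, 75)), 0.95)
    expect_true(est$converged)
  }
})

test_that("estimation is bit-reproducible given subject, config and seed", {
  s <- sample_subject(population_params(), 31)
  cfg <- quick_config("GPR", n_ini = 7, seed = 14)
  e1 <- estimate_isi_window(s, cfg)
  e2 <- estimate_isi_window(s, cfg)
  expect_identical(e1, e2)
  e3 <- estimate_isi_window(s, quick_config("GPR", n_ini = 7, seed = 15))
  expect_false(identical(e1$observations, e3$observations))
})

test_that("an immediate iteration cap stops after the initial observations", {
  s <- canonical_subject(noise_cv = 0.3)
  est <- estimate_isi_window(s, quick_config("GPR", n_ini = 7, seed = 2,
                                             max_iterations = 0))
  expect_false(est$converged)
  expect_equal(est$n_observations, 7)
})

test_that("observation counts respect the budget bounds", {
  s <- sample_subject(population_params(), 55)
  for (m in c("NR", "GPR")) {
    est <- estimate_isi_window(s, quick_config(m, n_ini = 6, seed = 3))
    cfg <- est$config
    expect_lte(est$n_observations, cfg$n_ini + cfg$max_iterations)
    expect_equal(est$n_observations, nrow(est$observations))
  }
  pf <- estimate_isi_window(s, quick_config("PF", seed = 3, max_iterations = 20))
  iters <- max(pf$observations$iteration) + 1
  expect_lte(pf$n_observations, 30 * iters)
})

test_that("a totally unresponsive subject raises a no-response error", {
  s <- canonical_subject(noise_cv = 0, amplitude = 0, baseline = 0)
  expect_error(estimate_isi_window(s, quick_config("GPR", n_ini = 4, seed = 1)),
               "no response in search range")
})

test_that("the estimator config validates method-specific preconditions", {
  expect_error(estimator_config("NR", n_ini = 3), "NR")
  expect_error(estimator_config("GPR", n_ini = 1), "n_ini")
  expect_error(estimator_config("GPR", search_lower = 10, search_upper = 5))
  expect_silent(estimator_config("SVMR", n_ini = 2))
})

test_that("the offline pool oracle retrieves nearest-ISI measurements", {
  s <- canonical_subject(noise_cv = 0)
  sw <- incremental_sweep(s, protocol_config(n_intervals = 62), seed = 4)
  obs <- pool_oracle(sw$trials)
  withr::with_seed(1, {
    expect_equal(obs(40), expected_mep(s, 40), tolerance = 1e-9)
    expect_warning(obs(-50), "nearest")
  })
  # offline estimation on a complete noiseless pool matches ground truth
  est <- estimate_isi_window(obs, quick_config("NR", n_ini = 7, seed = 5))
  expect_lte(max_end_error(est$window, sw$window), 5)
})
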