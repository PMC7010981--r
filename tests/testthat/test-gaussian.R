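test_that("the single-Gaussian fit recovers exact model-class data", {
  isi <- seq(0, 100, by = 5)
  truth <- gaussian_model(1, 40, 17.5)
  d <- tibble::tibble(isi = isi, mep = predict(truth, isi))
  fit <- fit_single_gaussian(d)
  expect_equal(fit$model$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$model$center, 40, tolerance = 1e-6)
  expect_equal(fit$model$width, 17.5, tolerance = 1e-6)
})

test_that("the single-Gaussian fit tolerates multiplicative noise", {
  truth <- gaussian_model(1, 40, 17.5)
  withr::with_seed(21, {
    isi <- seq(0, 120, length.out = 50)
    mu <- predict(truth, isi)
    d <- tibble::tibble(isi = isi, mep = pmax(0, mu * (1 + 0.1 * rnorm(50))))
    fit <- fit_single_gaussian(d)
    expect_lt(abs(fit$model$center - 40), 5)
    expect_lt(abs(fit$model$width - 17.5) / 17.5, 0.2)
  })
})

test_that("the single-Gaussian fit enforces its preconditions", {
  expect_error(fit_single_gaussian(tibble::tibble(isi = c(0, 5, 10), mep = c(0, 1, 0))),
               "at least 4")
  expect_error(fit_single_gaussian(tibble::tibble(isi = c(0, 0, 5, 5), mep = c(0, 0, 1, 1))),
               "distinct")
  expect_error(fit_single_gaussian(tibble::tibble(isi = seq(0, 30, 5),
                                                  mep = rep(0, 7))),
               "no response detected")
})

test_that("tidy and glance expose the fitted parameters", {
  isi <- seq(0, 100, by = 10)
  d <- tibble::tibble(isi = isi, mep = predict(gaussian_model(0.8, 50, 20), isi))
  fit <- fit_single_gaussian(d)
  td <- tidy(fit)
  expect_equal(td$term, c("amplitude", "center", "width"))
  expect_equal(td$estimate[2], 50, tolerance = 1e-5)
  expect_equal(glance(fit)$n, length(isi))
})

test_that("the two-Gaussian fit collapses the spurious component on single-peak data", {
  isi <- seq(0, 150, by = 5)
  d <- tibble::tibble(isi = isi, mep = predict(gaussian_model(1, 60, 15), isi))
  fit <- fit_two_gaussian(d)
  expect_lte(fit$low$amplitude, 1e-3 * fit$high$amplitude)
  expect_equal(fit$high$center, 60, tolerance = 0.5)
})

test_that("the two-Gaussian fit resolves well-separated equal peaks", {
  isi <- seq(0, 300, by = 5)
  mep <- predict(gaussian_model(1, 80, 15), isi) +
    predict(gaussian_model(1, 220, 15), isi)
  fit <- fit_two_gaussian(tibble::tibble(isi = isi, mep = mep))
  expect_equal(fit$high$amplitude / fit$low$amplitude, 1, tolerance = 0.05)
  expect_equal(sort(c(fit$high$center, fit$low$center)), c(80, 220), tolerance = 1)
})

test_that("noisy single-peak subjects give large high/low amplitude ratios on average", {
  pop <- population_params()
  ratios <- vapply(1:6, function(i) {
    s <- sample_subject(pop, 800 + i)
    withr::with_seed(900 + i, {
      isi <- seq(0, 304.5, by = 5)
      d <- tibble::tibble(isi = isi, mep = measure_mep(s, isi) - s$baseline_mep)
      d$mep <- pmax(d$mep, 0)
      fit <- fit_two_gaussian(d)
      fit$high$amplitude / max(fit$low$amplitude, 1e-6)
    })
  }, numeric(1))
  expect_gt(mean(pmin(ratios, 1e3)), 2)
})

test_that("the two-sigma window of a Gaussian model is mu +/- 2 sigma", {
  w <- window_from_gaussian(gaussian_model(1, 40, 17.5))
  expect_equal(c(w$lower, w$upper, w$length), c(5, 75, 70))
  w2 <- window_from_gaussian(gaussian_model(1, 0, 1))
  expect_equal(c(w2$lower, w2$upper), c(-2, 2))
  # normalised profile value at the window ends rounds to 0.135
  m <- gaussian_model(0.7, 40, 17.5)
  at_ends <- predict(m, c(w$lower, w$upper)) / m$amplitude
  expect_equal(round(at_ends, 3), c(0.135, 0.135))
})

test_that("curve thresholding agrees with the two-sigma window on Gaussian curves", {
  for (pars in list(c(1, 40, 17.5), c(0.5, 150, 30), c(2, 250, 12))) {
    m <- gaussian_model(pars[1], pars[2], pars[3])
    isi <- seq(0, 304.5, by = 5)
    w <- window_from_curve(tibble::tibble(isi = isi, mep = predict(m, isi)))
    truth <- window_from_gaussian(m)
    expect_lt(abs(w$lower - truth$lower), 5)
    expect_lt(abs(w$upper - truth$upper), 5)
  }
})

test_that("curve thresholding handles degenerate and bimodal curves", {
  isi <- seq(0, 100, by = 5)
  expect_error(window_from_curve(tibble::tibble(isi = isi, mep = rep(0, length(isi)))),
               "no response")
  # two disjoint humps: the window brackets the one holding the global max
  mep <- predict(gaussian_model(1, 25, 6), isi) + predict(gaussian_model(0.6, 75, 6), isi)
  w <- window_from_curve(tibble::tibble(isi = isi, mep = mep))
  expect_gt(w$lower, 5)
  expect_lt(w$upper, 50)
  # curve above threshold everywhere: clipped to the range with edge flags
  w2 <- window_from_curve(tibble::tibble(isi = isi, mep = rep(1, length(isi)) +
                                           0.01 * sin(isi)))
  expect_equal(c(w2$lower, w2$upper), c(0, 100))
  expect_true(w2$edge_lower && w2$edge_upper)
})

test_that("window objects validate their geometry", {
  expect_error(isiw_window(10, 5), "upper")
  w <- isiw_window(5, 75)
  expect_equal(w$length, 70)
  expect_equal(as_tibble(w)$length, 70)
  expect_output(print(w), "ISI window")
})
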