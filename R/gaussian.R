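#' Closed ISI interval (window)
#'
#' A window is the contiguous range of inter-stimulus intervals (ISIs) over
#' which paired sub-threshold stimulation produces an enhanced motor evoked
#' potential.  It is represented as a closed interval `[lower, upper]` in
#' milliseconds together with its length.
#'
#' @param lower,upper Window ends in ms (`upper >= lower`).
#' @param edge_lower,edge_upper Flags set when the corresponding end was
#'   clipped to the search-range edge rather than found by a threshold
#'   crossing.
#' @return An object of class `isiw_window`: a list with elements `lower`,
#'   `upper`, `length`, `edge_lower`, `edge_upper`.
#' @examples
#' isiw_window(5, 75)
#' @export
isiw_window <- function(lower, upper, edge_lower = FALSE, edge_upper = FALSE) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper))
  if (upper < lower) {
    rlang::abort("`upper` must be >= `lower`.")
  }
  structure(
    list(lower = lower, upper = upper, length = upper - lower,
         edge_lower = isTRUE(edge_lower), edge_upper = isTRUE(edge_upper)),
    class = "isiw_window"
  )
}

#' @export
print.isiw_window <- function(x, ...) {
  edges <- c(if (x$edge_lower) "lower end at range edge",
             if (x$edge_upper) "upper end at range edge")
  cat(sprintf("<ISI window> [%.6g, %.6g] ms (length %.6g ms)%s\n",
              x$lower, x$upper, x$length,
              if (length(edges)) paste0(" [", paste(edges, collapse = "; "), "]") else ""))
  invisible(x)
}

#' @export
as_tibble.isiw_window <- function(x, ...) {
  tibble::tibble(lower = x$lower, upper = x$upper, length = x$length,
                 edge_lower = x$edge_lower, edge_upper = x$edge_upper)
}

# Coerce a window-like object (isiw_window or length-2 numeric) to isiw_window.
as_isiw_window <- function(x) {
  if (inherits(x, "isiw_window")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(isiw_window(min(x), max(x)))
  if (is.list(x) && all(c("lower", "upper") %in% names(x))) {
    return(isiw_window(x$lower, x$upper))
  }
  rlang::abort("Cannot interpret `x` as an ISI window; supply `isiw_window()` or c(lower, upper).")
}

#' Single-Gaussian MEP enhancement profile
#'
#' The parametric model of MEP enhancement against ISI:
#' `A * exp(-(isi - mu)^2 / (2 * sigma^2))`, with peak amplitude `A` (mV),
#' centre `mu` (ms) and width `sigma` (ms).
#'
#' @param amplitude Peak enhancement above baseline, mV (`>= 0`).
#' @param center Profile centre `mu`, ms.
#' @param width Profile width `sigma`, ms (`> 0`).
#' @return An object of class `gaussian_model`.
#' @examples
#' m <- gaussian_model(1, 40, 17.5)
#' predict(m, c(5, 40, 75))
#' @export
gaussian_model <- function(amplitude, center, width) {
  stopifnot(is.numeric(amplitude), is.numeric(center), is.numeric(width))
  if (width <= 0) rlang::abort("`width` must be > 0.")
  if (amplitude < 0) rlang::abort("`amplitude` must be >= 0.")
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<Gaussian profile> A = %.4g mV, mu = %.4g ms, sigma = %.4g ms\n",
              x$amplitude, x$center, x$width))
  invisible(x)
}

#' @param object A `gaussian_model`.
#' @param isi ISIs (ms) at which to evaluate the profile.
#' @param ... Unused.
#' @rdname gaussian_model
#' @export
predict.gaussian_model <- function(object, isi, ...) {
  object$amplitude * exp(-(isi - object$center)^2 / (2 * object$width^2))
}

# Least-squares Gaussian fit with explicit starting values; returns NULL on
# optimiser failure.  Box constraints keep the centre near the data and the
# width positive.
fit_gauss_once <- function(x, y, start, mu_box, sigma_max) {
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      data = dat,
      start = start,
      lower = c(A = 0, mu = mu_box[1], sigma = 1e-3),
      upper = c(A = Inf, mu = mu_box[2], sigma = sigma_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(coef = cf, rss = sum(stats::resid(fit)^2))
}

# The three multi-start initialisations for the single-Gaussian fit:
# argmax-based, moment-based, and range-midpoint.
gauss_starts <- function(x, y) {
  span <- diff(range(x))
  if (span <= 0) span <- 1
  amax <- max(y)
  w <- pmax(y, 0)
  if (sum(w) > 0) {
    mu_m <- sum(w * x) / sum(w)
    sd_m <- sqrt(sum(w * (x - mu_m)^2) / sum(w))
  } else {
    mu_m <- mean(x); sd_m <- span / 4
  }
  list(
    list(A = amax, mu = x[which.max(y)], sigma = max(span / 8, 1e-2)),
    list(A = amax, mu = mu_m, sigma = max(sd_m, 1e-2)),
    list(A = amax, mu = mean(range(x)), sigma = max(span / 4, 1e-2))
  )
}

#' Fit a single-Gaussian model to (ISI, MEP) observations
#'
#' Least-squares fit of `A * exp(-(isi - mu)^2 / (2 * sigma^2))` to observed
#' MEP enhancements, using three starting points (argmax-, moment- and
#' midpoint-based) and keeping the lowest-residual converged fit.  Requires at
#' least 4 observations at 3 or more distinct ISIs.
#'
#' @param data A data frame with numeric columns `isi` (ms) and `mep` (mV).
#' @param search_range Optional c(lower, upper) ms used to box-constrain the
#'   fitted centre; defaults to the observed ISI range extended by one span on
#'   each side.
#' @return An object of class `gaussian_fit`: the fitted [gaussian_model()]
#'   in `$model` plus the observations and residual sum of squares.  [tidy()]
#'   and [glance()] methods are available.
#' @examples
#' isi <- seq(0, 100, by = 5)
#' d <- tibble::tibble(isi = isi, mep = predict(gaussian_model(1, 40, 17.5), isi))
#' fit_single_gaussian(d)$model
#' @export
fit_single_gaussian <- function(data, search_range = NULL) {
  x <- data$isi
  y <- data$mep
  if (is.null(x) || is.null(y)) {
    rlang::abort("`data` must have columns `isi` and `mep`.")
  }
  if (length(x) < 4L || length(unique(x)) < 3L) {
    rlang::abort("Need at least 4 observations at 3 or more distinct ISIs.")
  }
  if (!any(y > 0)) rlang::abort("no response detected")
  span <- diff(range(x))
  if (is.null(search_range)) search_range <- range(x)
  L <- diff(search_range)
  mu_box <- c(search_range[1] - L, search_range[2] + L)
  sigma_max <- max(2 * L, 2 * span, 10)

  fits <- purrr::compact(purrr::map(
    gauss_starts(x, y),
    ~ fit_gauss_once(x, y, .x, mu_box, sigma_max)
  ))
  fits <- purrr::keep(fits, ~ .x$coef[["sigma"]] > 0)
  if (!length(fits)) rlang::abort("fit failed")
  best <- fits[[which.min(purrr::map_dbl(fits, "rss"))]]
  cf <- best$coef
  structure(
    list(model = gaussian_model(cf[["A"]], cf[["mu"]], cf[["sigma"]]),
         data = tibble::tibble(isi = x, mep = y),
         rss = best$rss, n = length(x)),
    class = "gaussian_fit"
  )
}

#' Fit a two-Gaussian model to (ISI, MEP) observations
#'
#' Least-squares fit of a sum of two Gaussian components with non-negative
#' amplitudes.  Components are returned sorted by amplitude ("high" first),
#' the convention used when asking whether a second component is needed at
#' all: on single-peaked profiles the low component's amplitude collapses
#' towards zero.
#'
#' @inheritParams fit_single_gaussian
#' @return A list of class `two_gaussian_fit` with elements `high` and `low`
#'   (both [gaussian_model()]), `rss` and `n`.
#' @export
fit_two_gaussian <- function(data, search_range = NULL) {
  x <- data$isi
  y <- data$mep
  if (is.null(x) || is.null(y)) {
    rlang::abort("`data` must have columns `isi` and `mep`.")
  }
  if (length(x) < 7L) rlang::abort("Need at least 7 observations.")
  if (!any(y > 0)) rlang::abort("no response detected")
  span <- diff(range(x))
  if (span <= 0) rlang::abort("Need observations at distinct ISIs.")
  if (is.null(search_range)) search_range <- range(x)
  L <- diff(search_range)
  lowb <- c(A1 = 0, mu1 = search_range[1] - L, s1 = 1e-3,
            A2 = 0, mu2 = search_range[1] - L, s2 = 1e-3)
  uppb <- c(A1 = Inf, mu1 = search_range[2] + L, s1 = 2 * L,
            A2 = Inf, mu2 = search_range[2] + L, s2 = 2 * L)
  amax <- max(y)
  mu_1 <- x[which.max(y)]
  # second component seeded at the strongest response away from the first peak
  masked <- y
  masked[abs(x - mu_1) < span / 4] <- -Inf
  mu_2 <- if (all(!is.finite(masked))) mean(range(x)) else x[which.max(masked)]
  q <- stats::quantile(range(x), c(0.25, 0.5, 0.75))
  starts <- list(
    list(A1 = amax, mu1 = mu_1, s1 = span / 8,
         A2 = max(masked[is.finite(masked)], amax / 4), mu2 = mu_2, s2 = span / 8),
    list(A1 = amax, mu1 = mu_1, s1 = span / 8,
         A2 = amax / 4, mu2 = q[[1]], s2 = span / 8),
    list(A1 = amax, mu1 = q[[2]], s1 = span / 6,
         A2 = amax / 4, mu2 = q[[3]], s2 = span / 6)
  )
  two_gauss_resid <- function(par) {
    y - par[["A1"]] * exp(-(x - par[["mu1"]])^2 / (2 * par[["s1"]]^2)) -
      par[["A2"]] * exp(-(x - par[["mu2"]])^2 / (2 * par[["s2"]]^2))
  }
  fit1 <- function(st) {
    # nls.lm rather than nlsLM: the degenerate (collapsed-component) optimum
    # this fit is meant to detect makes the model-object construction of
    # nlsLM fail on a singular gradient
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = unlist(st), lower = lowb, upper = uppb, fn = two_gauss_resid,
        control = minpack.lm::nls.lm.control(maxiter = 300))
      list(coef = fit$par, rss = fit$deviance)
    }, error = function(e) NULL, warning = function(w) NULL)
  }
  fits <- purrr::compact(purrr::map(starts, fit1))
  if (!length(fits)) rlang::abort("fit failed")
  best <- fits[[which.min(purrr::map_dbl(fits, "rss"))]]
  cf <- best$coef
  g1 <- gaussian_model(cf[["A1"]], cf[["mu1"]], max(cf[["s1"]], 1e-3))
  g2 <- gaussian_model(cf[["A2"]], cf[["mu2"]], max(cf[["s2"]], 1e-3))
  ord <- order(c(g1$amplitude, g2$amplitude), decreasing = TRUE)
  comps <- list(g1, g2)[ord]
  structure(list(high = comps[[1]], low = comps[[2]],
                 rss = best$rss, n = length(x)),
            class = "two_gaussian_fit")
}

#' Extract the two-sigma ISI window from a Gaussian profile
#'
#' For a Gaussian enhancement profile the effective window is taken as the
#' range within two standard deviations of the centre, `[mu - 2*sigma,
#' mu + 2*sigma]` (covering ~95% of the profile mass); the normalised profile
#' equals `exp(-2) ~ 0.135` of its peak at both ends.
#'
#' @param model A [gaussian_model()] (or `gaussian_fit`).
#' @return An [isiw_window()].
#' @examples
#' window_from_gaussian(gaussian_model(1, 40, 17.5)) # [5, 75]
#' @export
window_from_gaussian <- function(model) {
  if (inherits(model, "gaussian_fit")) model <- model$model
  stopifnot(inherits(model, "gaussian_model"))
  isiw_window(model$center - 2 * model$width, model$center + 2 * model$width)
}

#' Extract an ISI window from a nonparametric profile curve by thresholding
#'
#' Applies the same 0.135-of-peak amplitude criterion used for the Gaussian
#' two-sigma window to an arbitrary non-negative curve on an ISI grid: the
#' window ends are the first and last crossings of
#' `threshold_fraction * max(curve)` around the global-maximum grid point,
#' refined by linear interpolation between the bracketing grid points.  If the
#' curve is still above threshold at a grid edge, the window is clipped there
#' and the corresponding edge flag is set.
#'
#' @param curve A data frame with numeric columns `isi` (ms, increasing) and
#'   `mep` (non-negative, positive maximum).
#' @param threshold_fraction Fraction of the curve maximum defining the window
#'   ends (default 0.135, the normalised Gaussian value at +/- 2 sigma).
#' @return An [isiw_window()] with edge flags.
#' @examples
#' isi <- seq(0, 100, by = 5)
#' window_from_curve(tibble::tibble(isi = isi, mep = exp(-(isi - 40)^2 / (2 * 17.5^2))))
#' @export
window_from_curve <- function(curve, threshold_fraction = 0.135) {
  x <- curve$isi
  y <- curve$mep
  if (is.null(x) || is.null(y)) rlang::abort("`curve` must have columns `isi` and `mep`.")
  stopifnot(length(x) == length(y), !is.unsorted(x),
            threshold_fraction > 0, threshold_fraction < 1)
  if (any(y < 0)) rlang::abort("`curve` must be non-negative.")
  ymax <- max(y)
  if (ymax <= 0) rlang::abort("no response")
  thr <- threshold_fraction * ymax
  imax <- which.max(y)
  n <- length(y)

  # walk left from the peak to the first sub-threshold sample
  i <- imax
  while (i > 1L && y[i - 1L] >= thr) i <- i - 1L
  if (i == 1L) {
    lower <- x[1L]; edge_lo <- y[1L] >= thr
  } else {
    # y[i-1] < thr <= y[i]: interpolate the crossing
    lower <- x[i - 1L] + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
    edge_lo <- FALSE
  }
  j <- imax
  while (j < n && y[j + 1L] >= thr) j <- j + 1L
  if (j == n) {
    upper <- x[n]; edge_hi <- y[n] >= thr
  } else {
    upper <- x[j] + (y[j] - thr) / (y[j] - y[j + 1L]) * (x[j + 1L] - x[j])
    edge_hi <- FALSE
  }
  isiw_window(lower, upper, edge_lower = edge_lo, edge_upper = edge_hi)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "center", "width"),
    estimate = c(x$model$amplitude, x$model$center, x$model$width)
  )
}

#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n)
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("<single-Gaussian fit>\n")
  print(x$model)
  cat(sprintf("  n = %d, RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}
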