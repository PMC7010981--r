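#' Configuration of the adaptive ISI-window estimators
#'
#' @param method One of `"NR"` (single-Gaussian nonlinear regression),
#'   `"SVMR"` (support vector machine regression), `"GPR"` (Gaussian process
#'   regression) or `"PF"` (particle filter).
#' @param n_ini Number of initial observations seeding NR/SVMR/GPR
#'   (recommended 6-7; NR needs at least 4).  Ignored by PF, which instead
#'   distributes `n_particles` positions.
#' @param search_lower,search_upper Search range of ISIs, ms
#'   (impact-referenced; accelerometer mode starts the range at the detected
#'   impact, i.e. ISI 0).
#' @param grid_step ISI grid increment, ms (default 5).
#' @param variance_threshold Stopping threshold on the sample variance of the
#'   last `stop_history` window-end estimates, ms^2 (default 50, i.e. about a
#'   7 ms standard deviation — one grid step of slack).
#' @param stop_history Number of trailing iterations entering the stopping
#'   rule (default 5).
#' @param max_iterations Iteration cap (default 99).
#' @param threshold_fraction Curve-threshold fraction for nonparametric
#'   window extraction (default 0.135, the normalised Gaussian value at
#'   +/- 2 sigma).
#' @param n_particles Particle count for PF (default 30).
#' @param svm_epsilon_fraction Epsilon of the SVR epsilon-insensitive loss as
#'   a fraction of the observed MEP range (default 0.01; the window ends sit
#'   where the curve crosses 0.135 of its peak, and a wider tube flattens the
#'   fitted curve exactly there, biasing both ends outward).
#' @param svm_cost SVR cost parameter (default 100).
#' @param gp_lengthscale Initial GP kernel length scale, ms (default 25).
#' @param seed Integer seed; every stochastic step of the run derives from it.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(method = c("GPR", "NR", "SVMR", "PF"),
                             n_ini = 7,
                             search_lower = 0, search_upper = 304.5,
                             grid_step = 5,
                             variance_threshold = 50, stop_history = 5,
                             max_iterations = 99,
                             threshold_fraction = 0.135,
                             n_particles = 30,
                             svm_epsilon_fraction = 0.01, svm_cost = 100,
                             gp_lengthscale = 25,
                             seed = 1L) {
  method <- match.arg(method)
  stopifnot(search_upper > search_lower, grid_step > 0,
            threshold_fraction > 0, threshold_fraction < 1,
            stop_history >= 2, max_iterations >= 0,
            variance_threshold > 0, n_particles >= 2)
  if (n_ini < 2) rlang::abort("`n_ini` must be >= 2.")
  if (method == "NR" && n_ini < 4) {
    rlang::abort("NR needs `n_ini` >= 4 (the Gaussian fit has 3 parameters).")
  }
  structure(
    list(method = method, n_ini = n_ini,
         search_lower = search_lower, search_upper = search_upper,
         grid_step = grid_step,
         variance_threshold = variance_threshold,
         stop_history = stop_history, max_iterations = max_iterations,
         threshold_fraction = threshold_fraction,
         n_particles = n_particles,
         svm_epsilon_fraction = svm_epsilon_fraction, svm_cost = svm_cost,
         gp_lengthscale = gp_lengthscale,
         seed = as.integer(seed)),
    class = "estimator_config"
  )
}

config_grid <- function(config) {
  seq(config$search_lower, config$search_upper, by = config$grid_step)
}

snap_to_grid <- function(isi, config) {
  grid <- config_grid(config)
  grid[which.min(abs(grid - isi))]
}

#' Stopping rule of the estimation loop
#'
#' The loop stops when the sample variances of both the lower and the upper
#' window-end estimates over the last `stop_history` iterations fall below
#' `variance_threshold` (50 ms^2 by default, i.e. a 7 ms standard deviation),
#' or when the iteration count reaches `max_iterations`.
#'
#' @param end_history A data frame with columns `lower` and `upper`, one row
#'   per completed iteration.
#' @param config An [estimator_config()].
#' @param iteration Current iteration count; defaults to the history length.
#' @return `TRUE` if the loop should stop.
#' @export
check_stopping <- function(end_history, config, iteration = nrow(end_history)) {
  if (iteration >= config$max_iterations) return(TRUE)
  ends_stable(end_history, config)
}

# variance part of the stopping rule (TRUE = converged)
ends_stable <- function(end_history, config) {
  h <- config$stop_history
  if (is.null(end_history) || nrow(end_history) < h) return(FALSE)
  tail_lo <- utils::tail(end_history$lower, h)
  tail_hi <- utils::tail(end_history$upper, h)
  if (any(is.na(tail_lo)) || any(is.na(tail_hi))) return(FALSE)
  stats::var(tail_lo) < config$variance_threshold &&
    stats::var(tail_hi) < config$variance_threshold
}

#' Choose the next ISI to observe
#'
#' Boundary-refining acquisition for NR and SVMR: alternate between the
#' current lower and upper window-end estimates (snapped to the grid and
#' clipped to the search range), since end uncertainty dominates the window
#' metric.  Variance-directed acquisition for GPR: the grid ISI with the
#' largest posterior predictive variance.  PF does not use an acquisition
#' function (it observes at its particle positions).  When no window estimate
#' exists (fit failure), falls back to the unsampled grid ISI farthest from
#' all previous observations.  Repeat visits to an ISI are allowed: responses
#' are stochastic.
#'
#' @param state A list with elements `window` (current [isiw_window()] or
#'   `NULL`), `observations` (tibble with column `isi`), `last_end`
#'   (`"lower"`, `"upper"` or `NA`) and, for GPR, `gp` (a [gp_fit()]).
#' @param config An [estimator_config()].
#' @return A list with `isi` (the next ISI, ms) and `last_end` (updated
#'   alternation state).
#' @export
acquire_next_isi <- function(state, config) {
  grid <- config_grid(config)
  if (is.null(state$window)) {
    unseen <- setdiff(grid, state$observations$isi)
    if (!length(unseen)) unseen <- grid
    d <- purrr::map_dbl(unseen, ~ min(abs(.x - state$observations$isi)))
    return(list(isi = unseen[which.max(d)], last_end = state$last_end))
  }
  if (config$method == "GPR") {
    pv <- gp_predict(state$gp, grid)
    return(list(isi = grid[which.max(pv$var)], last_end = state$last_end))
  }
  # NR / SVMR: alternate window ends
  nxt <- if (identical(state$last_end, "lower")) "upper" else "lower"
  target <- if (nxt == "lower") state$window$lower else state$window$upper
  list(isi = snap_to_grid(min(max(target, config$search_lower),
                              config$search_upper), config),
       last_end = nxt)
}

#' One particle-filter step
#'
#' Each particle's weight is multiplied by its observed MEP plus a small
#' floor (1% of the largest MEP observed so far), normalised, and the cloud
#' is redistributed by systematic resampling with Gaussian jitter
#' (SD = one grid step) clipped to the search range.
#'
#' @param particles A list with `positions` and `weights` (see
#'   [estimate_isi_window()]'s PF branch).
#' @param mep Observed MEPs at `particles$positions`.
#' @param config An [estimator_config()].
#' @param floor_ref Reference MEP for the weight floor (max MEP observed so
#'   far); the floor is `0.01 * floor_ref` (or 1e-9 when nothing positive has
#'   been seen, so flat likelihoods revert to uniform weights).
#' @return The updated particle list (weights sum to 1, positions in range).
#' @export
pf_step <- function(particles, mep, config, floor_ref = max(mep)) {
  stopifnot(length(mep) == length(particles$positions))
  eps <- if (is.finite(floor_ref) && floor_ref > 0) 0.01 * floor_ref else 1e-9
  w <- particles$weights * (pmax(mep, 0) + eps)
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  idx <- systematic_resample(w)
  pos <- particles$positions[idx] + stats::rnorm(length(idx), 0, config$grid_step)
  pos <- pmin(pmax(pos, config$search_lower), config$search_upper)
  list(positions = pos, weights = rep(1 / length(idx), length(idx)))
}

systematic_resample <- function(w) {
  n <- length(w)
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(w)) + 1L
}

# Evenly spaced initial ISIs spanning the search range inclusive of both
# ends, snapped to the grid.
initial_isis <- function(config, n) {
  raw <- seq(config$search_lower, config$search_upper, length.out = n)
  purrr::map_dbl(raw, snap_to_grid, config = config)
}

# One fit + window extraction for the current observations.  All methods
# reference MEPs to the minimum observed value (the baseline estimate) so
# the fitted/thresholded quantity is the enhancement above baseline.
# Returns list(window, curve, gp, error).
fit_current <- function(obs, config) {
  grid <- config_grid(config)
  ref <- min(obs$mep)
  y <- obs$mep - ref
  dat <- tibble::tibble(isi = obs$isi, mep = y)
  out <- list(window = NULL, curve = NULL, gp = NULL, error = NA_character_)
  sr <- c(config$search_lower, config$search_upper)
  tryCatch({
    if (config$method %in% c("NR", "PF")) {
      fit <- fit_single_gaussian(dat, search_range = sr)
      out$window <- window_from_gaussian(fit$model)
      out$curve <- tibble::tibble(isi = grid,
                                  mep = ref + predict(fit$model, grid))
    } else if (config$method == "SVMR") {
      eps <- config$svm_epsilon_fraction * max(diff(range(y)), 1e-6)
      sv <- e1071::svm(x = matrix(obs$isi, ncol = 1), y = y,
                       type = "eps-regression", kernel = "radial",
                       gamma = 1 / (2 * config$gp_lengthscale^2),
                       cost = config$svm_cost, epsilon = eps, scale = FALSE)
      pred <- as.numeric(stats::predict(sv, matrix(grid, ncol = 1)))
      out$window <- window_from_curve(
        tibble::tibble(isi = grid, mep = pmax(pred, 0)),
        config$threshold_fraction)
      out$curve <- tibble::tibble(isi = grid, mep = ref + pred)
    } else { # GPR
      gp <- gp_fit(dat, lengthscale_init = config$gp_lengthscale)
      pred <- gp_predict(gp, grid)
      out$gp <- gp
      out$window <- window_from_curve(
        tibble::tibble(isi = grid, mep = pmax(pred$mean, 0)),
        config$threshold_fraction)
      out$curve <- tibble::tibble(isi = grid, mep = ref + pred$mean)
    }
    # clip the window to the search range
    w <- out$window
    out$window <- isiw_window(max(w$lower, config$search_lower),
                              min(w$upper, config$search_upper),
                              edge_lower = w$edge_lower || w$lower < config$search_lower,
                              edge_upper = w$edge_upper || w$upper > config$search_upper)
    out
  }, error = function(e) {
    out$error <- conditionMessage(e)
    out
  })
}

#' Adaptively estimate an ISI window from sequential MEP observations
#'
#' Runs the observe-acquire-refit loop of the chosen method.  NR, SVMR and
#' GPR start from `n_ini` observations at evenly spaced grid ISIs spanning
#' the search range (both ends included); PF instead distributes
#' `n_particles` positions evenly and observes at all of them each iteration.
#' Every iteration refits the model, extracts the current window (two-sigma
#' ends of the fitted Gaussian for NR/PF, 0.135-of-peak threshold crossings
#' of the predicted curve for SVMR/GPR), records the ends, checks the
#' stopping rule, and acquires the next observation.  The run is
#' deterministic given the subject realisation and `config$seed`.
#'
#' @param subject Either an `isiw_subject` (observed through
#'   [measure_mep()]), a function `function(isi) -> mep`, or a trial-log
#'   data frame used as a pre-recorded observation pool (nearest-ISI lookup;
#'   see [pool_oracle()]).
#' @param config An [estimator_config()].
#' @param valve_referenced When `TRUE` and `subject` is an `isiw_subject`,
#'   adds the per-trial hammer-delay jitter to each queried ISI (no
#'   accelerometer: timing is valve-referenced).
#' @return An object of class `isiw_estimate`: list with `window`
#'   ([isiw_window()]), `curve` (tibble `isi`, `mep` on the grid),
#'   `observations` (tibble `iteration`, `isi`, `mep`), `n_observations`,
#'   `converged`, `end_history` (tibble `iteration`, `lower`, `upper`),
#'   `method` and `config`.
#' @examples
#' s <- sample_subject(population_params(noise_cv = 0), seed = 7)
#' est <- estimate_isi_window(s, estimator_config("NR", n_ini = 7, seed = 1))
#' est$window
#' @export
estimate_isi_window <- function(subject, config = estimator_config(),
                                valve_referenced = FALSE) {
  stopifnot(inherits(config, "estimator_config"))
  observe <- as_observer(subject, valve_referenced)
  withr::with_seed(config$seed, {
    if (config$method == "PF") {
      run_pf_loop(observe, config)
    } else {
      run_regression_loop(observe, config)
    }
  })
}

as_observer <- function(subject, valve_referenced = FALSE) {
  if (is.function(subject)) return(subject)
  if (inherits(subject, "isiw_subject")) {
    if (valve_referenced && subject$delay_jitter_sd > 0) {
      return(function(isi) {
        measure_mep(subject, isi + stats::rnorm(length(isi), 0, subject$delay_jitter_sd))
      })
    }
    return(function(isi) measure_mep(subject, isi))
  }
  if (is.data.frame(subject)) return(pool_oracle(subject))
  rlang::abort("`subject` must be an isiw_subject, a function, or a trial-log data frame.")
}

run_regression_loop <- function(observe, config) {
  isis <- initial_isis(config, config$n_ini)
  obs <- tibble::tibble(iteration = 0L, isi = isis, mep = observe(isis))

  # no response among the initial observations: sweep the remaining grid
  # once before giving up
  if (!any(obs$mep > 0)) {
    rest <- setdiff(config_grid(config), obs$isi)
    if (length(rest)) {
      obs <- dplyr::bind_rows(
        obs, tibble::tibble(iteration = 0L, isi = rest, mep = observe(rest)))
    }
    if (!any(obs$mep > 0)) rlang::abort("no response in search range")
  }

  ends <- tibble::tibble(iteration = integer(), lower = double(), upper = double())
  state <- list(window = NULL, gp = NULL, last_end = NA_character_)
  iter <- 0L
  converged <- FALSE
  cur <- NULL
  repeat {
    cur <- fit_current(obs, config)
    if (!is.null(cur$window)) {
      state$window <- cur$window
      state$gp <- cur$gp
      ends <- dplyr::bind_rows(ends, tibble::tibble(
        iteration = iter, lower = cur$window$lower, upper = cur$window$upper))
    }
    if (ends_stable(ends, config)) { converged <- TRUE; break }
    if (iter >= config$max_iterations) break
    acq <- acquire_next_isi(list(window = state$window,
                                 observations = obs,
                                 last_end = state$last_end,
                                 gp = state$gp), config)
    state$last_end <- acq$last_end
    iter <- iter + 1L
    obs <- dplyr::bind_rows(obs, tibble::tibble(
      iteration = iter, isi = acq$isi, mep = observe(acq$isi)))
  }
  if (is.null(state$window)) rlang::abort("fit failed: no window estimate obtained")
  new_estimate(state$window, cur$curve, obs, converged, ends, config)
}

run_pf_loop <- function(observe, config) {
  particles <- list(
    positions = seq(config$search_lower, config$search_upper,
                    length.out = config$n_particles),
    weights = rep(1 / config$n_particles, config$n_particles)
  )
  obs <- tibble::tibble(iteration = integer(), isi = double(), mep = double())
  ends <- tibble::tibble(iteration = integer(), lower = double(), upper = double())
  window <- NULL
  curve <- NULL
  iter <- 0L
  converged <- FALSE
  repeat {
    mep <- observe(particles$positions)
    obs <- dplyr::bind_rows(obs, tibble::tibble(
      iteration = iter, isi = particles$positions, mep = mep))
    cur <- fit_current(obs, config) # Gaussian fit to the cumulative cloud
    if (!is.null(cur$window)) {
      window <- cur$window
      curve <- cur$curve
      ends <- dplyr::bind_rows(ends, tibble::tibble(
        iteration = iter, lower = window$lower, upper = window$upper))
    }
    if (ends_stable(ends, config)) { converged <- TRUE; break }
    if (iter >= config$max_iterations) break
    particles <- pf_step(particles, mep, config, floor_ref = max(obs$mep))
    iter <- iter + 1L
  }
  if (is.null(window)) rlang::abort("fit failed: no window estimate obtained")
  new_estimate(window, curve, obs, converged, ends, config)
}

new_estimate <- function(window, curve, obs, converged, ends, config) {
  structure(
    list(window = window, curve = curve, observations = obs,
         n_observations = nrow(obs), converged = converged,
         end_history = ends, method = config$method, config = config),
    class = "isiw_estimate"
  )
}

#' Build an offline observation oracle from a recorded trial log
#'
#' Mirrors the offline evaluation mode in which the estimator retrieves MEP
#' measurements from a pre-recorded pool: a query returns a (seeded) random
#' draw among the recorded trials at the nearest available ISI.  Queries
#' farther than one grid step from any recorded ISI trigger a warning.
#'
#' @param trials A data frame with columns `isi_ms` and `mep_pp_mv` (a trial
#'   log, see [write_trial_log()]), or columns `isi` and `mep`.
#' @param warn_distance Distance (ms) beyond which a nearest-ISI substitution
#'   is warned about (default 5).
#' @return A function `function(isi) -> mep` usable as the `subject` argument
#'   of [estimate_isi_window()].
#' @export
pool_oracle <- function(trials, warn_distance = 5) {
  isi <- trials$isi_ms %||% trials$isi
  mep <- trials$mep_pp_mv %||% trials$mep
  if (is.null(isi) || is.null(mep)) {
    rlang::abort("`trials` must have columns `isi_ms`/`mep_pp_mv` (or `isi`/`mep`).")
  }
  keep <- is.finite(isi) & is.finite(mep)
  isi <- isi[keep]; mep <- mep[keep]
  if (!length(isi)) rlang::abort("empty observation pool")
  function(query) {
    purrr::map_dbl(query, function(q) {
      d <- abs(isi - q)
      nearest <- min(d)
      if (nearest > warn_distance) {
        rlang::warn(sprintf(
          "requested ISI %.1f ms not in pool; using nearest recorded ISI %.1f ms",
          q, isi[which.min(d)]))
      }
      cand <- which(d <= nearest + 1e-9)
      mep[cand[sample.int(length(cand), 1)]]
    })
  }
}

#' @export
print.isiw_estimate <- function(x, ...) {
  cat(sprintf("<ISI window estimate> method %s, %d observations, %s\n",
              x$method, x$n_observations,
              if (x$converged) "converged" else "not converged"))
  print(x$window)
  invisible(x)
}

#' @export
tidy.isiw_estimate <- function(x, ...) x$end_history

#' @export
glance.isiw_estimate <- function(x, ...) {
  tibble::tibble(method = x$method,
                 lower = x$window$lower, upper = x$window$upper,
                 length = x$window$length,
                 n_observations = x$n_observations,
                 iterations = max(c(0L, x$observations$iteration)),
                 converged = x$converged)
}
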