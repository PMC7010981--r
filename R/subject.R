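#' Population statistics of the virtual-subject simulator
#'
#' Defines the distribution from which virtual subjects are drawn.  Defaults
#' follow the reported population structure: effective window lengths of mean
#' 108 ms and SD 45 ms (truncated below at 20 ms, the narrow end of
#' physiological windows), a repeatable pneumatic hammer delay of mean
#' 195.5 ms and SD 2 ms, and multiplicative trial-to-trial MEP noise with a
#' coefficient of variation of 0.3.
#'
#' @param window_length_mean,window_length_sd Window length distribution, ms.
#' @param delay_mean,delay_sd Hammer delay distribution, ms.  `delay_sd` is
#'   used both between subjects and as per-trial jitter in valve-referenced
#'   querying.
#' @param peak_amplitude_range Range of per-subject peak MEP enhancement, mV.
#' @param noise_cv Coefficient of variation of trial MEPs (multiplicative).
#' @param baseline_mep Baseline MEP (response at 100% resting motor
#'   threshold), mV.
#' @param search_range_ms Valve-referenced search span, ms; the usable
#'   impact-referenced ISI span is `search_range_ms - delay_mean`.
#' @return A list of class `population_params`.
#' @export
population_params <- function(window_length_mean = 108, window_length_sd = 45,
                              delay_mean = 195.5, delay_sd = 2,
                              peak_amplitude_range = c(0.3, 1.5),
                              noise_cv = 0.3, baseline_mep = 0.05,
                              search_range_ms = 500) {
  stopifnot(window_length_mean > 0, window_length_sd >= 0,
            delay_sd >= 0, noise_cv >= 0, baseline_mep >= 0,
            length(peak_amplitude_range) == 2,
            peak_amplitude_range[1] > 0,
            peak_amplitude_range[2] >= peak_amplitude_range[1],
            search_range_ms > delay_mean)
  structure(
    list(window_length_mean = window_length_mean,
         window_length_sd = window_length_sd,
         delay_mean = delay_mean, delay_sd = delay_sd,
         peak_amplitude_range = peak_amplitude_range,
         noise_cv = noise_cv, baseline_mep = baseline_mep,
         search_range_ms = search_range_ms),
    class = "population_params"
  )
}

# Truncated-normal draw by rejection; degenerate SD returns the clipped mean.
rtruncnorm1 <- function(n, mean, sd, lower, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw a virtual subject from the population
#'
#' Samples a ground-truth subject: window length `L ~ N(mean, sd)` truncated
#' at `L >= 20` ms, profile width `sigma = L / 4`, centre drawn uniformly so
#' the true window (`centre +/- 2 sigma`) lies inside the usable
#' impact-referenced ISI span, peak amplitude uniform over
#' `peak_amplitude_range`, and hammer delay `~ N(delay_mean, delay_sd)`.
#' Deterministic given `seed` (the caller's RNG state is untouched).
#'
#' @param pop A [population_params()].
#' @param seed Integer seed.
#' @return A list of class `isiw_subject` with elements `profile`
#'   ([gaussian_model()]), `t_delay`, `baseline_mep`, `noise_cv`,
#'   `true_window` ([isiw_window()]), `isi_span` (usable impact-referenced
#'   span, ms) and `seed`.
#' @export
sample_subject <- function(pop = population_params(), seed = 1L) {
  stopifnot(inherits(pop, "population_params"))
  withr::with_seed(as.integer(seed), {
    span <- pop$search_range_ms - pop$delay_mean
    L <- rtruncnorm1(1, pop$window_length_mean, pop$window_length_sd,
                     lower = 20, upper = span - 10)
    sigma <- L / 4
    center <- stats::runif(1, 2 * sigma, span - 2 * sigma)
    A <- stats::runif(1, pop$peak_amplitude_range[1], pop$peak_amplitude_range[2])
    delay <- stats::rnorm(1, pop$delay_mean, pop$delay_sd)
    profile <- gaussian_model(A, center, sigma)
    structure(
      list(profile = profile, t_delay = delay,
           baseline_mep = pop$baseline_mep, noise_cv = pop$noise_cv,
           delay_jitter_sd = pop$delay_sd,
           true_window = window_from_gaussian(profile),
           isi_span = span, seed = as.integer(seed)),
      class = "isiw_subject"
    )
  })
}

#' Draw several virtual subjects as a tibble
#'
#' @inheritParams sample_subject
#' @param n Number of subjects.
#' @return A tibble with one row per subject (identifiers, profile
#'   parameters, delay, true-window ends) and the subject objects in the
#'   list-column `subject`.
#' @export
sample_subjects <- function(pop = population_params(), n, seed = 1L) {
  seeds <- as.integer(seed) + seq_len(n) - 1L
  subs <- purrr::map(seeds, ~ sample_subject(pop, .x))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    seed = seeds,
    amplitude = purrr::map_dbl(subs, ~ .x$profile$amplitude),
    center = purrr::map_dbl(subs, ~ .x$profile$center),
    width = purrr::map_dbl(subs, ~ .x$profile$width),
    t_delay = purrr::map_dbl(subs, "t_delay"),
    window_lower = purrr::map_dbl(subs, ~ .x$true_window$lower),
    window_upper = purrr::map_dbl(subs, ~ .x$true_window$upper),
    window_length = purrr::map_dbl(subs, ~ .x$true_window$length),
    subject = subs
  )
}

#' @export
print.isiw_subject <- function(x, ...) {
  cat("<virtual subject>\n")
  print(x$profile)
  cat(sprintf("  delay %.2f ms, baseline %.3g mV, noise CV %.2f\n",
              x$t_delay, x$baseline_mep, x$noise_cv))
  cat(sprintf("  true window [%.2f, %.2f] ms (length %.2f ms)\n",
              x$true_window$lower, x$true_window$upper, x$true_window$length))
  invisible(x)
}

#' Simulate one MEP measurement at a given ISI
#'
#' The expected MEP is `baseline + A * exp(-(isi - mu)^2 / (2 * sigma^2))`;
#' the returned value multiplies it by `(1 + noise_cv * z)` with `z` standard
#' normal, clipped at zero (multiplicative noise, so scatter grows with the
#' mean).  Uses the current RNG state; seed the session (or wrap in
#' `withr::with_seed()`) for reproducibility.
#'
#' @param subject An [sample_subject()] result.
#' @param isi ISI(s) in ms, impact-referenced; may be negative (TMS before
#'   impact), which simply yields baseline response.
#' @return Numeric vector of simulated peak-to-peak MEPs, mV.
#' @export
measure_mep <- function(subject, isi) {
  stopifnot(inherits(subject, "isiw_subject"), is.numeric(isi), all(is.finite(isi)))
  expected <- subject$baseline_mep + predict(subject$profile, isi)
  pmax(0, expected * (1 + subject$noise_cv * stats::rnorm(length(isi))))
}

#' Run the conventional incremental sweep on a virtual subject
#'
#' Sweeps the ISI grid, taking `reps_per_isi` measurements at each grid ISI,
#' discarding the first `discard_first` (startle response) and recording the
#' mean of the rest.  The ground-truth window is the longest contiguous run
#' of grid ISIs whose mean exceeds the baseline by at least
#' `threshold_fraction` of the peak enhancement (0.135 of peak, the same
#' two-sigma criterion used for window extraction), reported as
#' `[first ISI, last ISI]`; ties break toward the earlier run.
#'
#' @param subject An [sample_subject()] result.
#' @param protocol A [protocol_config()]; the grid should cover the subject's
#'   true window.
#' @param seed Optional integer seed isolating the sweep's RNG use.
#' @param threshold_fraction Supra-baseline criterion as a fraction of peak
#'   enhancement (default 0.135).
#' @param t_valve Valve command time used in the trial log, ms.
#' @return An object of class `isiw_sweep`: list with `profile` (tibble
#'   `isi`, `mean_mep`, `n_used`), `trials` (trial-log tibble), `window`
#'   ([isiw_window()] or `NULL`), `empty` flag, and `subject`.
#' @export
incremental_sweep <- function(subject, protocol = protocol_config(),
                              seed = NULL, threshold_fraction = 0.135,
                              t_valve = 50) {
  stopifnot(inherits(subject, "isiw_subject"), inherits(protocol, "protocol_config"))
  run <- function() {
    grid <- protocol$grid_start_ms +
      protocol$grid_step_ms * (seq_len(protocol$n_intervals) - 1)
    reps <- protocol$reps_per_isi
    keep <- seq(protocol$discard_first + 1L, reps)
    rows <- purrr::map(seq_along(grid), function(i) {
      g <- grid[i]
      jitter <- stats::rnorm(reps, 0, subject$delay_jitter_sd)
      t_hit <- t_valve + subject$t_delay + jitter
      t_tms <- t_valve + subject$t_delay + g
      isi <- t_tms - t_hit
      mep <- measure_mep(subject, isi)
      tibble::tibble(
        grid_isi_ms = g, rep = seq_len(reps),
        t_valve_ms = t_valve, t_tms_ms = t_tms, t_hit_ms = t_hit,
        isi_ms = isi, mep_pp_mv = mep, kept = seq_len(reps) %in% keep
      )
    })
    trials <- dplyr::bind_rows(rows, .id = NULL)
    trials$trial_id <- seq_len(nrow(trials))
    trials$subject_id <- sprintf("seed%d", subject$seed)
    profile <- trials |>
      dplyr::filter(.data$kept) |>
      dplyr::group_by(isi = .data$grid_isi_ms) |>
      dplyr::summarise(mean_mep = mean(.data$mep_pp_mv), n_used = dplyr::n(),
                       .groups = "drop")
    win <- supra_baseline_window(profile$isi, profile$mean_mep,
                                 subject$baseline_mep, threshold_fraction)
    structure(
      list(profile = profile, trials = trials, window = win,
           empty = is.null(win), subject = subject),
      class = "isiw_sweep"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Longest contiguous run of grid ISIs whose mean exceeds baseline by
# threshold_fraction of the peak enhancement; ties toward the earlier run.
supra_baseline_window <- function(isi, mean_mep, baseline, threshold_fraction) {
  peak <- max(mean_mep) - baseline
  if (peak <= 0) return(NULL)
  above <- mean_mep >= baseline + threshold_fraction * peak
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])] # which.max -> earliest on ties
  isiw_window(isi[starts[best]], isi[ends[best]],
              edge_lower = starts[best] == 1L,
              edge_upper = ends[best] == length(isi))
}

#' @export
print.isiw_sweep <- function(x, ...) {
  cat(sprintf("<incremental sweep> %d trials over %d grid ISIs\n",
              nrow(x$trials), nrow(x$profile)))
  if (x$empty) cat("  no supra-baseline window found\n") else print(x$window)
  invisible(x)
}

#' @export
tidy.isiw_sweep <- function(x, ...) x$profile

#' Simulate the accelerometer trace of one tapping trial
#'
#' Produces a hammer acceleration trace whose first zero crossing after
#' motion onset lands exactly at `t_valve + t_delay`: launch and braking are
#' modelled as one sine half-cycle (positive launch lobe crossing zero at the
#' impact, negative lobe afterwards), preceded and followed by quiescence.
#'
#' @param subject An [sample_subject()] result (its `t_delay` is used), or a
#'   numeric delay in ms.
#' @param t_valve Valve command time, ms.
#' @param sampling_interval Sampling interval, ms.
#' @param duration Trace duration, ms.
#' @param amplitude Peak acceleration, arbitrary units.
#' @param travel_ms Duration of hammer travel before impact, ms.
#' @return A [sampled_trace()] tibble.
#' @export
simulate_acceleration_trace <- function(subject, t_valve = 50,
                                        sampling_interval = 0.5,
                                        duration = 500, amplitude = 5,
                                        travel_ms = 30) {
  delay <- if (inherits(subject, "isiw_subject")) subject$t_delay else as.numeric(subject)
  t_hit <- t_valve + delay
  t0 <- t_hit - travel_ms
  tt <- seq(0, duration, by = sampling_interval)
  phase <- (tt - t0) / travel_ms # sine half-cycle per unit phase
  v <- ifelse(phase > 0 & phase < 2, amplitude * sinpi(phase), 0)
  sampled_trace(v, sampling_interval, start_time = 0)
}
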