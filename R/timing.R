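#' Event timings of a paired-stimulation trial
#'
#' All times are in milliseconds from trial start.  The valve command
#' (`t_valve`) launches the pneumatic hammer; the impact (`t_hit`) follows
#' after the system delay `t_delay = t_hit - t_valve`; the TMS pulse fires at
#' `t_tms`.  The inter-stimulus interval is `isi = t_tms - t_hit` and may be
#' negative (TMS before impact).
#'
#' @param t_valve,t_tms Command times, ms (non-negative, finite).
#' @param t_hit Detected or simulated impact time, ms; `NA` when no
#'   accelerometer reading is available.
#' @param subject_id,trial_id Optional identifiers carried into trial logs.
#' @return A tibble with one row per trial and columns `trial_id`,
#'   `subject_id`, `t_valve_ms`, `t_tms_ms`, `t_hit_ms`, `t_delay_ms`,
#'   `isi_ms`.
#' @examples
#' stimulation_timing(t_valve = 50, t_tms = 400, t_hit = 245)
#' @export
stimulation_timing <- function(t_valve, t_tms, t_hit = NA_real_,
                               subject_id = NA_character_,
                               trial_id = seq_along(t_valve)) {
  n <- max(length(t_valve), length(t_tms), length(t_hit))
  t_valve <- rep_len(as.numeric(t_valve), n)
  t_tms <- rep_len(as.numeric(t_tms), n)
  t_hit <- rep_len(as.numeric(t_hit), n)
  if (any(!is.finite(t_valve)) || any(!is.finite(t_tms))) {
    rlang::abort("`t_valve` and `t_tms` must be finite.")
  }
  if (any(t_valve < 0) || any(t_tms < 0) || any(t_hit < 0, na.rm = TRUE)) {
    rlang::abort("All event times must be non-negative.")
  }
  if (any(t_hit < t_valve, na.rm = TRUE)) {
    rlang::abort("`t_hit` must be >= `t_valve`.")
  }
  tibble::tibble(
    trial_id = rep_len(trial_id, n),
    subject_id = rep_len(subject_id, n),
    t_valve_ms = t_valve,
    t_tms_ms = t_tms,
    t_hit_ms = t_hit,
    t_delay_ms = t_hit - t_valve,
    isi_ms = t_tms - t_hit
  )
}

#' Compute inter-stimulus intervals from trial timings
#'
#' `isi = t_tms - t_hit`: the interval between the mechanical impact and the
#' TMS pulse.  Negative values mean TMS preceded the impact.
#'
#' @param timing A data frame with columns `t_tms_ms` and `t_hit_ms` (e.g.
#'   from [stimulation_timing()]).
#' @return The tibble with `isi_ms` (re)computed.
#' @examples
#' compute_isi(stimulation_timing(50, 400, 245))$isi_ms # 155
#' @export
compute_isi <- function(timing) {
  if (is.null(timing$t_tms_ms) || is.null(timing$t_hit_ms)) {
    rlang::abort("`timing` must have columns `t_tms_ms` and `t_hit_ms`.")
  }
  if (any(is.na(timing$t_hit_ms))) {
    rlang::abort("impact time unavailable; use valve-referenced timing")
  }
  dplyr::mutate(tibble::as_tibble(timing), isi_ms = .data$t_tms_ms - .data$t_hit_ms)
}

#' Uniformly sampled trace
#'
#' Builds the tibble representation (`time_ms`, `value`) of a uniformly
#' sampled accelerometer or EMG trace: sample k sits at
#' `start_time + k * sampling_interval`.
#'
#' @param values Numeric samples (acceleration in arbitrary units or EMG mV).
#' @param sampling_interval Sampling interval in ms (`> 0`).
#' @param start_time Time of the first sample, ms.
#' @return A tibble with columns `time_ms`, `value`.
#' @export
sampled_trace <- function(values, sampling_interval, start_time = 0) {
  stopifnot(is.numeric(values), length(values) > 0,
            is.numeric(sampling_interval), sampling_interval > 0)
  tibble::tibble(
    time_ms = start_time + (seq_along(values) - 1) * sampling_interval,
    value = as.numeric(values)
  )
}

#' Detect the hammer impact time from an acceleration trace
#'
#' The impact time `t_hit` is the first zero crossing of the signed
#' acceleration after the initiation of hammer motion.  Motion initiation is
#' the first sample whose magnitude exceeds `onset_threshold`; the crossing
#' time is refined by linear interpolation between the bracketing samples.
#' The detection is invariant under positive rescaling of the trace when the
#' default (relative) threshold is used.
#'
#' @param trace A data frame with columns `time_ms`, `value`
#'   (see [sampled_trace()]).
#' @param onset_threshold Acceleration magnitude marking motion initiation;
#'   default 10% of the trace's maximum absolute value.
#' @return Impact time in ms.
#' @export
detect_impact_time <- function(trace, onset_threshold = NULL) {
  t <- trace$time_ms
  v <- trace$value
  if (is.null(t) || is.null(v) || !length(v)) {
    rlang::abort("`trace` must have non-empty columns `time_ms` and `value`.")
  }
  if (is.null(onset_threshold)) onset_threshold <- 0.1 * max(abs(v))
  if (!is.numeric(onset_threshold) || onset_threshold <= 0 ||
      !any(abs(v) > onset_threshold)) {
    rlang::abort("no motion detected")
  }
  i0 <- which(abs(v) > onset_threshold)[1L]
  s0 <- sign(v[i0])
  for (k in seq(i0 + 1L, length.out = max(0L, length(v) - i0))) {
    if (v[k] == 0) return(t[k])
    if (sign(v[k]) != s0) {
      # linear interpolation between samples k-1 and k
      return(t[k - 1L] + v[k - 1L] / (v[k - 1L] - v[k]) * (t[k] - t[k - 1L]))
    }
  }
  rlang::abort("no impact detected")
}

#' Peak-to-peak MEP amplitude from an EMG trace
#'
#' Returns `max - min` of the EMG samples inside the response window.  The
#' caller is responsible for placing the window after the TMS pulse and
#' outside stimulation-artifact intervals (the CLI default is 10-60 ms after
#' `t_tms` with +/- 5 ms artifact masks).
#'
#' @param emg A data frame with columns `time_ms`, `value` (mV).
#' @param response_window An [isiw_window()] or `c(lower, upper)` in ms, lying
#'   within the trace's time span.
#' @return Peak-to-peak amplitude in mV (`>= 0`).
#' @export
extract_mep_amplitude <- function(emg, response_window) {
  w <- as_isiw_window(response_window)
  t <- emg$time_ms
  v <- emg$value
  if (is.null(t) || is.null(v)) rlang::abort("`emg` must have columns `time_ms` and `value`.")
  if (w$lower < min(t) || w$upper > max(t)) {
    rlang::abort("response window lies outside the trace")
  }
  inside <- t >= w$lower & t <= w$upper
  if (!any(inside)) rlang::abort("response window contains no samples")
  max(v[inside]) - min(v[inside])
}

#' Protocol configuration of the conventional incremental sweep
#'
#' Defaults reproduce the conventional protocol: 12 repetitions per ISI with
#' the first 2 discarded (startle response), 1 s per trial, 120 s rest after
#' each ISI block, 50 ISI steps of 5 ms, and two 600 s long breaks.
#'
#' @param reps_per_isi Repetitions per ISI (default 12).
#' @param discard_first Leading repetitions discarded per ISI (default 2).
#' @param trial_duration_s Seconds per stimulation trial (default 1).
#' @param rest_between_blocks_s Rest after each ISI block, s (default 120).
#' @param n_intervals Number of ISI grid steps (default 50).
#' @param long_breaks_s Long between-session breaks, s (default two of 600).
#' @param grid_step_ms ISI grid increment, ms (default 5).
#' @param grid_start_ms First grid ISI, ms (default 0, impact-referenced).
#' @param search_range_ms Length of the valve-referenced search range, ms
#'   (default 500).
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(reps_per_isi = 12, discard_first = 2,
                            trial_duration_s = 1, rest_between_blocks_s = 120,
                            n_intervals = 50, long_breaks_s = c(600, 600),
                            grid_step_ms = 5, grid_start_ms = 0,
                            search_range_ms = 500) {
  stopifnot(reps_per_isi >= 1, discard_first >= 0,
            grid_step_ms > 0, search_range_ms > 0, n_intervals >= 1,
            trial_duration_s >= 0, rest_between_blocks_s >= 0,
            all(long_breaks_s >= 0))
  if (discard_first >= reps_per_isi) {
    rlang::abort("`discard_first` must be < `reps_per_isi`.")
  }
  structure(
    list(reps_per_isi = reps_per_isi, discard_first = discard_first,
         trial_duration_s = trial_duration_s,
         rest_between_blocks_s = rest_between_blocks_s,
         n_intervals = n_intervals, long_breaks_s = long_breaks_s,
         grid_step_ms = grid_step_ms, grid_start_ms = grid_start_ms,
         search_range_ms = search_range_ms),
    class = "protocol_config"
  )
}

#' Trial and time budget of the incremental protocol
#'
#' Total trials and wall-clock seconds needed to sweep the full ISI grid:
#' `trials = reps_per_isi * n_intervals` and
#' `seconds = (trial_duration_s * reps_per_isi + rest_between_blocks_s) *
#' n_intervals + sum(long_breaks_s)`.  The defaults give 600 trials and
#' 7,800 s (130 min).
#'
#' @param protocol A [protocol_config()].
#' @return A one-row tibble with `total_trials`, `total_seconds`,
#'   `total_minutes`.
#' @examples
#' trial_budget(protocol_config())
#' @export
trial_budget <- function(protocol = protocol_config()) {
  stopifnot(inherits(protocol, "protocol_config"))
  trials <- protocol$reps_per_isi * protocol$n_intervals
  seconds <- (protocol$trial_duration_s * protocol$reps_per_isi +
                protocol$rest_between_blocks_s) * protocol$n_intervals +
    sum(protocol$long_breaks_s)
  tibble::tibble(total_trials = trials, total_seconds = seconds,
                 total_minutes = seconds / 60)
}
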