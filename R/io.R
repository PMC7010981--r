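#' Read and write trial logs
#'
#' Trial logs are CSV files with one row per trial and header
#' `trial_id, subject_id, t_valve_ms, t_tms_ms, t_hit_ms, isi_ms, mep_pp_mv`;
#' a missing impact time (no accelerometer) is an empty field.
#'
#' @param trials A data frame containing at least the log columns.
#' @param path File path.
#' @return `read_trial_log()` returns a tibble; `write_trial_log()` returns
#'   `path` invisibly.
#' @export
write_trial_log <- function(trials, path) {
  cols <- c("trial_id", "subject_id", "t_valve_ms", "t_tms_ms", "t_hit_ms",
            "isi_ms", "mep_pp_mv")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    rlang::abort(paste0("trial log is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  readr::write_csv(trials[cols], path, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_integer(),
      subject_id = readr::col_character(),
      t_valve_ms = readr::col_double(),
      t_tms_ms = readr::col_double(),
      t_hit_ms = readr::col_double(),
      isi_ms = readr::col_double(),
      mep_pp_mv = readr::col_double()
    )
  )
}

#' Read a sampled trace from CSV
#'
#' Expects columns `time_ms` and `value`; the sampling interval is inferred
#' from the time stamps and validated as uniform to a relative tolerance of
#' 1e-6.
#'
#' @param path File path.
#' @return A [sampled_trace()] tibble with attribute `sampling_interval`.
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, col_types = readr::cols(
    time_ms = readr::col_double(), value = readr::col_double()))
  if (nrow(tr) < 2) rlang::abort("trace must contain at least 2 samples")
  dt <- diff(tr$time_ms)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
    rlang::abort("trace is not uniformly sampled (relative tolerance 1e-6)")
  }
  attr(tr, "sampling_interval") <- dt[1]
  tr
}

#' Serialise a virtual subject's ground truth to JSON
#'
#' @param subject An [sample_subject()] result.
#' @param path File path.
#' @return `path`, invisibly; `read_subject_json()` returns the subject.
#' @export
write_subject_json <- function(subject, path) {
  stopifnot(inherits(subject, "isiw_subject"))
  jsonlite::write_json(
    list(profile = list(amplitude = subject$profile$amplitude,
                        center = subject$profile$center,
                        width = subject$profile$width),
         t_delay = subject$t_delay,
         baseline_mep = subject$baseline_mep,
         noise_cv = subject$noise_cv,
         delay_jitter_sd = subject$delay_jitter_sd,
         true_window = list(lower = subject$true_window$lower,
                            upper = subject$true_window$upper),
         isi_span = subject$isi_span,
         seed = subject$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subject_json
#' @export
read_subject_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- gaussian_model(j$profile$amplitude, j$profile$center, j$profile$width)
  structure(
    list(profile = profile, t_delay = j$t_delay,
         baseline_mep = j$baseline_mep, noise_cv = j$noise_cv,
         delay_jitter_sd = j$delay_jitter_sd,
         true_window = window_from_gaussian(profile),
         isi_span = j$isi_span, seed = as.integer(j$seed)),
    class = "isiw_subject"
  )
}

#' Serialise an estimation result to JSON
#'
#' @param estimate An [estimate_isi_window()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "isiw_estimate"))
  jsonlite::write_json(
    list(method = estimate$method,
         window = list(lower = estimate$window$lower,
                       upper = estimate$window$upper,
                       length = estimate$window$length,
                       edge_lower = estimate$window$edge_lower,
                       edge_upper = estimate$window$edge_upper),
         converged = estimate$converged,
         n_observations = estimate$n_observations,
         curve = list(isi = estimate$curve$isi, mep = estimate$curve$mep),
         observations = list(iteration = estimate$observations$iteration,
                             isi = estimate$observations$isi,
                             mep = estimate$observations$mep),
         end_history = list(iteration = estimate$end_history$iteration,
                            lower = estimate$end_history$lower,
                            upper = estimate$end_history$upper),
         seed = estimate$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert an estimation result's observation log to a trial log
#'
#' Reconstructs nominal event times from the observed ISIs: the valve fires
#' at `t_valve`, the impact at `t_valve + delay`, TMS at `impact + isi`.
#'
#' @param estimate An [estimate_isi_window()] result.
#' @param delay Hammer delay used for the reconstruction, ms.
#' @param t_valve Valve command time, ms.
#' @param subject_id Identifier written to the log.
#' @return A trial-log tibble (see [write_trial_log()]).
#' @export
estimate_trial_log <- function(estimate, delay = 195.5, t_valve = 50,
                               subject_id = "estimate") {
  obs <- estimate$observations
  t_hit <- t_valve + delay
  tibble::tibble(
    trial_id = seq_len(nrow(obs)),
    subject_id = subject_id,
    t_valve_ms = t_valve,
    t_tms_ms = t_hit + obs$isi,
    t_hit_ms = t_hit,
    isi_ms = obs$isi,
    mep_pp_mv = obs$mep
  )
}
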