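# Shared fixtures, all generated in code.

# The canonical single-Gaussian subject of the worked example: profile
# centred at 40 ms with sigma 17.5 ms, so the true two-sigma window is
# [5, 75] ms (length 70 ms).
canonical_subject <- function(noise_cv = 0, amplitude = 1, baseline = 0.05) {
  profile <- gaussian_model(amplitude, 40, 17.5)
  structure(
    list(profile = profile, t_delay = 195.5, baseline_mep = baseline,
         noise_cv = noise_cv, delay_jitter_sd = 0,
         true_window = window_from_gaussian(profile),
         isi_span = 304.5, seed = 0L),
    class = "isiw_subject"
  )
}

quick_config <- function(method = "GPR", ...) {
  estimator_config(method, search_lower = 0, search_upper = 304.5, ...)
}

# Direct evaluation of a noiseless measurement (oracle for measure_mep)
expected_mep <- function(subject, isi) {
  subject$baseline_mep + subject$profile$amplitude *
    exp(-(isi - subject$profile$center)^2 / (2 * subject$profile$width^2))
}

max_end_error <- function(window, truth) {
  truth <- isiwin:::as_isiw_window(truth)
  max(abs(window$lower - truth$lower), abs(window$upper - truth$upper))
}
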