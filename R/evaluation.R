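#' Interval-overlap F1 score between two ISI windows
#'
#' Treating the windows as continuous intervals: the true-positive mass is
#' the length of their intersection, false positives the estimated length
#' outside truth, false negatives the truth length outside the estimate, and
#' `F1 = 2 TP / (2 TP + FP + FN)`.  Identical windows score 1; disjoint
#' windows score 0.  The score is symmetric and invariant under a common
#' time translation.
#'
#' @param estimated,truth [isiw_window()]s or `c(lower, upper)` pairs, ms.
#' @return F1 score in `[0, 1]`.
#' @examples
#' f1_interval(c(0, 100), c(50, 150)) # 0.5
#' @export
f1_interval <- function(estimated, truth) {
  e <- as_isiw_window(estimated)
  t <- as_isiw_window(truth)
  if (t$length <= 0) rlang::abort("zero-length truth window: F1 undefined")
  tp <- max(0, min(e$upper, t$upper) - max(e$lower, t$lower))
  fp <- e$length - tp
  fn <- t$length - tp
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Pearson correlation between an estimated and a measured MEP profile
#'
#' Pearson product-moment correlation of the two curves' values on a common
#' ISI grid.  When the curves are tabled on different grids the estimated
#' curve is linearly interpolated onto the measured grid first.
#'
#' @param estimated,measured Data frames with columns `isi` and `mep`, or
#'   plain numeric vectors already on a common grid.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
profile_correlation <- function(estimated, measured) {
  if (is.numeric(estimated) && is.numeric(measured)) {
    a <- estimated; b <- measured
  } else {
    a_isi <- estimated$isi; a_val <- estimated$mep
    b_isi <- measured$isi; b_val <- measured$mep
    if (is.null(a_isi) || is.null(b_isi)) {
      rlang::abort("curves must have columns `isi` and `mep` (or be numeric vectors).")
    }
    interp <- stats::approx(a_isi, a_val, xout = b_isi, rule = 1)
    ok <- !is.na(interp$y)
    a <- interp$y[ok]; b <- b_val[ok]
  }
  if (length(a) < 3) rlang::abort("need at least 3 common grid points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("constant curve: correlation undefined")
  }
  stats::cor(a, b)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning a tidy one-row
#' tibble, with the decision at `alpha = 0.05` ("normal" when the null of
#' normality is not rejected).
#'
#' @param samples Numeric vector, `n >= 3`, not all equal.
#' @param alpha Significance level for the decision column.
#' @return A tibble with columns `statistic` (W), `p_value`, `n`, `normal`.
#' @export
shapiro_wilk <- function(samples, alpha = 0.05) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 3) rlang::abort("need at least 3 samples")
  if (stats::sd(samples) == 0) rlang::abort("constant samples: test undefined")
  ht <- stats::shapiro.test(samples)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(samples), normal = ht$p.value >= alpha)
}

#' Normality of a measured MEP profile treated as a distribution over ISI
#'
#' The enhancement profile is interpreted as an (unnormalised) density over
#' ISI: grid ISIs are resampled with weights proportional to the mean
#' enhancement above baseline (with uniform within-bin jitter to undo the
#' grid discretisation) and the resample is submitted to the Shapiro-Wilk
#' test.  For single-Gaussian subjects the resample is approximately normal,
#' so the null is usually not rejected.
#'
#' @param profile A data frame with columns `isi` and `mean_mep` (e.g. the
#'   `profile` of an [incremental_sweep()]).
#' @param baseline Baseline MEP, mV.
#' @param n_draws Resample size (default 50).
#' @param seed Integer seed for the resampling.
#' @return A [shapiro_wilk()] tibble.
#' @export
profile_normality <- function(profile, baseline = 0, n_draws = 50, seed = 1L) {
  w <- pmax(profile$mean_mep - baseline, 0)
  if (sum(w) <= 0) rlang::abort("no enhancement above baseline")
  step <- stats::median(diff(sort(unique(profile$isi))))
  withr::with_seed(as.integer(seed), {
    draws <- sample(profile$isi, n_draws, replace = TRUE, prob = w) +
      stats::runif(n_draws, -step / 2, step / 2)
    shapiro_wilk(draws)
  })
}

#' Percentage of estimation runs that converged
#'
#' @param results A list of [estimate_isi_window()] results (or a logical
#'   vector of convergence flags).
#' @return Percentage in `[0, 100]`.
#' @export
convergence_percentage <- function(results) {
  flags <- if (is.logical(results)) results else purrr::map_lgl(results, "converged")
  if (!length(flags)) rlang::abort("empty result list")
  100 * mean(flags)
}

#' Benchmark the estimators on a synthetic population
#'
#' For every (method, n_ini, accelerometer-mode) cell: simulates the same set
#' of virtual subjects, runs the incremental sweep to obtain each subject's
#' ground-truth window and measured profile, runs the adaptive estimator, and
#' aggregates interval F1, profile correlation, observation counts and
#' convergence.  Accelerometer mode starts the search range at the detected
#' impact (ISI 0); valve mode spans `[-delay, span]` in impact-referenced
#' coordinates and adds per-trial delay jitter to every query.  NR cells with
#' `n_ini < 4` are marked unavailable.  The whole report is reproducible from
#' `seed`.
#'
#' @param pop A [population_params()].
#' @param methods Character vector among `"NR"`, `"SVMR"`, `"GPR"`, `"PF"`.
#' @param n_ini_values Integer vector of initial observation counts (ignored
#'   for PF, reported once per mode with `n_ini = NA`).
#' @param accelerometer Logical vector of modes to run (default both
#'   `c(TRUE, FALSE)`).
#' @param n_subjects Number of virtual subjects per cell (>= 2).
#' @param seed Integer seed.
#' @param keep_runs Keep the per-subject results in the `runs` attribute.
#' @return A tibble of class `isiw_benchmark`, one row per cell: `method`,
#'   `n_ini`, `accelerometer`, `n_subjects`, `available`, `mean_n_obs`,
#'   `sd_n_obs`, `mean_f1`, `sd_f1`, `mean_correlation`, `convergence_pct`.
#' @export
run_benchmark <- function(pop = population_params(),
                          methods = c("NR", "SVMR", "GPR", "PF"),
                          n_ini_values = 7,
                          accelerometer = c(TRUE, FALSE),
                          n_subjects = 20,
                          seed = 1L,
                          keep_runs = FALSE) {
  stopifnot(n_subjects >= 2)
  seed <- as.integer(seed)
  span <- pop$search_range_ms - pop$delay_mean
  step <- 5
  subjects <- purrr::map(seq_len(n_subjects), ~ sample_subject(pop, seed + .x))

  # incremental-sweep ground truth, once per subject
  sweep_protocol <- protocol_config(
    n_intervals = floor(span / step) + 1L, grid_step_ms = step,
    search_range_ms = pop$search_range_ms)
  sweeps <- purrr::imap(subjects, function(s, i) {
    incremental_sweep(s, sweep_protocol, seed = seed + 10000L + i)
  })

  cells <- tidyr::expand_grid(
    method = methods, n_ini = n_ini_values, accelerometer = accelerometer) |>
    dplyr::distinct(
      .data$method,
      n_ini = dplyr::if_else(.data$method == "PF", NA_integer_,
                             as.integer(.data$n_ini)),
      .data$accelerometer)

  run_cell <- function(method, n_ini, acc) {
    if (method == "NR" && !is.na(n_ini) && n_ini < 4) return(NULL)
    runs <- purrr::imap(subjects, function(s, i) {
      lo <- if (acc) 0 else -s$t_delay
      hi <- span
      cfg <- estimator_config(
        method = method, n_ini = if (is.na(n_ini)) 7 else n_ini,
        search_lower = lo, search_upper = hi, grid_step = step,
        seed = seed + 20000L + i)
      est <- tryCatch(
        estimate_isi_window(s, cfg, valve_referenced = !acc),
        error = function(e) NULL)
      sw <- sweeps[[i]]
      if (is.null(est) || is.null(sw$window)) {
        return(list(est = est, f1 = NA_real_, r = NA_real_,
                    n_obs = if (is.null(est)) NA_real_ else est$n_observations,
                    converged = if (is.null(est)) FALSE else est$converged))
      }
      r <- tryCatch(
        profile_correlation(est$curve,
                            dplyr::rename(sw$profile, mep = "mean_mep")),
        error = function(e) NA_real_)
      list(est = est, f1 = f1_interval(est$window, sw$window), r = r,
           n_obs = est$n_observations, converged = est$converged)
    })
    runs
  }

  all_runs <- list()
  report <- purrr::pmap(cells, function(method, n_ini, accelerometer) {
    runs <- run_cell(method, n_ini, accelerometer)
    base <- tibble::tibble(method = method, n_ini = n_ini,
                           accelerometer = accelerometer,
                           n_subjects = n_subjects)
    if (is.null(runs)) {
      return(dplyr::mutate(base, available = FALSE,
                           mean_n_obs = NA_real_, sd_n_obs = NA_real_,
                           mean_f1 = NA_real_, sd_f1 = NA_real_,
                           mean_correlation = NA_real_,
                           convergence_pct = NA_real_))
    }
    if (keep_runs) {
      all_runs[[paste(method, n_ini, accelerometer, sep = "_")]] <<- runs
    }
    f1 <- purrr::map_dbl(runs, "f1")
    nobs <- purrr::map_dbl(runs, "n_obs")
    rr <- purrr::map_dbl(runs, "r")
    dplyr::mutate(base, available = TRUE,
                  mean_n_obs = mean(nobs, na.rm = TRUE),
                  sd_n_obs = stats::sd(nobs, na.rm = TRUE),
                  mean_f1 = mean(f1, na.rm = TRUE),
                  sd_f1 = stats::sd(f1, na.rm = TRUE),
                  mean_correlation = mean(rr, na.rm = TRUE),
                  convergence_pct = convergence_percentage(
                    purrr::map_lgl(runs, "converged")))
  }) |> dplyr::bind_rows()

  out <- structure(report, class = c("isiw_benchmark", class(report)))
  attr(out, "seed") <- seed
  if (keep_runs) attr(out, "runs") <- all_runs
  attr(out, "subjects") <- subjects
  attr(out, "sweeps") <- sweeps
  out
}

#' @export
tidy.isiw_benchmark <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
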