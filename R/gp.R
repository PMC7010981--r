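# Gaussian process regression with a squared-exponential kernel, used by the
# GPR estimator.  Hyperparameters (signal variance, length scale, noise
# variance) are fitted by maximising the log marginal likelihood; the small
# problem sizes here (tens of observations) make the Cholesky-based exact
# posterior cheap.

se_kernel <- function(x1, x2, s2, ell) {
  d <- outer(x1, x2, "-")
  s2 * exp(-0.5 * (d / ell)^2)
}

gp_loglik <- function(logpar, x, y) {
  s2 <- exp(logpar[1]); ell <- exp(logpar[2]); noise <- exp(logpar[3])
  K <- se_kernel(x, x, s2, ell)
  diag(K) <- diag(K) + noise + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

#' Fit a Gaussian process regression to (ISI, MEP) observations
#'
#' Exact GP regression with a squared-exponential kernel
#' `k(x, x') = s2 * exp(-(x - x')^2 / (2 * ell^2))` plus i.i.d. Gaussian
#' observation noise and a zero prior mean (the modelled quantity is the
#' enhancement above baseline, which decays to zero away from the window).
#' The length scale is initialised at 25 ms (five grid steps of the 5 ms ISI
#' grid, matching the smooth unimodal enhancement profiles being modelled)
#' and all three hyperparameters are refined by maximising the log marginal
#' likelihood.
#'
#' @param data A data frame with numeric columns `isi` (ms) and `mep` (mV).
#' @param lengthscale_init Initial kernel length scale, ms.
#' @return An object of class `gp_fit` (kernel hyperparameters, training
#'   data, Cholesky factor); use [gp_predict()] for the posterior.
#' @export
gp_fit <- function(data, lengthscale_init = 25) {
  x <- data$isi
  y <- data$mep
  if (is.null(x) || is.null(y)) rlang::abort("`data` must have columns `isi` and `mep`.")
  stopifnot(length(x) >= 2)
  # zero prior mean: the modelled quantity is the enhancement above
  # baseline, which decays to zero away from the window
  m <- 0
  yc <- y - m
  v <- stats::var(yc)
  if (!is.finite(v) || v <= 0) v <- 1e-6
  init <- log(c(v, lengthscale_init, 0.1 * v))
  opt <- tryCatch(
    stats::optim(init, gp_loglik, x = x, y = yc, method = "L-BFGS-B",
                 lower = log(c(1e-8, 1, 1e-10)),
                 upper = log(c(1e4, 1e3, 1e4))),
    error = function(e) list(par = init)
  )
  s2 <- exp(opt$par[1]); ell <- exp(opt$par[2]); noise <- exp(opt$par[3])
  K <- se_kernel(x, x, s2, ell)
  diag(K) <- diag(K) + noise + 1e-8
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(
    list(x = x, y = y, y_mean = m, s2 = s2, ell = ell, noise = noise,
         chol = ch, alpha = alpha),
    class = "gp_fit"
  )
}

#' Posterior mean and variance of a fitted GP
#'
#' @param fit A [gp_fit()].
#' @param isi ISIs (ms) at which to evaluate the posterior.
#' @return A tibble with columns `isi`, `mean` (posterior predictive mean)
#'   and `var` (posterior variance of the latent function, excluding
#'   observation noise).
#' @export
gp_predict <- function(fit, isi) {
  stopifnot(inherits(fit, "gp_fit"))
  Ks <- se_kernel(isi, fit$x, fit$s2, fit$ell)
  mu <- drop(Ks %*% fit$alpha) + fit$y_mean
  Vh <- forwardsolve(t(fit$chol), t(Ks))
  v <- pmax(fit$s2 - colSums(Vh^2), 0)
  tibble::tibble(isi = isi, mean = mu, var = v)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<GP fit> n = %d, signal sd = %.4g, length scale = %.4g ms, noise sd = %.4g\n",
    length(x$x), sqrt(x$s2), x$ell, sqrt(x$noise)))
  invisible(x)
}
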