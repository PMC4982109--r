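#' Covariance kernels for Gaussian-process model components
#'
#' Closed-form covariance matrices on an arbitrary finite grid of observation
#' times (in years) for the stochastic-process components used in the extended
#' linear mixed models: scaled Brownian motion, scaled fractional Brownian
#' motion, and the exponential-decay residual correlation structure.
#'
#' * `bm_cov()`: scaled Brownian motion, `Cov[W_s, W_t] = kappa * min(s, t)`.
#'   The process starts at zero, so rows/columns for `t = 0` are zero.
#' * `fbm_cov()`: scaled fractional Brownian motion with Hurst index `H` in
#'   (0, 1), `Cov[W_s, W_t] = (kappa / 2) * (|s|^(2H) + |t|^(2H) - |t - s|^(2H))`,
#'   so `Var[W_t] = kappa * |t|^(2H)` and `kappa` is the process variance at
#'   `t = 1`.  `H = 0.5` recovers standard Brownian motion; `H < 0.5` gives
#'   negatively correlated (mean-reverting, jagged) increments and `H > 0.5`
#'   positively correlated (trending) increments.
#' * `expcor_cov()`: exponential-decay residual correlation,
#'   `r_jk = sigma^2 * exp(-|t_j - t_k| / gamma_range)`.
#'
#' All three return symmetric positive semi-definite matrices; the assembled
#' model covariance remains positive definite because an independent
#' measurement-error variance is always present.
#'
#' @param times numeric vector of non-negative observation times (years),
#'   sorted non-decreasing; duplicates are permitted.
#' @param kappa positive process scale (variance at `t = 1`).
#' @param hurst Hurst index, strictly inside (0, 1).
#' @param sigma positive residual standard deviation.
#' @param gamma_range positive range parameter of the exponential decay
#'   (years).
#'
#' @return An `n x n` symmetric numeric matrix, `n = length(times)`.
#' @examples
#' bm_cov(c(1, 2), kappa = 2)
#' fbm_cov(c(0.5, 1.5, 3), kappa = 1, hurst = 0.5)  # equals bm_cov()
#' expcor_cov(c(0, 0.03), sigma = 2.79, gamma_range = 0.03)
#' @name kernels
NULL

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L) {
    stop("`times` must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (anyNA(times) || any(times < 0)) {
    stop("`times` must be non-negative and free of NA", call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("`times` must be sorted non-decreasing", call. = FALSE)
  }
  as.numeric(times)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  as.numeric(x)
}

#' @rdname kernels
#' @export
bm_cov <- function(times, kappa) {
  times <- check_times(times)
  kappa <- check_positive(kappa, "kappa")
  kappa * outer(times, times, pmin)
}

#' @rdname kernels
#' @export
fbm_cov <- function(times, kappa, hurst) {
  times <- check_times(times)
  kappa <- check_positive(kappa, "kappa")
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst >= 1) {
    stop("`hurst` must lie strictly inside (0, 1)", call. = FALSE)
  }
  h2 <- 2 * hurst
  t2h <- times^h2  # 0^(2H) == 0 for all H in (0,1)
  (kappa / 2) * (outer(t2h, t2h, `+`) - abs(outer(times, times, `-`))^h2)
}

#' @rdname kernels
#' @export
expcor_cov <- function(times, sigma, gamma_range) {
  times <- check_times(times)
  sigma <- check_positive(sigma, "sigma")
  gamma_range <- check_positive(gamma_range, "gamma_range")
  sigma^2 * exp(-abs(outer(times, times, `-`)) / gamma_range)
}
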