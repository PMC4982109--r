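# Per-subject Mahalanobis statistics at the fitted parameters.
fit_delta2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (is.null(fit$params)) stop("fit has no parameter estimates", call. = FALSE)
  spec <- fit$spec
  p <- fit$params
  groups <- group_longdata(fit$data, spec)
  beta <- c(p[["beta0"]], p[["beta1"]])
  if (spec$two_group) beta <- c(beta, p[["delta0"]], p[["delta1"]])
  d2 <- cpp_delta2(groups, beta, p[["U00"]], p[["rho"]], p[["U11"]],
                   p[["sigma"]], process_code(spec$process),
                   if (spec$process %in% c("bm", "fbm")) p[["kappa"]] else 0,
                   if (spec$process == "fbm") p[["hurst"]] else 0.5,
                   if (spec$process == "expcor") p[["gamma_range"]] else 1)
  tibble::tibble(
    id = unlist(lapply(groups, `[[`, "ids"), use.names = FALSE),
    n_i = unlist(lapply(groups, function(g)
      rep(length(g$times), ncol(g$Y))), use.names = FALSE),
    delta2 = pmax(unlist(d2, use.names = FALSE), 0))
}

DEVIATE_SENTINEL <- 8

#' Subject-level residual statistics
#'
#' For each subject computes the Mahalanobis statistic
#' `delta2 = (y - X b)' V^{-1} (y - X b)` at the fitted parameters and maps
#' it to a standard-normal deviate through its reference distribution:
#' chi-squared with `n_i` degrees of freedom under the normal marginal, and
#' `delta2 / n_i ~ F(n_i, df_hat)` under the multivariate-t marginal.  Under
#' a correctly specified model the deviates are standard normal, so their
#' Q-Q plot against N(0,1) is a subject-level goodness-of-fit display.
#' Deviates are clipped to +/- 8 (a zero residual vector would otherwise map
#' to -Inf).
#'
#' @param fit a converged `mixed_fit`.
#' @return A tibble with `id`, `n_i`, `delta2`, `normal_deviate`.
#' @export
subject_stats <- function(fit) {
  tb <- fit_delta2(fit)
  p <- if (fit$spec$marginal == "normal") {
    stats::pchisq(tb$delta2, df = tb$n_i)
  } else {
    stats::pf(tb$delta2 / tb$n_i, df1 = tb$n_i, df2 = fit$params[["df"]])
  }
  dev <- stats::qnorm(p)
  tb$normal_deviate <- pmin(pmax(dev, -DEVIATE_SENTINEL), DEVIATE_SENTINEL)
  tb
}

#' Posterior of the latent scale variables under a multivariate-t fit
#'
#' Conditional on the data, each subject's latent scale follows
#' `tau_i | y_i ~ gamma((v + n_i)/2, (v + delta2_i)/2)` (shape/rate), with
#' empirical Bayes mean `tau_hat = (v + n_i) / (v + delta2_i)`.  Small
#' `tau_hat` identifies subjects whose trajectories are more variable than
#' the population scale matrix implies.
#'
#' @param fit a converged `mixed_fit` with `marginal = "t"`.
#' @return A tibble with `id`, `n_i`, `delta2`, `shape`, `rate`, `tau_hat`.
#' @export
tau_posterior <- function(fit) {
  if (fit$spec$marginal != "t") {
    stop("tau posterior is defined only for multivariate-t fits",
         call. = FALSE)
  }
  tb <- fit_delta2(fit)
  v <- fit$params[["df"]]
  tb$shape <- (v + tb$n_i) / 2
  tb$rate <- (v + tb$delta2) / 2
  tb$tau_hat <- tb$shape / tb$rate
  tb
}

# Cholesky-transformed residuals L^{-1}(y - X b) per subject, grouped.
base_residuals <- function(fit) {
  spec <- fit$spec
  p <- fit$params
  groups <- group_longdata(fit$data, spec)
  beta <- c(p[["beta0"]], p[["beta1"]])
  if (spec$two_group) beta <- c(beta, p[["delta0"]], p[["delta1"]])
  purrr::map_dfr(groups, function(g) {
    sm <- assemble_scale_matrix(g$times, spec, p,
                                group = if (spec$two_group) g$group else NULL)
    E <- g$Y - as.numeric(g$X %*% beta)
    U <- forwardsolve(sm$L, E)
    tibble::tibble(id = rep(g$ids, each = length(g$times)),
                   time = rep(g$times, times = ncol(g$Y)),
                   residual = as.numeric(U))
  })
}

#' Cholesky-transformed measurement-level residuals
#'
#' Transforms each subject's marginal residuals `y_i - X_i b` by the inverse
#' of the lower Cholesky factor of a per-subject covariance matrix:
#'
#' * `"mvn"` (normal fits): covariance `V_i`; under a correct model the
#'   residuals are iid standard normal.
#' * `"t_eb"` (t fits): covariance `V_i / tau_hat_i` with the empirical
#'   Bayes estimate of the latent scale.
#' * `"t_sampled"` (t fits): `n_draws` independent samples of the full
#'   latent vector tau from the per-subject gamma posteriors, one residual
#'   set per draw (column `draw`); feeds [composite_qq_bands()].
#' * `"t_none"` (t fits): scale matrix `V_i` with no latent-scale
#'   correction; per-subject Q-Q plots then have slope about
#'   `tau_i^(-1/2)`.
#'
#' @param fit a converged `mixed_fit`.
#' @param mode one of `"mvn"`, `"t_eb"`, `"t_sampled"`, `"t_none"`.
#' @param n_draws number of posterior draws for `"t_sampled"`.
#' @param seed integer seed for `"t_sampled"`.
#' @return A tibble `id`, `time`, `residual` (plus `draw` for
#'   `"t_sampled"`), of class `residual_set` with attribute `mode`.
#' @export
cholesky_residuals <- function(fit, mode = c("mvn", "t_eb", "t_sampled",
                                             "t_none"),
                               n_draws = 1000, seed = NULL) {
  mode <- match.arg(mode)
  is_t <- fit$spec$marginal == "t"
  if (mode == "mvn" && is_t) {
    stop("mode 'mvn' applies to normal fits; use a t_* mode", call. = FALSE)
  }
  if (mode != "mvn" && !is_t) {
    stop("t_* modes require a multivariate-t fit", call. = FALSE)
  }
  r0 <- base_residuals(fit)
  out <- switch(mode,
    mvn = , t_none = r0,
    t_eb = {
      tp <- tau_posterior(fit)
      r0$residual <- r0$residual * sqrt(tp$tau_hat[match(r0$id, tp$id)])
      r0
    },
    t_sampled = {
      tp <- tau_posterior(fit)
      i <- match(r0$id, tp$id)
      draws <- with_seed(seed, {
        matrix(rgamma(nrow(tp) * n_draws, shape = tp$shape, rate = tp$rate),
               nrow = nrow(tp), ncol = n_draws)
      })
      purrr::map_dfr(seq_len(n_draws), function(k) {
        tibble::tibble(draw = k, id = r0$id, time = r0$time,
                       residual = r0$residual * sqrt(draws[i, k]))
      })
    })
  attr(out, "mode") <- mode
  class(out) <- c("residual_set", class(out))
  out
}

#' Composite Q-Q bands over posterior draws of the latent scales
#'
#' From a `"t_sampled"` residual set, sorts each draw's residuals and
#' summarises, at every order-statistic position, the 2.5th, 50th and
#' 97.5th percentiles of the sample quantiles across draws.  Theoretical
#' quantiles are the standard-normal plotting positions
#' `qnorm((i - 0.5) / n)`.
#'
#' @param sampled a `residual_set` with a `draw` column (or any tibble with
#'   columns `draw`, `residual`; all draws must have equal length).
#' @return A tibble `theoretical`, `q025`, `q50`, `q975` of class
#'   `qq_bands`.
#' @export
composite_qq_bands <- function(sampled) {
  if (!"draw" %in% names(sampled)) {
    stop("need a sampled residual set (column `draw`)", call. = FALSE)
  }
  sizes <- table(sampled$draw)
  if (length(unique(as.integer(sizes))) != 1L) {
    stop("draws have unequal lengths", call. = FALSE)
  }
  n <- as.integer(sizes[1])
  M <- vapply(split(sampled$residual, sampled$draw), sort, numeric(n))
  qs <- t(apply(M, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  structure(tibble::tibble(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                           q025 = qs[, 1], q50 = qs[, 2], q975 = qs[, 3]),
            class = c("qq_bands", class(tibble::tibble())))
}

#' Per-subject Q-Q data for subjects with many observations
#'
#' Selects a seeded random sample of subjects with at least `min_obs`
#' measurements and returns, for each, the sorted uncorrected residuals
#' (`"t_none"` mode) against standard-normal plotting positions.  Under a
#' correct multivariate-t model each subject's points fall near a line of
#' slope `tau_i^(-1/2)`; the empirical Bayes estimate `tau_hat` and the
#' implied slope are attached per subject.
#'
#' @param fit a converged multivariate-t `mixed_fit`.
#' @param min_obs minimum number of observations for a subject to qualify
#'   (16 keeps subjects with more than 15 measurements).
#' @param n_subjects number of subjects to sample; if fewer qualify, all are
#'   returned with a warning.
#' @param seed integer seed for the sample.
#' @return A tibble `id`, `theoretical`, `residual`, `tau_hat`,
#'   `expected_slope`.
#' @export
per_subject_qq <- function(fit, min_obs = 16, n_subjects = 25, seed = NULL) {
  if (fit$spec$marginal != "t") {
    stop("per-subject Q-Q panels target multivariate-t fits", call. = FALSE)
  }
  tp <- tau_posterior(fit)
  qual <- tp$id[tp$n_i >= min_obs]
  if (length(qual) == 0L) stop("no subject has enough observations",
                               call. = FALSE)
  if (length(qual) < n_subjects) {
    warning("only ", length(qual), " subjects qualify; returning all")
    pick <- qual
  } else {
    pick <- with_seed(seed, sample(qual, n_subjects))
  }
  r0 <- cholesky_residuals(fit, "t_none")
  purrr::map_dfr(pick, function(s) {
    r <- sort(r0$residual[r0$id == s])
    th <- tp$tau_hat[tp$id == s]
    tibble::tibble(id = s,
                   theoretical = stats::qnorm((seq_along(r) - 0.5) /
                                                length(r)),
                   residual = r,
                   tau_hat = th,
                   expected_slope = th^(-0.5))
  })
}

#' @export
autoplot.residual_set <- function(object, ...) {
  if ("draw" %in% names(object)) {
    return(autoplot(composite_qq_bands(object)))
  }
  r <- sort(object$residual)
  df <- tibble::tibble(theoretical = stats::qnorm((seq_along(r) - 0.5) /
                                                    length(r)),
                       sample = r)
  ggplot2::ggplot(df, ggplot2::aes(.data$theoretical, .data$sample)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "Theoretical quantile", y = "Sample quantile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qq_bands <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theoretical)) +
    ggplot2::geom_abline(colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q025), linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q975), linetype = 3) +
    ggplot2::labs(x = "Theoretical quantile", y = "Sample quantile") +
    ggplot2::theme_minimal()
}

#' Q-Q panels for a per-subject residual table
#'
#' @param qq output of [per_subject_qq()].
#' @return A ggplot with one facet per subject.
#' @export
plot_subject_qq <- function(qq) {
  ggplot2::ggplot(qq, ggplot2::aes(.data$theoretical, .data$residual)) +
    ggplot2::geom_abline(ggplot2::aes(slope = .data$expected_slope,
                                      intercept = 0),
                         colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~id, scales = "free_y") +
    ggplot2::labs(x = "Theoretical quantile", y = "Residual") +
    ggplot2::theme_minimal()
}
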