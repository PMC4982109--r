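#' Control settings for model fitting
#'
#' @param maxit maximum BFGS iterations.
#' @param reltol relative convergence tolerance on the objective.
#' @param hess_step finite-difference step for the observed information
#'   (central differences on the transformed scale).
#' @param n_restarts number of jittered restarts attempted when the first
#'   optimisation does not converge.
#' @return A list of control settings.
#' @export
fit_control <- function(maxit = 500L, reltol = 1e-8, hess_step = 1e-4,
                        n_restarts = 1L) {
  list(maxit = as.integer(maxit), reltol = reltol, hess_step = hess_step,
       n_restarts = as.integer(n_restarts))
}

# Moment-based starting values for the random-slopes model.
start_rs <- function(data, spec) {
  fml <- if (spec$two_group) y ~ time + group + group:time else y ~ time
  lf <- stats::lm(fml, data = data)
  cf <- stats::coef(lf)
  r <- stats::resid(lf)
  sub_mean <- tapply(r, data$id, mean)
  nper <- tapply(r, data$id, length)
  s2b <- stats::var(sub_mean)
  within <- tapply(r, data$id, function(v) if (length(v) > 1) stats::var(v) else NA_real_)
  s2w <- mean(within, na.rm = TRUE)
  if (!is.finite(s2w)) s2w <- stats::var(r)
  if (!is.finite(s2b) || s2b <= 0) s2b <- stats::var(r) / 2
  tsc <- mean(data$time^2) + 1
  vals <- list(beta0 = unname(cf[["(Intercept)"]]), beta1 = unname(cf[["time"]]),
               U00 = max(s2b, 1e-2), rho = 0,
               U11 = max(s2w / 2, 1e-2) / tsc,
               sigma = sqrt(max(s2w / 2, 1e-2)))
  if (spec$two_group) {
    vals$delta0 <- unname(cf[["group"]])
    vals$delta1 <- unname(cf[["time:group"]])
  }
  vals
}

# Default starting values: the random-slopes fit seeds richer models; new
# components start at kappa = 1, H = 0.5, gamma = 0.25 years, df = 10.
default_start <- function(data, spec, control) {
  base_spec <- lmm_spec("none", "normal", spec$two_group)
  vals <- if (spec$process == "none" && spec$marginal == "normal") {
    start_rs(data, spec)
  } else {
    rs <- fit_mixed(data, base_spec, control = control, ladder = FALSE)
    if (rs$failed) start_rs(data, base_spec) else as.list(as.numeric(rs$params))
  }
  if (is.null(names(vals)) || !("beta0" %in% names(vals))) {
    names(vals) <- param_names(base_spec)
  }
  vals <- vals[param_names(base_spec)]
  if (spec$process %in% c("bm", "fbm")) vals$kappa <- 1
  if (spec$process == "fbm") vals$hurst <- 0.5
  if (spec$process == "expcor") vals$gamma_range <- 0.25
  if (spec$marginal == "t") vals$df <- 10
  do.call(lmm_params, c(list(spec), vals[param_names(spec)]))
}

#' Fit an extended linear mixed model by maximum likelihood
#'
#' Maximises the marginal log-likelihood over the unconstrained
#' (transformed) parameter vector with a quasi-Newton (BFGS) search.
#' Starting values follow a ladder: a moment-based random-slopes fit seeds
#' richer models, with new components initialised at `kappa = 1`,
#' `H = 0.5`, `gamma_range = 0.25` and `df = 10`.  The observed-information
#' covariance matrix of the transformed estimates is obtained by central
#' finite differences at the optimum.  A fit is recorded as *failed* when
#' parameter estimates are not returned or when the covariance matrix of the
#' estimates is not positive definite; failed fits are excluded from study
#' summaries downstream.
#'
#' @param data long-format data frame (see [as_longdata()]); at least two
#'   subjects.
#' @param spec an [lmm_spec()].
#' @param start optional [lmm_params()] starting values (skips the ladder).
#' @param control a [fit_control()] list.
#' @param seed integer seed for the jittered restart (only drawn on if the
#'   first optimisation fails to converge).
#' @param ladder internal; set `FALSE` to force moment-based starts.
#' @return An object of class `mixed_fit`: a list with elements `spec`,
#'   `params` (natural-scale estimates), `theta` (transformed estimates),
#'   `vcov` (transformed scale), `loglik`, `bic`, `n_obs`, `n_subjects`,
#'   `k`, `converged`, `failed`, `boundary` (character vector of flagged
#'   parameters) and the fitted `data`.
#' @examples
#' fx <- make_fixture("tiny_rs", seed = 1)
#' fit <- fit_mixed(fx, lmm_spec("none"))
#' glance(fit)
#' @export
fit_mixed <- function(data, spec, start = NULL, control = fit_control(),
                      seed = NULL, ladder = TRUE) {
  stopifnot(inherits(spec, "lmm_spec"))
  data <- as_longdata(data)
  if (length(unique(data$id)) < 2L) {
    stop("need at least two subjects", call. = FALSE)
  }
  groups <- group_longdata(data, spec)
  nm <- param_names(spec)

  if (is.null(start)) {
    start <- if (ladder) default_start(data, spec, control) else {
      vals <- start_rs(data, lmm_spec("none", "normal", spec$two_group))
      if (spec$process %in% c("bm", "fbm")) vals$kappa <- 1
      if (spec$process == "fbm") vals$hurst <- 0.5
      if (spec$process == "expcor") vals$gamma_range <- 0.25
      if (spec$marginal == "t") vals$df <- 10
      do.call(lmm_params, c(list(spec), vals[nm]))
    }
  } else {
    validate_params(start, spec)
  }
  theta0 <- transform_params(start, spec)

  nll <- function(th) {
    ll <- loglik_groups(groups, spec, untransform_params(th, spec))
    if (!is.finite(ll)) 1e10 else -ll
  }

  run_optim <- function(th) {
    tryCatch(stats::optim(th, nll, method = "BFGS",
                          control = list(maxit = control$maxit,
                                         reltol = control$reltol)),
             error = function(e) NULL)
  }

  opt <- run_optim(theta0)
  tries <- 0L
  while ((is.null(opt) || opt$convergence != 0) &&
         tries < control$n_restarts) {
    tries <- tries + 1L
    jit_seed <- if (is.null(seed)) tries else seed + tries
    jitter <- with_seed(jit_seed, stats::rnorm(length(theta0), 0, 0.2))
    base <- if (is.null(opt)) theta0 else opt$par
    opt2 <- run_optim(base + jitter)
    if (!is.null(opt2) && (is.null(opt) || opt2$value <= opt$value)) opt <- opt2
  }

  n_obs <- nrow(data)
  k <- n_params(spec)
  out <- list(spec = spec, params = NULL, theta = NULL, vcov = NULL,
              loglik = NA_real_, bic = NA_real_, n_obs = n_obs,
              n_subjects = length(unique(data$id)), k = k,
              converged = FALSE, failed = TRUE, boundary = character(),
              data = data)
  class(out) <- "mixed_fit"
  if (is.null(opt) || !all(is.finite(opt$par)) || opt$value >= 1e10) {
    return(out)
  }

  theta_hat <- opt$par
  params_hat <- untransform_params(theta_hat, spec)
  out$params <- params_hat
  out$theta <- theta_hat
  out$loglik <- -opt$value
  out$bic <- bic_value(out$loglik, k, n_obs)
  out$converged <- opt$convergence == 0

  out$boundary <- nm[(nm == "rho" & abs(params_hat) > 1 - 1e-4) |
                     (nm == "hurst" &
                        (params_hat < 1e-4 | params_hat > 1 - 1e-4))]

  H <- tryCatch(stats::optimHess(theta_hat, nll,
                                 control = list(ndeps = rep(control$hess_step,
                                                            length(theta_hat)))),
                error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  pd <- !is.null(vc) && all(is.finite(vc)) &&
    !inherits(tryCatch(chol((vc + t(vc)) / 2), error = function(e) e), "error")
  if (pd) {
    dimnames(vc) <- list(names(theta_hat), names(theta_hat))
    out$vcov <- vc
    out$failed <- FALSE
  }
  out
}

#' @export
print.mixed_fit <- function(x, ...) {
  print(x$spec)
  if (is.null(x$params)) {
    cat("  <fit failed: no parameter estimates returned>\n")
    return(invisible(x))
  }
  cat(sprintf("  logLik %.2f | BIC %.2f | %d obs, %d subjects | k = %d%s%s\n",
              x$loglik, x$bic, x$n_obs, x$n_subjects, x$k,
              if (x$failed) " | FAILED" else "",
              if (length(x$boundary))
                paste0(" | boundary: ", paste(x$boundary, collapse = ","))
              else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
logLik.mixed_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.mixed_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

# derivative of natural wrt transformed parameter, at the estimate
link_deriv <- function(name, natural) {
  switch(link_of(name),
         identity = 1,
         log = natural,
         rho = (1 - natural^2) / 2,
         logit = natural * (1 - natural))
}

#' Tidy summaries of a fitted model
#'
#' `tidy()` returns one row per parameter with the natural-scale estimate,
#' a delta-method standard error, and Wald confidence limits computed on the
#' transformed (unconstrained) scale and back-transformed — so limits for
#' `rho` always lie in (-1, 1) and limits for variances are positive and
#' asymmetric around the estimate.  Parameters flagged as boundary cases
#' carry `NA` intervals.  `glance()` returns the one-row model summary.
#'
#' @param x,object a `mixed_fit`.
#' @param conf.level confidence level for the Wald intervals.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mixed_fit <- function(x, conf.level = 0.95, ...) {
  nm <- names(x$params)
  est <- as.numeric(x$params)
  if (is.null(x$vcov)) {
    return(tibble::tibble(term = nm, estimate = est, std.error = NA_real_,
                          conf.low = NA_real_, conf.high = NA_real_))
  }
  se_t <- sqrt(diag(x$vcov))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  lo <- x$theta - z * se_t
  hi <- x$theta + z * se_t
  back <- function(v) as.numeric(untransform_params(v, x$spec))
  tb <- tibble::tibble(
    term = nm,
    estimate = est,
    std.error = se_t * abs(vapply(seq_along(nm),
                                  function(i) link_deriv(nm[i], est[i]),
                                  numeric(1))),
    conf.low = back(lo),
    conf.high = back(hi))
  if (length(x$boundary)) {
    bad <- tb$term %in% x$boundary
    tb$conf.low[bad] <- NA_real_
    tb$conf.high[bad] <- NA_real_
  }
  tb
}

#' @rdname tidy.mixed_fit
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, BIC = x$bic, k = x$k, nobs = x$n_obs,
                 n_subjects = x$n_subjects, converged = x$converged,
                 failed = x$failed)
}

#' Compare two fitted models
#'
#' Nested models are compared with the likelihood-ratio test (`2 * delta
#' loglik` against a chi-squared with `df_diff` degrees of freedom);
#' non-nested models on the same data with the BIC difference.  Both fits
#' must be to the same dataset.
#'
#' @param fit_simple,fit_rich `mixed_fit` objects on the same data,
#'   `fit_rich` having at least as many parameters.
#' @return A one-row tibble with `two_delta_ll`, `df_diff`, `p_value` and
#'   `delta_bic` (BIC of the rich model minus BIC of the simple one).
#' @export
compare_mixed <- function(fit_simple, fit_rich) {
  stopifnot(inherits(fit_simple, "mixed_fit"), inherits(fit_rich, "mixed_fit"))
  if (fit_simple$n_obs != fit_rich$n_obs) {
    stop("fits are not on the same data", call. = FALSE)
  }
  df_diff <- fit_rich$k - fit_simple$k
  if (df_diff < 0) stop("`fit_rich` has fewer parameters than `fit_simple`",
                        call. = FALSE)
  two_dll <- 2 * (fit_rich$loglik - fit_simple$loglik)
  p <- if (df_diff > 0) {
    stats::pchisq(two_dll, df_diff, lower.tail = FALSE)
  } else if (abs(two_dll) < 1e-8) 1 else NA_real_
  tibble::tibble(two_delta_ll = two_dll, df_diff = df_diff, p_value = p,
                 delta_bic = fit_rich$bic - fit_simple$bic)
}
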