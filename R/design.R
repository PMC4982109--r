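#' Fixed- and random-effects design matrices for one subject
#'
#' The fixed-effects design is `[1, t]`, extended to `[1, t, g, g*t]` under a
#' two-group specification (group offsets `delta0`, `delta1` apply to group
#' 1).  The random-effects design is always `[1, t]` (random intercept and
#' slope).
#'
#' @param times numeric vector of observation times (years).
#' @param spec an [lmm_spec()].
#' @param group 0/1 group label (required when `spec$two_group`).
#' @return A list with matrices `X` (n x p) and `Z` (n x 2).
#' @export
build_design <- function(times, spec, group = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  times <- as.numeric(times)
  Z <- cbind(1, times)
  colnames(Z) <- c("intercept", "slope")
  if (spec$two_group) {
    if (is.null(group)) {
      stop("two-group spec requires a `group` label", call. = FALSE)
    }
    g <- as.numeric(group)
    X <- cbind(Z, g, g * times)
    colnames(X) <- c("beta0", "beta1", "delta0", "delta1")
  } else {
    X <- Z
    colnames(X) <- c("beta0", "beta1")
  }
  list(X = X, Z = Z)
}

#' Assemble the per-subject marginal scale matrix
#'
#' Builds the components of the marginal scale matrix for one subject:
#' `V = Z Psi Z' + Sigma + sigma^2 I`, where `Psi` is the 2x2 random-effects
#' scale matrix, `Sigma` the Gaussian-process covariance selected by the
#' specification (zero when `process` is `"none"` or `"expcor"`), and the
#' residual term is `sigma^2 I` (replaced by the full exponential-decay
#' matrix under `"expcor"`).  Under the multivariate-t marginal `V` is the
#' *scale* matrix shared with the normal model; the covariance is
#' `v/(v-2) * V` for `v > 2`.
#'
#' @param times numeric vector of observation times for the subject.
#' @param spec an [lmm_spec()].
#' @param params an [lmm_params()] vector valid for `spec`.
#' @param group optional 0/1 group label (two-group specs).
#' @return A list with `X`, `Z`, `Psi`, `Sigma`, `R` (residual covariance),
#'   `V` and its lower Cholesky factor `L`.
#' @examples
#' spec <- lmm_spec("bm")
#' p <- lmm_params(spec, beta0 = 23.81, beta1 = -1.15, U00 = 28.69,
#'                 rho = -1, U11 = 0.20, sigma = 2.28, kappa = 7.00)
#' assemble_scale_matrix(1, spec, p)$V
#' @export
assemble_scale_matrix <- function(times, spec, params, group = NULL) {
  validate_params(params, spec)
  d <- build_design(times, spec, group)
  n <- length(times)
  Psi <- psi_matrix(params)
  Sigma <- switch(spec$process,
                  none = , expcor = matrix(0, n, n),
                  bm = bm_cov(times, params[["kappa"]]),
                  fbm = fbm_cov(times, params[["kappa"]], params[["hurst"]]))
  R <- if (spec$process == "expcor") {
    expcor_cov(times, params[["sigma"]], params[["gamma_range"]])
  } else {
    diag(params[["sigma"]]^2, n)
  }
  V <- d$Z %*% Psi %*% t(d$Z) + Sigma + R
  V <- (V + t(V)) / 2
  L <- tryCatch(t(chol(V)), error = function(e) {
    stop("scale matrix not positive definite at these parameters",
         call. = FALSE)
  })
  list(X = d$X, Z = d$Z, Psi = Psi, Sigma = Sigma, R = R, V = V, L = L)
}

# Group subjects sharing an identical (times, group) pattern so that one
# Cholesky factorisation serves all of them in the likelihood.  Returns a
# list of groups: times, group label, X, and the n x m outcome matrix Y
# whose columns are subjects, plus the subject ids.
group_longdata <- function(data, spec) {
  data <- as_longdata(data)
  if (spec$two_group && !("group" %in% names(data))) {
    stop("two-group spec requires a `group` column", call. = FALSE)
  }
  ids <- unique(data$id)
  tsplit <- split(data$time, factor(data$id, levels = ids))
  ysplit <- split(data$y, factor(data$id, levels = ids))
  gvec <- if ("group" %in% names(data)) {
    vapply(split(data$group, factor(data$id, levels = ids)), `[`, numeric(1), 1L)
  } else {
    rep(0, length(ids))
  }
  key <- paste(gvec, vapply(tsplit, paste, character(1), collapse = ","))
  idx <- split(seq_along(ids), key)
  lapply(idx, function(ii) {
    times <- tsplit[[ii[1]]]
    g <- gvec[ii[1]]
    d <- build_design(times, spec, group = if (spec$two_group) g else NULL)
    list(times = times, group = g, X = d$X, Z = d$Z,
         Y = matrix(unlist(ysplit[ii], use.names = FALSE),
                    nrow = length(times)),
         ids = ids[ii])
  })
}

# Total observations and subjects of a long dataset
n_obs_longdata <- function(data) nrow(data)
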