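#' Specify an extended linear mixed model
#'
#' A model specification selects which variance components and which marginal
#' family are active.  Every model contains correlated random intercept and
#' slope terms.  The `process` argument optionally adds a non-stationary
#' Gaussian-process component (scaled Brownian motion `"bm"` or fractional
#' Brownian motion `"fbm"`), or replaces the independent residual errors with
#' an exponential-decay correlation structure (`"expcor"`).  The marginal
#' family is either multivariate normal (`"normal"`) or multivariate-t
#' (`"t"`), the latter obtained by scaling all variance components by a
#' subject-level latent `tau ~ gamma(v/2, v/2)`.
#'
#' @param process one of `"none"`, `"bm"`, `"fbm"`, `"expcor"`.
#' @param marginal one of `"normal"`, `"t"`.
#' @param two_group logical; if `TRUE` the fixed effects gain offsets
#'   `delta0` (intercept) and `delta1` (slope) for the second group
#'   (group label 1).
#' @return An object of class `lmm_spec`.
#' @examples
#' lmm_spec("fbm", "t")
#' @export
lmm_spec <- function(process = c("none", "bm", "fbm", "expcor"),
                     marginal = c("normal", "t"),
                     two_group = FALSE) {
  process <- match.arg(process)
  marginal <- match.arg(marginal)
  stopifnot(is.logical(two_group), length(two_group) == 1L, !is.na(two_group))
  structure(list(process = process, marginal = marginal,
                 two_group = two_group),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  proc <- switch(x$process,
                 none = "measurement error only",
                 bm = "Brownian motion + measurement error",
                 fbm = "fractional Brownian motion + measurement error",
                 expcor = "exponential-decay correlated errors")
  cat("<lmm_spec> random slopes + ", proc,
      "; marginal ", if (x$marginal == "t") "multivariate-t" else "normal",
      if (x$two_group) "; two-group fixed effects" else "",
      "\n", sep = "")
  invisible(x)
}

#' Natural-scale parameter names active under a specification
#'
#' Parameter ordering is frozen so that optimizer traces and covariance
#' matrices are reproducible: fixed effects first, then the random-effects
#' scale components, the residual SD, process parameters, and the degrees of
#' freedom for the multivariate-t marginal.
#'
#' @param spec an [lmm_spec()].
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  nm <- c("beta0", "beta1")
  if (spec$two_group) nm <- c(nm, "delta0", "delta1")
  nm <- c(nm, "U00", "rho", "U11", "sigma")
  nm <- c(nm, switch(spec$process,
                     none = character(),
                     bm = "kappa",
                     fbm = c("kappa", "hurst"),
                     expcor = "gamma_range"))
  if (spec$marginal == "t") nm <- c(nm, "df")
  nm
}

#' Construct and validate a parameter set
#'
#' Builds the full natural-scale parameter vector `theta` for a model
#' specification.  Units: `beta0` in sqrt(cells/uL); `beta1`, `delta1` in
#' sqrt(cells/uL) per year; `U00`, `U11` are the random-intercept and
#' random-slope variances (conditional on the latent scale under the
#' multivariate-t marginal); `rho` their correlation; `sigma` the residual SD;
#' `kappa` the process variance at one year; `hurst` the Hurst index;
#' `gamma_range` the exponential-decay range in years; `df` the multivariate-t
#' degrees of freedom.
#'
#' @param spec an [lmm_spec()].
#' @param ... named parameter values; all names from [param_names()] for
#'   `spec` must be supplied (extras are an error).
#' @return A named numeric vector of class `lmm_params` with attribute
#'   `spec`.
#' @examples
#' lmm_params(lmm_spec("bm"), beta0 = 23.81, beta1 = -1.15, U00 = 28.69,
#'            rho = -1, U11 = 0.20, sigma = 2.28, kappa = 7.00)
#' @export
lmm_params <- function(spec, ...) {
  stopifnot(inherits(spec, "lmm_spec"))
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.numeric(vals[[1]])) {
    vals <- as.list(vals[[1]])
  }
  nm <- param_names(spec)
  missing <- setdiff(nm, names(vals))
  extra <- setdiff(names(vals), nm)
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(extra)) {
    stop("parameters not active under this spec: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  theta <- vapply(vals[nm], as.numeric, numeric(1))
  validate_params(theta, spec)
  structure(theta, spec = spec, class = "lmm_params")
}

validate_params <- function(theta, spec) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(all(is.finite(theta)), "parameters must be finite")
  chk(theta[["U00"]] > 0, "U00 must be positive")
  chk(theta[["U11"]] > 0, "U11 must be positive")
  chk(abs(theta[["rho"]]) <= 1, "rho must lie in [-1, 1]")
  chk(theta[["sigma"]] > 0, "sigma must be positive")
  if (spec$process %in% c("bm", "fbm")) {
    chk(theta[["kappa"]] > 0, "kappa must be positive")
  }
  if (spec$process == "fbm") {
    chk(theta[["hurst"]] > 0 && theta[["hurst"]] < 1,
        "hurst must lie strictly inside (0, 1)")
  }
  if (spec$process == "expcor") {
    chk(theta[["gamma_range"]] > 0, "gamma_range must be positive")
  }
  if (spec$marginal == "t") chk(theta[["df"]] > 0, "df must be positive")
  invisible(theta)
}

#' @export
print.lmm_params <- function(x, ...) {
  print.lmm_spec(attr(x, "spec"))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Transform map: which link applies to each natural parameter.
# identity for fixed effects; log for variances/scales/df; a scaled logistic
# onto (-1, 1) for rho (x -> 2 / (1 + exp(-x)) - 1, i.e. 2*atanh on the
# inverse side); logistic for the Hurst index.
link_of <- function(name) {
  switch(name,
         beta0 = , beta1 = , delta0 = , delta1 = "identity",
         U00 = , U11 = , sigma = , kappa = , gamma_range = , df = "log",
         rho = "rho",
         hurst = "logit",
         stop("unknown parameter: ", name))
}

#' Map parameters between natural and unconstrained scales
#'
#' The likelihood is maximised over an unconstrained vector: variances,
#' scales and the degrees of freedom are log-transformed, the random-effects
#' correlation uses a scaled logistic link onto (-1, 1)
#' (`rho = 2 / (1 + exp(-x)) - 1`), and the Hurst index a logistic link onto
#' (0, 1).  Fixed effects are untransformed.  `transform_params()` and
#' `untransform_params()` are exact inverses away from the closed boundaries;
#' a natural-scale value on a boundary (`rho = +/-1`) has no finite preimage
#' and raises an error (fitted estimates approaching a boundary are flagged,
#' not transformed).
#'
#' @param params an [lmm_params()] vector.
#' @param theta named numeric vector on the unconstrained scale.
#' @param spec an [lmm_spec()].
#' @return `transform_params()`: a named numeric vector (unconstrained);
#'   `untransform_params()`: an `lmm_params` vector.
#' @export
transform_params <- function(params, spec = attr(params, "spec")) {
  nm <- param_names(spec)
  out <- vapply(nm, function(p) {
    v <- params[[p]]
    switch(link_of(p),
           identity = v,
           log = log(v),
           rho = {
             if (abs(v) >= 1) stop("rho on boundary has no finite transform",
                                   call. = FALSE)
             log((1 + v) / (1 - v))
           },
           logit = stats::qlogis(v))
  }, numeric(1))
  names(out) <- paste0(vapply(nm, function(p) switch(link_of(p),
                                                     identity = "",
                                                     log = "log_",
                                                     rho = "link_",
                                                     logit = "logit_"),
                              character(1)), nm)
  out
}

#' @rdname transform_params
#' @export
untransform_params <- function(theta, spec) {
  nm <- param_names(spec)
  stopifnot(length(theta) == length(nm))
  vals <- vapply(seq_along(nm), function(i) {
    v <- theta[[i]]
    switch(link_of(nm[i]),
           identity = v,
           log = exp(v),
           rho = 2 / (1 + exp(-v)) - 1,
           logit = stats::plogis(v))
  }, numeric(1))
  names(vals) <- nm
  structure(vals, spec = spec, class = "lmm_params")
}

#' Number of free parameters of a specification
#' @param spec an [lmm_spec()].
#' @return integer count, e.g. 6 for the random-slopes model, 8 when a
#'   fractional Brownian motion component is added, 9 for its multivariate-t
#'   version.
#' @export
n_params <- function(spec) length(param_names(spec))

# 2x2 random-effects scale matrix Psi from natural parameters
psi_matrix <- function(params) {
  u00 <- params[["U00"]]; u11 <- params[["U11"]]; rho <- params[["rho"]]
  c12 <- rho * sqrt(u00 * u11)
  matrix(c(u00, c12, c12, u11), 2L, 2L)
}
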