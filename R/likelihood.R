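process_code <- function(process) {
  match(process, c("none", "bm", "fbm", "expcor")) - 1L
}

# Likelihood at natural-scale parameters from pre-grouped data.
loglik_groups <- function(groups, spec, params) {
  beta <- c(params[["beta0"]], params[["beta1"]])
  if (spec$two_group) beta <- c(beta, params[["delta0"]], params[["delta1"]])
  cpp_loglik(groups, beta,
             params[["U00"]], params[["rho"]], params[["U11"]],
             params[["sigma"]],
             process_code(spec$process),
             if (spec$process %in% c("bm", "fbm")) params[["kappa"]] else 0,
             if (spec$process == "fbm") params[["hurst"]] else 0.5,
             if (spec$process == "expcor") params[["gamma_range"]] else 1,
             if (spec$marginal == "t") 1L else 0L,
             if (spec$marginal == "t") params[["df"]] else 0)
}

#' Log-likelihood of an extended linear mixed model
#'
#' Evaluates the marginal log-likelihood of long-format data under a model
#' specification and natural-scale parameters.  Under the normal marginal
#' each subject contributes a multivariate-normal log-density with
#' covariance `V_i = Z_i Psi Z_i' + Sigma_i + sigma^2 I`; under the
#' multivariate-t marginal the density with shared degrees of freedom `v`
#' and scale matrix `V_i` is used.  Subjects are independent, so the total
#' is the sum over subjects.  Computation uses one Cholesky factorisation
#' per distinct observation-time pattern (log-determinants from the factor
#' diagonal, quadratic forms via triangular solves).
#'
#' @param data long-format data frame (see [as_longdata()]).
#' @param spec an [lmm_spec()].
#' @param params an [lmm_params()] vector for `spec`.
#' @return The log-likelihood (scalar); `-Inf` if the scale matrix is not
#'   positive definite at `params`.
#' @examples
#' fx <- make_fixture("tiny_rs", seed = 1)
#' mixed_loglik(fx, attr(fx, "spec"), attr(fx, "params"))
#' @export
mixed_loglik <- function(data, spec, params) {
  stopifnot(inherits(spec, "lmm_spec"))
  validate_params(params, spec)
  groups <- group_longdata(data, spec)
  loglik_groups(groups, spec, params)
}

#' Bayesian information criterion from its ingredients
#'
#' `BIC = -2 * loglik + k * log(n_obs)`, with the penalty based on the total
#' number of observations in the dataset (not the number of subjects).
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n_obs total number of observations.
#' @return The BIC value.
#' @examples
#' bic_value(-230029, 8, 84856)
#' @export
bic_value <- function(loglik, k, n_obs) {
  -2 * loglik + k * log(n_obs)
}
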