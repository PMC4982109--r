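# Independent brute-force oracles.  These deliberately re-derive the model
# densities from first principles (dense matrices, explicit inverses and
# determinants, quadrature over the latent-scale hierarchy) so they share no
# code path with the package's grouped Cholesky implementation.

oracle_cov <- function(times, spec, params) {
  n <- length(times)
  u00 <- params[["U00"]]; u11 <- params[["U11"]]; rho <- params[["rho"]]
  c01 <- rho * sqrt(u00 * u11)
  V <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- times[j]; t <- times[k]
    v <- u00 + c01 * (s + t) + u11 * s * t
    if (spec$process == "bm") v <- v + params[["kappa"]] * min(s, t)
    if (spec$process == "fbm") {
      h2 <- 2 * params[["hurst"]]
      v <- v + params[["kappa"]] / 2 * (s^h2 + t^h2 - abs(s - t)^h2)
    }
    if (spec$process == "expcor") {
      v <- v + params[["sigma"]]^2 * exp(-abs(s - t) / params[["gamma_range"]])
    }
    if (j == k && spec$process != "expcor") v <- v + params[["sigma"]]^2
    V[j, k] <- v
  }
  V
}

oracle_mu <- function(times, spec, params, group = 0) {
  mu <- params[["beta0"]] + params[["beta1"]] * times
  if (spec$two_group && group == 1) {
    mu <- mu + params[["delta0"]] + params[["delta1"]] * times
  }
  mu
}

# dense MVN log-density with explicit inverse and determinant
oracle_mvn_loglik_subject <- function(y, times, spec, params, group = 0) {
  V <- oracle_cov(times, spec, params)
  r <- y - oracle_mu(times, spec, params, group)
  n <- length(y)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% solve(V) %*% r))
}

# closed-form multivariate-t log-density, written independently
oracle_mvt_loglik_subject <- function(y, times, spec, params, group = 0) {
  V <- oracle_cov(times, spec, params)
  r <- y - oracle_mu(times, spec, params, group)
  n <- length(y)
  v <- params[["df"]]
  d2 <- as.numeric(t(r) %*% solve(V) %*% r)
  lgamma((v + n) / 2) - lgamma(v / 2) - n / 2 * log(v * pi) -
    0.5 * as.numeric(determinant(V)$modulus) -
    (v + n) / 2 * log(1 + d2 / v)
}

# gamma-normal hierarchy: density by adaptive quadrature over tau
oracle_mvt_quadrature_subject <- function(y, times, spec, params,
                                          group = 0) {
  V <- oracle_cov(times, spec, params)
  r <- y - oracle_mu(times, spec, params, group)
  n <- length(y)
  v <- params[["df"]]
  Vi <- solve(V)
  ld <- as.numeric(determinant(V)$modulus)
  d2 <- as.numeric(t(r) %*% Vi %*% r)
  f <- function(tau) {
    exp(-0.5 * (n * log(2 * pi) + ld - n * log(tau) + tau * d2) +
          stats::dgamma(tau, shape = v / 2, rate = v / 2, log = TRUE))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-11,
                       abs.tol = 0)$value)
}

# small random dataset on a random grid, with outcomes drawn loosely (the
# oracles evaluate densities at arbitrary points, so y need not come from
# the model)
random_subject <- function(n, seed) {
  set.seed(seed)
  list(times = sort(round(runif(n, 0, 8), 3)),
       y = rnorm(n, 20, 6))
}

random_params <- function(spec, seed) {
  set.seed(seed)
  vals <- list(beta0 = rnorm(1, 22, 2), beta1 = rnorm(1, -1, 0.5),
               U00 = runif(1, 5, 40), rho = runif(1, -0.9, 0.9),
               U11 = runif(1, 0.1, 2), sigma = runif(1, 0.5, 3))
  if (spec$two_group) {
    vals$delta0 <- rnorm(1); vals$delta1 <- rnorm(1, 0, 0.3)
  }
  if (spec$process %in% c("bm", "fbm")) vals$kappa <- runif(1, 1, 10)
  if (spec$process == "fbm") vals$hurst <- runif(1, 0.1, 0.9)
  if (spec$process == "expcor") vals$gamma_range <- runif(1, 0.05, 1)
  if (spec$marginal == "t") vals$df <- runif(1, 3, 15)
  do.call(lmm_params, c(list(spec), vals))
}
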