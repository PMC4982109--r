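# shared fitted objects for the diagnostics tests
diag_fit_normal <- local({
  spec <- lmm_spec("none")
  p <- lmm_params(spec, beta0 = 24, beta1 = -1.3, U00 = 30, rho = -0.4,
                  U11 = 1.5, sigma = 2.7)
  co <- simulate_cohort(spec, p, visit_schedule(1, 4), 1500, seed = 101)
  dat <- co[co$visit_type == "scheduled", c("id", "time", "y")]
  fit_mixed(dat, spec)
})

diag_fit_t <- local({
  spec <- lmm_spec("fbm", "t")
  p <- cd4_preset("cascade_mvt_fbm")
  co <- simulate_cohort(spec, p, visit_schedule(0.25, 5), 400, seed = 102)
  dat <- co[co$visit_type == "scheduled", c("id", "time", "y")]
  list(fit = fit_mixed(dat, spec), latents = attr(co, "latents"))
})

test_that("subject-level deviates are standard normal under a correct model", {
  st <- subject_stats(diag_fit_normal)
  expect_true(all(st$delta2 >= 0))
  expect_equal(nrow(st), 1500)
  ks <- stats::ks.test(st$normal_deviate, "pnorm")
  expect_gt(ks$p.value, 0.01)
  # overall scale: sum of delta2 over total observations near 1
  expect_equal(sum(st$delta2) / sum(st$n_i), 1, tolerance = 0.05)
})

test_that("a zero residual vector maps to the finite sentinel deviate", {
  fit <- diag_fit_normal
  b <- c(fit$params[["beta0"]], fit$params[["beta1"]])
  first <- fit$data$id == fit$data$id[1]
  fit$data$y[first] <- b[1] + b[2] * fit$data$time[first]
  st <- subject_stats(fit)
  expect_equal(st$delta2[st$id == fit$data$id[1]], 0)
  expect_equal(st$normal_deviate[st$id == fit$data$id[1]], -8)
})

test_that("latent-scale posterior follows the conjugate gamma form", {
  fit <- diag_fit_t$fit
  tp <- tau_posterior(fit)
  v <- fit$params[["df"]]
  expect_equal(tp$shape, (v + tp$n_i) / 2)
  expect_equal(tp$rate, (v + tp$delta2) / 2)
  expect_equal(tp$tau_hat, (v + tp$n_i) / (v + tp$delta2))
  # delta2 = n gives posterior mean 1; delta2 = 0 gives (v + n) / v
  i <- which.min(abs(tp$delta2 - tp$n_i))
  expect_equal(tp$tau_hat[i], (v + tp$n_i[i]) / (v + tp$delta2[i]))
  # empirical-Bayes mean equals the Monte-Carlo posterior mean
  set.seed(1)
  draws <- stats::rgamma(1e6, shape = tp$shape[1], rate = tp$rate[1])
  expect_equal(mean(draws), tp$tau_hat[1], tolerance = 5e-3)
  expect_error(tau_posterior(diag_fit_normal), "multivariate-t")
})

test_that("tau_hat tracks inverse subject variability", {
  tp <- tau_posterior(diag_fit_t$fit)
  lat <- diag_fit_t$latents
  ct <- suppressWarnings(
    stats::cor.test(tp$tau_hat, lat$tau[match(tp$id, lat$id)],
                    method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("Cholesky residuals from a correct normal model are standard normal", {
  rs <- cholesky_residuals(diag_fit_normal, "mvn")
  n <- nrow(rs)
  expect_gte(n, 1e4 * 0.5)
  expect_lt(abs(mean(rs$residual)), 4 / sqrt(n))
  expect_gt(stats::var(rs$residual), 0.95)
  expect_lt(stats::var(rs$residual), 1.05)
  # scalar case: residual = (y - mu) / sqrt(V)
  spec <- lmm_spec("none")
  p <- lmm_params(spec, beta0 = 2, beta1 = 0, U00 = 3, rho = 0, U11 = 1,
                  sigma = 1)
  d <- data.frame(id = c(1, 2), time = 0, y = c(4, 1))
  f <- structure(list(spec = spec, params = p, data = as_longdata(d)),
                 class = "mixed_fit")
  r1 <- cholesky_residuals(f, "mvn")
  expect_equal(r1$residual, (d$y - 2) / sqrt(3 + 1))
})

test_that("empirical-Bayes-corrected residuals from a t model pass a KS check", {
  rs <- cholesky_residuals(diag_fit_t$fit, "t_eb")
  ks <- stats::ks.test(rs$residual, "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("sampled-tau residual sets are exchangeable and feed monotone bands", {
  rs <- cholesky_residuals(diag_fit_t$fit, "t_sampled", n_draws = 40,
                           seed = 9)
  sds <- tapply(rs$residual, rs$draw, stats::sd)
  expect_lt(stats::sd(sds) / mean(sds), 0.05)
  bands <- composite_qq_bands(rs)
  expect_true(all(diff(bands$q50) >= 0))
  expect_true(all(bands$q025 <= bands$q50 & bands$q50 <= bands$q975))
  # identical draws collapse the three bands
  one <- rs[rs$draw == 1, ]
  dup <- rbind(one, transform(one, draw = 2))
  b2 <- composite_qq_bands(dup)
  expect_equal(b2$q025, b2$q975)
})

test_that("per-subject Q-Q selects subjects with more than 15 observations", {
  fit <- diag_fit_t$fit
  tab <- table(fit$data$id)
  expect_true(all(tab == 21))
  qq <- per_subject_qq(fit, min_obs = 16, n_subjects = 10, seed = 3)
  expect_equal(length(unique(qq$id)), 10)
  expect_equal(qq$expected_slope, qq$tau_hat^(-0.5))
  # deterministic under the seed
  qq2 <- per_subject_qq(fit, min_obs = 16, n_subjects = 10, seed = 3)
  expect_identical(qq, qq2)
  # per-subject slope of sorted residuals approximates tau^(-1/2)
  lat <- diag_fit_t$latents
  slopes <- vapply(split(qq, qq$id), function(g) {
    stats::coef(stats::lm(residual ~ theoretical, data = g))[[2]]
  }, numeric(1))
  truth <- lat$tau[match(as.numeric(names(slopes)), lat$id)]^(-0.5)
  expect_gt(stats::cor(slopes, truth), 0.8)
  expect_warning(per_subject_qq(fit, min_obs = 16, n_subjects = 1e5,
                                seed = 1), "qualify")
})
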