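test_that("random-slopes ML fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("nlme")
  fx <- make_fixture("tiny_rs", seed = 4)
  # a larger replicate for a stable comparison
  spec <- attr(fx, "spec")
  co <- simulate_cohort(spec, attr(fx, "params"),
                        visit_schedule(0.5, 4), 80, seed = 8)
  dat <- as.data.frame(co[co$visit_type == "scheduled",
                          c("id", "time", "y")])
  fit <- fit_mixed(dat, spec)
  ref <- nlme::lme(y ~ time, random = ~ time | id, data = dat,
                   method = "ML",
                   control = nlme::lmeControl(opt = "optim",
                                              maxIter = 200,
                                              msMaxIter = 200))
  expect_false(fit$failed)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$params[["beta1"]],
               nlme::fixef(ref)[["time"]], tolerance = 1e-3)
  expect_equal(fit$params[["sigma"]], ref$sigma, tolerance = 1e-3)
})

test_that("slope is recovered within 3 standard errors on simulated data", {
  spec <- lmm_spec("none")
  p <- lmm_params(spec, beta0 = 24, beta1 = -1.3, U00 = 30, rho = -0.4,
                  U11 = 1.5, sigma = 2.7)
  co <- simulate_cohort(spec, p, visit_schedule(1, 5), 500, seed = 15)
  dat <- co[co$visit_type == "scheduled", c("id", "time", "y")]
  fit <- fit_mixed(dat, spec)
  expect_false(fit$failed)
  se <- sqrt(fit$vcov["beta1", "beta1"])
  expect_lt(abs(fit$params[["beta1"]] - p[["beta1"]]), 3 * se)
})

test_that("likelihood improves monotonically along the model ladder", {
  spec_gen <- lmm_spec("fbm")
  p <- cd4_preset("cascade_mvn_fbm")
  co <- simulate_cohort(spec_gen, p, visit_schedule(1 / 3, 5), 150,
                        seed = 33)
  dat <- co[co$visit_type == "scheduled", c("id", "time", "y")]
  f_rs <- fit_mixed(dat, lmm_spec("none"))
  f_bm <- fit_mixed(dat, lmm_spec("bm"))
  f_fbm <- fit_mixed(dat, lmm_spec("fbm"))
  tol <- 1e-4
  expect_gte(f_bm$loglik, f_rs$loglik - tol)
  expect_gte(f_fbm$loglik, f_bm$loglik - tol)
  # nested comparisons behave like likelihood-ratio tests
  cmp <- compare_mixed(f_rs, f_fbm)
  expect_equal(cmp$df_diff, 2)
  expect_gte(cmp$two_delta_ll, 0)
  expect_equal(cmp$delta_bic,
               -cmp$two_delta_ll + 2 * log(f_rs$n_obs), tolerance = 1e-8)
})

test_that("Wald intervals respect the transformed scales", {
  fx <- make_fixture("tiny_rs", seed = 2)
  co <- simulate_cohort(attr(fx, "spec"), attr(fx, "params"),
                        visit_schedule(0.5, 5), 120, seed = 19)
  dat <- co[co$visit_type == "scheduled", c("id", "time", "y")]
  fit <- fit_mixed(dat, lmm_spec("none"))
  tb <- tidy(fit)
  rho_row <- tb[tb$term == "rho", ]
  expect_gte(rho_row$conf.low, -1)
  expect_lte(rho_row$conf.high, 1)
  # log-scale interval: symmetric on the log scale, asymmetric natural
  sig <- tb[tb$term == "sigma", ]
  expect_equal(log(sig$conf.high) - log(sig$estimate),
               log(sig$estimate) - log(sig$conf.low), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(sig$conf.high - sig$estimate,
                                sig$estimate - sig$conf.low)))
  # all intervals contain the estimate
  expect_true(all(tb$conf.low <= tb$estimate & tb$estimate <= tb$conf.high))
})

test_that("model comparison handles identical fits and the 3.84 critical value", {
  fx <- make_fixture("tiny_rs", seed = 6)
  fit <- fit_mixed(fx, lmm_spec("none"))
  cmp <- compare_mixed(fit, fit)
  expect_equal(cmp$two_delta_ll, 0)
  expect_equal(cmp$p_value, 1)
  # one extra parameter: 2*delta-loglik of 3.84 sits at p ~ 0.05
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
})

test_that("nominal 95% intervals for the slope cover at the nominal rate", {
  # 200 uncensored replicates from the multivariate-t fBM generating model
  spec <- lmm_spec("fbm", "t")
  p <- cd4_preset("cascade_mvt_fbm")
  sched <- visit_schedule(1 / 3, 5)
  hits <- logical(0)
  zall <- c()
  for (r in 1:200) {
    co <- simulate_cohort(spec, p, sched, 500, seed = 6000 + r)
    dat <- co[co$visit_type == "scheduled", c("id", "time", "y")]
    fit <- fit_mixed(dat, spec)
    if (fit$failed) next
    se <- sqrt(fit$vcov["beta1", "beta1"])
    hits <- c(hits, abs(fit$params[["beta1"]] - p[["beta1"]]) <= 1.96 * se)
    z <- (as.numeric(fit$params) - as.numeric(p)) / tidy(fit)$std.error
    zall <- c(zall, z)
  }
  expect_gt(length(hits), 180)
  cover <- 100 * mean(hits)
  expect_gte(cover, 90)
  expect_lte(cover, 99)
})
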