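test_that("design matrices follow the intercept-slope (+ group offset) layout", {
  d <- build_design(c(0, 1), lmm_spec("none"))
  expect_equal(unname(d$X), cbind(c(1, 1), c(0, 1)))
  expect_equal(unname(d$Z), unname(d$X))

  d2 <- build_design(2, lmm_spec("none", two_group = TRUE), group = 1)
  expect_equal(unname(d2$X[1, ]), c(1, 2, 1, 2))
  d0 <- build_design(c(1, 3), lmm_spec("none", two_group = TRUE), group = 0)
  expect_equal(unname(d0$X[, 3:4]), matrix(0, 2, 2))
  expect_error(build_design(1, lmm_spec("none", two_group = TRUE)), "group")
})

test_that("parameter transforms are exact bijections", {
  spec <- lmm_spec("none")
  p <- lmm_params(spec, beta0 = 24.13, beta1 = -1.36, U00 = 33.68,
                  rho = -0.39, U11 = 1.62, sigma = 2.76)
  expect_equal(as.numeric(untransform_params(transform_params(p), spec)),
               as.numeric(p), tolerance = 1e-12)
  # rho = 0 maps to link 0 and back; H = 0.5 maps to logit 0
  expect_equal(transform_params(lmm_params(spec, beta0 = 0, beta1 = 0,
                                           U00 = 1, rho = 0, U11 = 1,
                                           sigma = 1))[["link_rho"]], 0)
  pf <- lmm_params(lmm_spec("fbm"), beta0 = 0, beta1 = 0, U00 = 1, rho = 0,
                   U11 = 1, sigma = 1, kappa = 1, hurst = 0.5)
  expect_equal(transform_params(pf)[["logit_hurst"]], 0)
  expect_error(transform_params(lmm_params(spec, beta0 = 0, beta1 = 0,
                                           U00 = 1, rho = -1, U11 = 1,
                                           sigma = 1)), "boundary")
})

test_that("transform/untransform round-trips random unconstrained vectors", {
  specs <- list(lmm_spec("none"), lmm_spec("bm"), lmm_spec("fbm", "t"),
                lmm_spec("expcor", "t", two_group = TRUE))
  set.seed(11)
  for (spec in specs) {
    for (i in 1:250) {
      th <- rnorm(n_params(spec), 0, 2)
      p <- untransform_params(th, spec)
      expect_equal(unname(transform_params(p, spec)), th,
                   tolerance = 1e-10)
    }
  }
})

test_that("assembled scale matrix matches the component formula", {
  spec <- lmm_spec("bm")
  p <- lmm_params(spec, beta0 = 23.81, beta1 = -1.15, U00 = 28.69, rho = -1,
                  U11 = 0.20, sigma = 2.28, kappa = 7.00)
  sm <- assemble_scale_matrix(1, spec, p)
  expect_equal(sm$V[1, 1],
               28.69 + 2 * (-1) * sqrt(28.69 * 0.20) + 0.20 + 7 + 2.28^2,
               tolerance = 1e-12)
  # rho = 0 gives a diagonal random-effects scale matrix
  p0 <- lmm_params(spec, beta0 = 0, beta1 = 0, U00 = 2, rho = 0, U11 = 3,
                   sigma = 1, kappa = 1)
  expect_equal(assemble_scale_matrix(c(1, 2), spec, p0)$Psi,
               diag(c(2, 3)))
  # expcor uses the full residual matrix, no extra sigma^2 on top
  spe <- lmm_spec("expcor")
  pe <- lmm_params(spe, beta0 = 0, beta1 = 0, U00 = 1, rho = 0, U11 = 1,
                   sigma = 2, gamma_range = 0.5)
  sme <- assemble_scale_matrix(c(0, 1), spe, pe)
  expect_equal(sme$R, expcor_cov(c(0, 1), 2, 0.5))
  expect_equal(sme$V, sme$Z %*% sme$Psi %*% t(sme$Z) + sme$R)
})

test_that("simulated subject vectors reproduce the assembled covariance", {
  spec <- lmm_spec("fbm")
  p <- lmm_params(spec, beta0 = 23.8, beta1 = -1.15, U00 = 27.5, rho = -0.6,
                  U11 = 0.6, sigma = 2, kappa = 9.3, hurst = 0.3)
  sched <- visit_schedule(1, 3, confirm_lag_years = 1 / 12)
  co <- simulate_cohort(spec, p, sched, 40000, seed = 21)
  w <- tidyr::pivot_wider(co[, c("id", "time", "y")], names_from = "time",
                          values_from = "y")
  Y <- as.matrix(w[, -1])
  tt <- as.numeric(colnames(w)[-1])
  emp <- stats::cov(Y)
  theo <- assemble_scale_matrix(tt, spec, p)$V
  # elementwise agreement within 4 monte-carlo standard errors
  se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / 40000)
  expect_true(all(abs(emp - theo) < 4.5 * se))
})

test_that("the multivariate-t marginal shares the scale matrix, covariance inflated by v/(v-2)", {
  spec <- lmm_spec("none", "t")
  p <- lmm_params(spec, beta0 = 0, beta1 = 0, U00 = 4, rho = 0.3, U11 = 1,
                  sigma = 1, df = 8)
  pn <- lmm_params(lmm_spec("none"), beta0 = 0, beta1 = 0, U00 = 4,
                   rho = 0.3, U11 = 1, sigma = 1)
  tt <- c(0.5, 1.5)
  Vt <- assemble_scale_matrix(tt, spec, p)$V
  Vn <- assemble_scale_matrix(tt, lmm_spec("none"), pn)$V
  expect_equal(Vt, Vn)
  sched <- visit_schedule(1, 1.5, include_baseline = FALSE,
                          confirm_lag_years = 0.5)
  co <- simulate_cohort(spec, p, sched, 60000, seed = 5)
  w <- tidyr::pivot_wider(co[, c("id", "time", "y")], names_from = "time",
                          values_from = "y")
  emp <- stats::cov(as.matrix(w[, -1]))
  tt2 <- as.numeric(colnames(w)[-1])
  theo <- assemble_scale_matrix(tt2, spec, p)$V * p[["df"]] / (p[["df"]] - 2)
  expect_true(all(abs(emp - theo) / theo < 0.08))
})

test_that("long data validation sorts within subject and enforces the contract", {
  d <- as_longdata(data.frame(id = c(1, 1, 2), time = c(2, 0, 1),
                              y = c(5, 7, 3)))
  expect_equal(d$time, c(0, 2, 1))
  expect_equal(d$y, c(7, 5, 3))
  expect_error(as_longdata(data.frame(id = 1, time = -1, y = 0)),
               "non-negative")
  expect_error(as_longdata(data.frame(id = 1, y = 0)), "missing columns")
  expect_error(as_longdata(data.frame(id = c(1, 1), time = c(0, 1),
                                      y = c(1, 2), group = c(0, 1))),
               "constant within subject")
})
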