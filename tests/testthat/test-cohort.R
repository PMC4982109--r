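test_that("visit schedules enumerate scheduled and confirmatory times", {
  s <- visit_schedule(1 / 3, 10)
  expect_length(s$scheduled_times, 31)
  expect_equal(s$confirm_times, s$scheduled_times + 1 / 12)
  s2 <- visit_schedule(1, 5, include_baseline = FALSE)
  expect_equal(s2$scheduled_times, 1:5)
  expect_error(visit_schedule(1 / 12, 5, confirm_lag_years = 1 / 6))
})

test_that("uncensored analysis datasets have the exact bookkeeping totals", {
  p <- cd4_preset("cascade_mvt_fbm")
  spec <- attr(p, "spec")
  co1 <- simulate_cohort(spec, p, visit_schedule(1, 5), 100, seed = 1)
  expect_equal(nrow(apply_censoring(co1, NULL)), 600)
  co3 <- simulate_cohort(spec, p, visit_schedule(1 / 3, 5), 100, seed = 1)
  expect_equal(nrow(apply_censoring(co3, NULL)), 1600)
})

test_that("cohorts are a deterministic function of the seed", {
  p <- cd4_preset("cascade_mvn_fbm")
  spec <- attr(p, "spec")
  s <- visit_schedule(1, 3)
  a <- simulate_cohort(spec, p, s, 25, seed = 42)
  b <- simulate_cohort(spec, p, s, 25, seed = 42)
  expect_identical(a$y, b$y)
  expect_identical(attr(a, "latents"), attr(b, "latents"))
  c2 <- simulate_cohort(spec, p, s, 25, seed = 43)
  expect_false(identical(a$y, c2$y))
})

test_that("the confirmatory censoring rule is applied visit by visit", {
  p <- cd4_preset("cascade_mvn_rs")
  spec <- attr(p, "spec")
  co <- simulate_cohort(spec, p, visit_schedule(1, 3), 3, seed = 5)
  thr <- sqrt(350)
  # subject 1: always above; subject 2: below at visit 2 but confirmatory
  # above (scan continues), both below at visit 4; subject 3: below at
  # baseline and confirmed
  hi <- thr + 5; lo <- thr - 5
  co$y[co$id == 1] <- hi
  y2 <- rep(hi, 8)
  y2[3] <- lo           # scheduled visit 2 below
  y2[4] <- hi           # confirmatory above -> no initiation
  y2[7] <- lo; y2[8] <- lo  # visit 4 scheduled+confirmatory below
  co$y[co$id == 2] <- y2
  co$y[co$id == 3] <- lo
  cens <- apply_censoring(co, 350)
  init <- attr(cens, "initiation")
  expect_equal(init$initiated, c(FALSE, TRUE, TRUE))
  expect_equal(init$init_visit, c(NA_integer_, 4L, 1L))
  expect_equal(init$init_time, c(NA, 3 + 1 / 12, 0 + 1 / 12))
  # subject 1 keeps all scheduled observations, no confirmatory ones
  expect_equal(sum(cens$id == 1 & cens$visit_type == "scheduled"), 4)
  expect_equal(sum(cens$id == 1 & cens$visit_type == "confirmatory"), 0)
  # subject 2 keeps 4 scheduled + the assessed confirmatories at visits 2, 4
  expect_equal(sum(cens$id == 2 & cens$visit_type == "scheduled"), 4)
  expect_equal(cens$time[cens$id == 2 & cens$visit_type == "confirmatory"],
               c(1 + 1 / 12, 3 + 1 / 12))
  # subject 3 is censored at baseline: baseline + its confirmation only
  expect_equal(nrow(cens[cens$id == 3, ]), 2)
})

test_that("initiation curves are monotone, conserved, and ordered in threshold", {
  p <- cd4_preset("cascade_mvt_fbm")
  spec <- attr(p, "spec")
  co <- simulate_cohort(spec, p, visit_schedule(1 / 3, 6), 3000, seed = 77)
  curves <- lapply(c(200, 350, 500), function(thr) {
    initiation_curve(apply_censoring(co, thr))
  })
  for (cv in curves) {
    expect_true(all(diff(cv$proportion) >= 0))
  }
  # conservation: value at the horizon equals the initiated fraction
  cens500 <- apply_censoring(co, 500)
  expect_equal(max(curves[[3]]$proportion),
               mean(attr(cens500, "initiation")$initiated))
  # more permissive thresholds initiate more, pointwise
  expect_true(all(curves[[1]]$proportion <= curves[[2]]$proportion))
  expect_true(all(curves[[2]]$proportion <= curves[[3]]$proportion))
  # nobody censored -> flat zero curve
  none <- initiation_curve(apply_censoring(co, NULL))
  expect_true(all(none$proportion == 0))
})

test_that("negative simulated values are retained and count as below threshold", {
  spec <- lmm_spec("none")
  p <- lmm_params(spec, beta0 = 0.5, beta1 = -1, U00 = 4, rho = 0, U11 = 0.2,
                  sigma = 1)
  co <- simulate_cohort(spec, p, visit_schedule(1, 2), 200, seed = 12)
  expect_gt(sum(co$y < 0), 0)
  cens <- apply_censoring(co, 200)
  expect_gt(mean(attr(cens, "initiation")$initiated), 0.95)
})

test_that("heavy-tailed marginals show excess kurtosis over the normal model", {
  pt <- cd4_preset("cascade_mvt_fbm")
  pn <- cd4_preset("cascade_mvn_fbm")
  s <- visit_schedule(1, 2)
  ct <- simulate_cohort(attr(pt, "spec"), pt, s, 20000, seed = 31)
  cn <- simulate_cohort(attr(pn, "spec"), pn, s, 20000, seed = 31)
  kt <- mean(scale(ct$y[ct$time == 2])^4)
  kn <- mean(scale(cn$y[cn$time == 2])^4)
  expect_gt(kt, kn + 0.5)
})
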