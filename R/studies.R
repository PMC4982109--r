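fitted_model_spec <- function(name, two_group = FALSE) {
  switch(name,
         rs = lmm_spec("none", "normal", two_group),
         rs_expcor = lmm_spec("expcor", "normal", two_group),
         rs_bm = lmm_spec("bm", "normal", two_group),
         rs_fbm = lmm_spec("fbm", "normal", two_group),
         mvt_rs = lmm_spec("none", "t", two_group),
         mvt_rs_fbm = lmm_spec("fbm", "t", two_group),
         stop("unknown fitted model '", name, "'", call. = FALSE))
}

censoring_threshold <- function(rule) {
  switch(rule,
         none = NULL,
         ART200 = 200,
         ART350 = 350,
         ART500 = 500,
         stop("unknown censoring rule '", rule, "'", call. = FALSE))
}

#' Treatment-initiation study: initiation curves under simulated monitoring
#'
#' Simulates large cohorts from one or more preset models under a 4-monthly
#' monitoring schedule with a confirmatory test one month after each visit,
#' applies CD4 threshold rules for treatment initiation, and returns the
#' cumulative initiation curve for each model and threshold.  The default
#' problem size of 50,000 patients keeps the Monte-Carlo standard error of
#' each curve point near 0.2 percentage points.
#'
#' @param presets character vector of preset names (see [cd4_presets()]).
#' @param n_subjects simulated patients per model.
#' @param thresholds CD4 initiation thresholds (cells/uL).
#' @param schedule a [visit_schedule()]; defaults to 4-monthly visits to 10
#'   years with a 1-month confirmatory lag.
#' @param grid_years evaluation grid for the curves; defaults to the
#'   schedule's confirmatory times.
#' @param seed integer seed.
#' @return A tibble `model`, `threshold`, `time`, `proportion` of class
#'   `initiation_study`.
#' @export
run_initiation_study <- function(presets = c("cascade_mvn_rs",
                                             "cascade_mvn_bm",
                                             "cascade_mvn_fbm",
                                             "cascade_mvt_fbm"),
                                 n_subjects = 50000,
                                 thresholds = c(500, 350, 200),
                                 schedule = visit_schedule(1 / 3, 10),
                                 grid_years = NULL,
                                 seed = 1) {
  out <- purrr::map_dfr(seq_along(presets), function(i) {
    params <- cd4_preset(presets[i])
    cohort <- simulate_cohort(attr(params, "spec"), params, schedule,
                              n_subjects, seed = seed + i)
    purrr::map_dfr(thresholds, function(thr) {
      cens <- apply_censoring(cohort, thr)
      curve <- initiation_curve(cens, grid_years = grid_years)
      tibble::tibble(model = presets[i], threshold = thr,
                     time = curve$time, proportion = curve$proportion)
    })
  })
  class(out) <- c("initiation_study", class(out))
  out
}

#' @export
autoplot.initiation_study <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time, .data$proportion,
                               colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~threshold, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Years since seroconversion",
                  y = "Proportion initiated") +
    ggplot2::theme_minimal()
}

# One simulated cohort analysed under one censoring rule and fitted model.
analyse_cohort <- function(cohort, rule, model, truth, control) {
  cens <- apply_censoring(cohort, censoring_threshold(rule))
  init <- attr(cens, "initiation")
  horizon <- attr(cohort, "schedule")$horizon_years
  prop_cens <- mean(init$initiated & !is.na(init$init_time) &
                      init$init_time <= horizon, na.rm = FALSE)
  dat <- cens[, intersect(c("id", "time", "y", "group"), names(cens))]
  spec <- fitted_model_spec(model, two_group = "group" %in% names(dat))
  fit <- fit_mixed(dat, spec, control = control)
  term <- if (spec$two_group) "delta1" else "beta1"
  est <- if (is.null(fit$params)) NA_real_ else fit$params[[term]]
  se <- if (fit$failed) NA_real_ else sqrt(fit$vcov[term, term])
  covered <- if (fit$failed) NA else abs(est - truth) <= stats::qnorm(0.975) * se
  tibble::tibble(rule = rule, model = model, failed = fit$failed,
                 estimate = est, se = se, covered = covered,
                 n_obs = nrow(dat), prop_censored = prop_cens)
}

summarise_cells <- function(res, truth) {
  dplyr::summarise(
    dplyr::group_by(res, .data$rule, .data$model),
    n_cohorts = dplyr::n(),
    failed_pct = 100 * mean(.data$failed),
    bias = mean(.data$estimate[!.data$failed]) - truth,
    coverage_pct = 100 * mean(.data$covered[!.data$failed]),
    sd_estimate = stats::sd(.data$estimate[!.data$failed]),
    mean_se = mean(.data$se[!.data$failed]),
    med_prop_censored_pct = 100 * stats::median(.data$prop_censored),
    iqr_prop_censored_lo = unname(100 * stats::quantile(.data$prop_censored,
                                                        0.25)),
    iqr_prop_censored_hi = unname(100 * stats::quantile(.data$prop_censored,
                                                        0.75)),
    med_n_obs = stats::median(.data$n_obs),
    iqr_n_obs_lo = unname(stats::quantile(.data$n_obs, 0.25)),
    iqr_n_obs_hi = unname(stats::quantile(.data$n_obs, 0.75)),
    .groups = "drop")
}

#' Slope-bias study under missing-at-random censoring
#'
#' Generates replicate cohorts from a preset generating model (by default
#' the multivariate-t fractional Brownian motion estimates), applies
#' treatment-initiation censoring rules with the 1-month confirmatory test,
#' fits the requested models to each (censored) cohort, and summarises the
#' bias of the mean-slope estimate `beta1`, the coverage of its nominal 95%
#' Wald interval, failure rates, and censoring/observation bookkeeping.
#' Observed confirmatory measurements are part of each analysis dataset.
#' Failed fits (no estimates, or a non-positive-definite covariance of the
#' estimates) are excluded from bias and coverage.
#'
#' @param n_cohorts number of replicate cohorts per cell.
#' @param n_subjects patients per cohort (100 or 200 in the reference
#'   design).
#' @param obs_per_year scheduled observation frequency (1 or 3).
#' @param horizon_years follow-up (5 years in the reference design), with a
#'   baseline visit at time zero.
#' @param censoring character vector from `"none"`, `"ART200"`, `"ART350"`,
#'   `"ART500"`.
#' @param models character vector of fitted models: `"rs"`, `"rs_bm"`,
#'   `"rs_fbm"`, `"mvt_rs_fbm"` (plus `"rs_expcor"`, `"mvt_rs"`).
#' @param gen_preset generating preset name.
#' @param seed integer seed; cohort `c` uses `seed + c`, so runs with fewer
#'   cohorts reproduce a prefix of longer runs.
#' @param control a [fit_control()].
#' @return A summary tibble (one row per censoring rule x fitted model)
#'   with attribute `estimates` holding the per-cohort results.
#' @export
run_bias_study <- function(n_cohorts = 500, n_subjects = 100,
                           obs_per_year = 1, horizon_years = 5,
                           censoring = c("none", "ART200", "ART350",
                                         "ART500"),
                           models = "rs",
                           gen_preset = "cascade_mvt_fbm",
                           seed = 1,
                           control = fit_control()) {
  params <- cd4_preset(gen_preset)
  spec <- attr(params, "spec")
  truth <- params[["beta1"]]
  schedule <- visit_schedule(1 / obs_per_year, horizon_years)
  res <- purrr::map_dfr(seq_len(n_cohorts), function(c) {
    cohort <- simulate_cohort(spec, params, schedule, n_subjects,
                              seed = seed + c)
    grid <- expand.grid(rule = censoring, model = models,
                        stringsAsFactors = FALSE)
    dplyr::bind_cols(
      cohort_id = c,
      purrr::map2_dfr(grid$rule, grid$model,
                      function(r, m) analyse_cohort(cohort, r, m, truth,
                                                    control)))
  })
  out <- summarise_cells(res, truth)
  out$truth <- truth
  attr(out, "estimates") <- res
  out
}

#' Two-group study: bias in the between-group slope difference
#'
#' Two groups are generated from the same preset model (no true group
#' differences), but censored under different treatment-initiation rules —
#' by default the first group at the 200 cells/uL cut-off and the second at
#' 500 cells/uL.  Models with group offsets `delta0` (intercept) and
#' `delta1` (slope) are then fitted to the combined censored data; any
#' nonzero mean of the `delta1` estimate is bias induced purely by the
#' differential censoring.
#'
#' @param n_cohorts number of replicate two-group cohorts.
#' @param n_per_group patients per group (100 or 200 in the reference
#'   design).
#' @param obs_per_year scheduled observation frequency (3 in the reference
#'   design).
#' @param horizon_years follow-up horizon.
#' @param rules length-2 character vector of censoring rules for groups 0
#'   and 1.
#' @param models fitted models (see [run_bias_study()]); each gains the
#'   group offset terms.
#' @param gen_preset generating preset name.
#' @param seed integer seed.
#' @param control a [fit_control()].
#' @return A summary tibble for the `delta1` estimates (truth 0) with
#'   attribute `estimates`.
#' @export
run_two_group_study <- function(n_cohorts = 100, n_per_group = 200,
                                obs_per_year = 3, horizon_years = 5,
                                rules = c("ART200", "ART500"),
                                models = "rs",
                                gen_preset = "cascade_mvt_fbm",
                                seed = 1,
                                control = fit_control()) {
  stopifnot(length(rules) == 2L)
  params <- cd4_preset(gen_preset)
  spec <- attr(params, "spec")
  schedule <- visit_schedule(1 / obs_per_year, horizon_years)
  res <- purrr::map_dfr(seq_len(n_cohorts), function(c) {
    parts <- purrr::map(1:2, function(g) {
      cohort <- simulate_cohort(spec, params, schedule, n_per_group,
                                seed = seed + 2L * c + (g - 1L),
                                group = rep(g - 1, n_per_group))
      cens <- apply_censoring(cohort, censoring_threshold(rules[g]))
      dat <- cens[, c("id", "time", "y", "group")]
      dat$id <- paste0("g", g - 1, "_", dat$id)
      dat
    })
    dat <- dplyr::bind_rows(parts)
    purrr::map_dfr(models, function(m) {
      fit <- fit_mixed(dat, fitted_model_spec(m, two_group = TRUE),
                       control = control)
      est <- if (is.null(fit$params)) NA_real_ else fit$params[["delta1"]]
      se <- if (fit$failed) NA_real_ else sqrt(fit$vcov["delta1", "delta1"])
      tibble::tibble(cohort_id = c, model = m, failed = fit$failed,
                     estimate = est, se = se,
                     covered = if (fit$failed) NA else
                       abs(est) <= stats::qnorm(0.975) * se)
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(res, .data$model),
    n_cohorts = dplyr::n(),
    failed_pct = 100 * mean(.data$failed),
    bias = mean(.data$estimate[!.data$failed]),
    coverage_pct = 100 * mean(.data$covered[!.data$failed]),
    sd_estimate = stats::sd(.data$estimate[!.data$failed]),
    mean_se = mean(.data$se[!.data$failed]),
    .groups = "drop")
  attr(out, "estimates") <- res
  out
}
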