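#' Observation schedule for simulated cohorts
#'
#' Scheduled visits run from baseline (time zero, optional) to the horizon
#' at a fixed interval; each scheduled visit has an associated confirmatory
#' measurement a fixed lag later (one month by default), generated for every
#' visit but only *observed* when the scheduled value falls below the
#' treatment-initiation threshold in play.
#'
#' @param interval_years positive spacing of scheduled visits (years);
#'   e.g. `1/3` for 4-monthly visits.
#' @param horizon_years positive follow-up horizon (years).
#' @param include_baseline logical; include a visit at time zero.
#' @param confirm_lag_years positive lag of the confirmatory measurement
#'   (years); must be smaller than `interval_years`.  One month is `1/12`.
#' @return An object of class `visit_schedule`.
#' @examples
#' visit_schedule(1 / 3, 10)  # 4-monthly visits to 10 years
#' @export
visit_schedule <- function(interval_years, horizon_years,
                           include_baseline = TRUE,
                           confirm_lag_years = 1 / 12) {
  stopifnot(interval_years > 0, horizon_years > 0,
            confirm_lag_years > 0, confirm_lag_years < interval_years)
  k_max <- floor(horizon_years / interval_years + 1e-9)
  idx <- if (include_baseline) 0:k_max else seq_len(k_max)
  sched <- idx * interval_years
  structure(list(interval_years = interval_years,
                 horizon_years = horizon_years,
                 include_baseline = include_baseline,
                 confirm_lag_years = confirm_lag_years,
                 scheduled_times = sched,
                 confirm_times = sched + confirm_lag_years),
            class = "visit_schedule")
}

# Kernel covariance on an arbitrary (possibly unsorted) time vector;
# internal generation path, bypasses the sortedness contract of the
# user-facing kernels.
kernel_matrix <- function(times, spec, params) {
  n <- length(times)
  switch(spec$process,
         none = , expcor = matrix(0, n, n),
         bm = params[["kappa"]] * outer(times, times, pmin),
         fbm = {
           h2 <- 2 * params[["hurst"]]
           t2h <- times^h2
           (params[["kappa"]] / 2) *
             (outer(t2h, t2h, `+`) - abs(outer(times, times, `-`))^h2)
         })
}

# Symmetric PSD square root via eigendecomposition (tolerates the zero
# variance at t = 0 and duplicated times, where Cholesky would fail).
psd_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Simulate an uncensored cohort from an extended linear mixed model
#'
#' Generates per-subject trajectories at every scheduled and confirmatory
#' time of a [visit_schedule()].  Under the multivariate-t marginal a latent
#' scale `tau_i ~ gamma(v/2, v/2)` is drawn per subject and the random
#' effects, process path and measurement errors are all scaled by
#' `tau_i^(-1/2)`.  Negative simulated values are retained (the model lives
#' on the square-root scale and the censoring rules treat them as below any
#' threshold).
#'
#' @param spec an [lmm_spec()].
#' @param params an [lmm_params()] for `spec`.
#' @param schedule a [visit_schedule()].
#' @param n_subjects number of subjects.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @param group optional 0/1 vector of length `n_subjects` attaching group
#'   labels (used by two-group designs; generation itself applies the
#'   `delta` offsets only if they are active in `params`).
#' @return A long tibble (`id`, `time`, `y`, `visit_type`, `visit_index`,
#'   and `group` if given) of class `cohort_sim`, with attributes
#'   `latents` (per-subject `tau`, `b0`, `b1`), `schedule`, `spec`,
#'   `params` and `initiation` (empty until [apply_censoring()]).
#' @export
simulate_cohort <- function(spec, params, schedule, n_subjects, seed,
                            group = NULL) {
  stopifnot(inherits(spec, "lmm_spec"), inherits(schedule, "visit_schedule"),
            n_subjects >= 1)
  validate_params(params, spec)
  if (!is.null(group)) stopifnot(length(group) == n_subjects,
                                 all(group %in% c(0, 1)))
  sched <- schedule$scheduled_times
  conf <- schedule$confirm_times
  t_all <- c(sched, conf)
  K <- length(sched)
  n_t <- length(t_all)

  mu <- params[["beta0"]] + params[["beta1"]] * t_all
  mu_mat <- matrix(mu, nrow = n_subjects, ncol = n_t, byrow = TRUE)
  if (spec$two_group && !is.null(group)) {
    off <- params[["delta0"]] + params[["delta1"]] * t_all
    mu_mat <- mu_mat + outer(as.numeric(group), off)
  }

  Sig <- kernel_matrix(t_all, spec, params)
  A <- psd_sqrt(Sig)
  Lpsi <- psd_sqrt(psi_matrix(params))  # tolerates |rho| = 1

  draws <- with_seed(seed, {
    tau <- if (spec$marginal == "t") {
      rgamma(n_subjects, shape = params[["df"]] / 2,
             rate = params[["df"]] / 2)
    } else {
      rep(1, n_subjects)
    }
    b <- matrix(rnorm(2 * n_subjects), n_subjects, 2) %*% t(Lpsi)
    W <- matrix(rnorm(n_subjects * n_t), n_subjects, n_t) %*% t(A)
    E <- if (spec$process == "expcor") {
      Ar <- psd_sqrt(expcor_cov_raw(t_all, params[["sigma"]],
                                    params[["gamma_range"]]))
      matrix(rnorm(n_subjects * n_t), n_subjects, n_t) %*% t(Ar)
    } else {
      matrix(rnorm(n_subjects * n_t, sd = params[["sigma"]]),
             n_subjects, n_t)
    }
    list(tau = tau, b = b, W = W, E = E)
  })
  s <- 1 / sqrt(draws$tau)
  Y <- mu_mat + s * (draws$b[, 1] + outer(draws$b[, 2], t_all) +
                       draws$W + draws$E)

  type <- rep(c("scheduled", "confirmatory"), each = K)
  vidx <- rep(seq_len(K), times = 2L)
  ord <- order(t_all, match(type, c("scheduled", "confirmatory")))
  out <- tibble::tibble(
    id = rep(seq_len(n_subjects), each = n_t),
    time = rep(t_all[ord], times = n_subjects),
    y = as.numeric(t(Y[, ord, drop = FALSE])),
    visit_type = rep(type[ord], times = n_subjects),
    visit_index = rep(vidx[ord], times = n_subjects))
  if (!is.null(group)) out$group <- rep(as.numeric(group), each = n_t)
  attr(out, "latents") <- tibble::tibble(id = seq_len(n_subjects),
                                         tau = draws$tau,
                                         b0 = draws$b[, 1] * s,
                                         b1 = draws$b[, 2] * s)
  attr(out, "schedule") <- schedule
  attr(out, "spec") <- spec
  attr(out, "params") <- params
  class(out) <- c("cohort_sim", class(out))
  out
}

# expcor without the sortedness check (generation path)
expcor_cov_raw <- function(times, sigma, gamma_range) {
  sigma^2 * exp(-abs(outer(times, times, `-`)) / gamma_range)
}

#' Apply a threshold-based treatment-initiation censoring rule
#'
#' Scans each subject's scheduled measurements in time order.  When a
#' scheduled value falls below the square root of the threshold, the
#' confirmatory measurement one lag later is assessed; the subject initiates
#' treatment (and is censored) at the confirmatory time if that value is
#' also below the threshold.  Scheduled observations after initiation are
#' removed.  Every confirmatory measurement that was *assessed* — i.e. at
#' any visit up to and including the triggering one whose scheduled value
#' was below the threshold — is retained in the analysis dataset, whether
#' or not it confirmed; keeping all values the censoring decision
#' conditioned on is what preserves the everywhere-missing-at-random
#' property that makes likelihood inference on the censored data valid.
#' Comparisons are made on the model's square-root scale, so negative
#' simulated values count as below any threshold.
#'
#' @param cohort a `cohort_sim` from [simulate_cohort()].
#' @param threshold_cells treatment-initiation threshold on the original
#'   scale (cells/uL), typically 200, 350 or 500; `NULL` applies no
#'   censoring.
#' @param confirmatory logical; require the confirmatory value below the
#'   threshold as well (the default clinical rule).
#' @return The censored cohort tibble, with attribute `initiation`: a
#'   tibble of `id`, `initiated`, `init_time` (confirmatory time of the
#'   triggering visit; `NA` if never) and `init_visit`.
#' @export
apply_censoring <- function(cohort, threshold_cells, confirmatory = TRUE) {
  stopifnot(inherits(cohort, "cohort_sim"))
  schedule <- attr(cohort, "schedule")
  n_sub <- length(unique(cohort$id))
  if (is.null(threshold_cells)) {
    # no rule: nothing triggers, so no confirmatory value is ever observed
    out <- cohort[cohort$visit_type == "scheduled", ]
    for (a in c("latents", "schedule", "spec", "params")) {
      attr(out, a) <- attr(cohort, a)
    }
    attr(out, "initiation") <- tibble::tibble(
      id = sort(unique(cohort$id)), initiated = FALSE,
      init_time = NA_real_, init_visit = NA_integer_)
    class(out) <- c("cohort_sim", setdiff(class(out), "cohort_sim"))
    return(out)
  }
  stopifnot(threshold_cells > 0)
  thr <- sqrt(threshold_cells)
  K <- length(schedule$scheduled_times)

  sv <- cohort[cohort$visit_type == "scheduled", ]
  cv <- cohort[cohort$visit_type == "confirmatory", ]
  o_s <- order(sv$id, sv$visit_index)
  o_c <- order(cv$id, cv$visit_index)
  S <- matrix(sv$y[o_s], nrow = K)
  C <- matrix(cv$y[o_c], nrow = K)
  if (ncol(S) != n_sub || nrow(sv) != K * n_sub || nrow(cv) != K * n_sub) {
    stop("cohort lacks the full scheduled/confirmatory lattice", call. = FALSE)
  }

  below_s <- S < thr
  trig <- if (confirmatory) below_s & (C < thr) else below_s
  hit <- which(trig)
  first_visit <- rep(Inf, n_sub)
  if (length(hit)) {
    row <- (hit - 1L) %% K + 1L
    col <- (hit - 1L) %/% K + 1L
    agg <- tapply(row, col, min)
    first_visit[as.integer(names(agg))] <- agg
  }
  initiated <- is.finite(first_visit)
  init_visit <- ifelse(initiated, first_visit, NA_integer_)
  init_time <- ifelse(initiated,
                      schedule$scheduled_times[first_visit] +
                        schedule$confirm_lag_years,
                      NA_real_)

  ids <- sort(unique(cohort$id))
  vmax <- first_visit[match(cohort$id, ids)]
  keep_sched <- cohort$visit_type == "scheduled" & cohort$visit_index <= vmax
  obs_conf <- below_s[cbind(cohort$visit_index, match(cohort$id, ids))]
  keep_conf <- cohort$visit_type == "confirmatory" & obs_conf &
    cohort$visit_index <= vmax
  out <- cohort[keep_sched | keep_conf, ]
  for (a in c("latents", "schedule", "spec", "params")) {
    attr(out, a) <- attr(cohort, a)
  }
  attr(out, "initiation") <- tibble::tibble(
    id = ids, initiated = initiated,
    init_time = init_time, init_visit = as.integer(init_visit))
  class(out) <- c("cohort_sim", setdiff(class(out), "cohort_sim"))
  out
}

#' Cumulative treatment-initiation curve of a censored cohort
#'
#' @param cohort a `cohort_sim` after [apply_censoring()].
#' @param grid_years numeric vector of times at which to evaluate the
#'   cumulative proportion initiated; defaults to the confirmatory times of
#'   the cohort's schedule.
#' @return A tibble (`time`, `proportion`) of class `initiation_curve`;
#'   the proportion is the number of subjects with initiation time at or
#'   before each grid time over the full cohort size, hence monotone
#'   non-decreasing.
#' @export
initiation_curve <- function(cohort, grid_years = NULL) {
  init <- attr(cohort, "initiation")
  if (is.null(init)) stop("apply a censoring rule first", call. = FALSE)
  if (nrow(init) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(grid_years)) {
    grid_years <- attr(cohort, "schedule")$confirm_times
  }
  tt <- init$init_time[init$initiated]
  prop <- vapply(grid_years, function(g) sum(tt <= g + 1e-12), numeric(1)) /
    nrow(init)
  structure(tibble::tibble(time = grid_years, proportion = prop),
            class = c("initiation_curve", class(tibble::tibble())))
}

#' @export
autoplot.initiation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$proportion)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years since seroconversion",
                  y = "Proportion initiated") +
    ggplot2::theme_minimal()
}
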