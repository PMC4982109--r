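#' Validate and normalise long-format longitudinal data
#'
#' The package works on long-format data frames with one row per measurement:
#' a subject identifier `id`, observation time `time` (years, non-negative),
#' outcome `y` on the analysis (square-root) scale, and an optional binary
#' `group` label (0/1) for two-group models.  `as_longdata()` checks the
#' contract and sorts rows by subject and time (carrying `y` along).
#'
#' @param data a data frame with columns `id`, `time`, `y` and optionally
#'   `group`.
#' @return A tibble sorted by `id`, `time`.
#' @examples
#' as_longdata(data.frame(id = c(1, 1), time = c(1, 0), y = c(20, 24)))
#' @export
as_longdata <- function(data) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  need <- c("id", "time", "y")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` has no rows", call. = FALSE)
  if (!is.numeric(data$time) || !is.numeric(data$y)) {
    stop("`time` and `y` must be numeric", call. = FALSE)
  }
  if (anyNA(data$time) || anyNA(data$y) || anyNA(data$id)) {
    stop("`id`, `time`, `y` must not contain NA", call. = FALSE)
  }
  if (any(data$time < 0)) stop("`time` must be non-negative", call. = FALSE)
  if ("group" %in% names(data)) {
    if (!all(data$group %in% c(0, 1))) {
      stop("`group` must be 0/1", call. = FALSE)
    }
    g <- tapply(data$group, data$id, function(v) length(unique(v)))
    if (any(g > 1L)) stop("`group` must be constant within subject",
                          call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(data), .data$id, .data$time)
  out
}

#' Read / write long-format longitudinal CSV files
#'
#' The on-disk format is a headed CSV with columns `id,time,y[,group]`
#' (extra columns are preserved on read).  `sqrt_transform = TRUE` applies
#' the square-root transform on load, for files holding raw counts rather
#' than values already on the analysis scale.
#'
#' @param path file path.
#' @param sqrt_transform logical; square-root transform `y` on load.
#' @param data a long-format data frame (see [as_longdata()]).
#' @return `read_long_csv()`: a validated tibble; `write_long_csv()`: `path`,
#'   invisibly.
#' @export
read_long_csv <- function(path, sqrt_transform = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (sqrt_transform) {
    if (any(df$y < 0)) stop("negative `y`: cannot sqrt-transform", call. = FALSE)
    df$y <- sqrt(df$y)
  }
  as_longdata(df)
}

#' @rdname read_long_csv
#' @export
write_long_csv <- function(data, path) {
  utils::write.csv(as_longdata(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Small canned datasets with known generating truth
#'
#' Generates a tiny longitudinal dataset (at most 20 subjects, at most 6
#' observations each) from a known parameter set, for use as a reproducible
#' fixture in examples and tests.  The generating `lmm_spec`, `lmm_params`
#' and (for `"tiny_t"`) the per-subject latent scales are attached as
#' attributes `spec`, `params` and `latents`.
#'
#' @param kind one of `"tiny_rs"` (random slopes + measurement error),
#'   `"tiny_fbm"` (adds a fractional Brownian motion component) or
#'   `"tiny_t"` (multivariate-t fBM model).
#' @param seed integer seed; the output is a deterministic function of
#'   `(kind, seed)`.
#' @return A long-format tibble with attributes `spec`, `params`, `latents`.
#' @examples
#' fx <- make_fixture("tiny_rs", seed = 1)
#' attr(fx, "params")
#' @export
make_fixture <- function(kind = c("tiny_rs", "tiny_fbm", "tiny_t"), seed = 1) {
  kind <- match.arg(kind)
  spec <- switch(kind,
                 tiny_rs = lmm_spec("none", "normal"),
                 tiny_fbm = lmm_spec("fbm", "normal"),
                 tiny_t = lmm_spec("fbm", "t"))
  params <- switch(kind,
    tiny_rs = lmm_params(spec, beta0 = 24, beta1 = -1.3, U00 = 30,
                         rho = -0.4, U11 = 1.5, sigma = 2.7),
    tiny_fbm = lmm_params(spec, beta0 = 23.8, beta1 = -1.15, U00 = 27.5,
                          rho = -0.59, U11 = 0.58, sigma = 2.0,
                          kappa = 9.3, hurst = 0.3),
    tiny_t = lmm_params(spec, beta0 = 23.59, beta1 = -1.11, U00 = 18.82,
                        rho = -0.51, U11 = 0.49, sigma = 1.45,
                        kappa = 8.02, hurst = 0.23, df = 5.76))
  sched <- visit_schedule(interval_years = 1, horizon_years = 5,
                          confirm_lag_years = 1 / 12)
  cohort <- simulate_cohort(spec, params, sched, n_subjects = 12, seed = seed)
  out <- dplyr::filter(cohort, .data$visit_type == "scheduled")
  out <- dplyr::select(out, "id", "time", "y")
  attr(out, "spec") <- spec
  attr(out, "params") <- params
  attr(out, "latents") <- attr(cohort, "latents")
  out
}
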