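# Published CASCADE parameter estimates used as simulation presets.
# Values are maximum-likelihood estimates from extended linear mixed models
# fitted to square-root pre-treatment CD4 counts of the CASCADE
# seroconverter cohort (84,856 measurements in 15,164 individuals); the
# source data are confidential, so these enter the package purely as
# generating values for simulation studies, never as reproduction targets.
preset_table <- function() {
  list(
    cascade_mvn_rs = list(
      spec = lmm_spec("none", "normal"),
      values = list(beta0 = 24.13, beta1 = -1.36, U00 = 33.68, rho = -0.39,
                    U11 = 1.62, sigma = 2.76)),
    cascade_mvn_expcor = list(
      spec = lmm_spec("expcor", "normal"),
      values = list(beta0 = 24.12, beta1 = -1.35, U00 = 33.22, rho = -0.38,
                    U11 = 1.54, sigma = 2.79, gamma_range = 0.03)),
    cascade_mvn_bm = list(
      spec = lmm_spec("bm", "normal"),
      values = list(beta0 = 23.81, beta1 = -1.15, U00 = 28.69, rho = -1,
                    U11 = 0.20, sigma = 2.28, kappa = 7.00)),
    cascade_mvn_fbm = list(
      spec = lmm_spec("fbm", "normal"),
      values = list(beta0 = 23.82, beta1 = -1.15, U00 = 27.46, rho = -0.59,
                    U11 = 0.58, sigma = 2.01, kappa = 9.32, hurst = 0.30)),
    cascade_mvt_rs = list(
      spec = lmm_spec("none", "t"),
      values = list(beta0 = 23.77, beta1 = -1.27, U00 = 23.82, rho = -0.37,
                    U11 = 1.17, sigma = 2.25, df = 5.64)),
    cascade_mvt_expcor = list(
      spec = lmm_spec("expcor", "t"),
      values = list(beta0 = 23.76, beta1 = -1.23, U00 = 22.83, rho = -0.36,
                    U11 = 1.01, sigma = 2.32, gamma_range = 0.07, df = 5.34)),
    cascade_mvt_bm = list(
      spec = lmm_spec("bm", "t"),
      values = list(beta0 = 23.57, beta1 = -1.10, U00 = 20.3, rho = -1,
                    U11 = 0.12, sigma = 1.88, kappa = 5.17, df = 5.83)),
    cascade_mvt_fbm = list(
      spec = lmm_spec("fbm", "t"),
      values = list(beta0 = 23.59, beta1 = -1.11, U00 = 18.82, rho = -0.51,
                    U11 = 0.49, sigma = 1.45, kappa = 8.02, hurst = 0.23,
                    df = 5.76)))
}

#' Published CD4 model presets
#'
#' Named parameter sets from extended linear mixed models previously fitted
#' to square-root pre-treatment CD4 counts in the CASCADE seroconverter
#' cohort.  Eight presets cover the crossing of marginal family
#' (multivariate normal `mvn`, multivariate-t `mvt`) with covariance
#' structure (`rs` random slopes + measurement error, `expcor`
#' exponential-decay errors, `bm` Brownian motion, `fbm` fractional
#' Brownian motion).  These are the generating truths of the package's
#' simulation studies; they are immutable and unit-tested against the
#' transcription file shipped in `inst/extdata/cascade_presets.csv`.
#'
#' @param name preset name, e.g. `"cascade_mvt_fbm"`.
#' @return `cd4_preset()`: an [lmm_params()] vector (its `lmm_spec` in the
#'   `spec` attribute); `cd4_presets()`: a long tibble of all preset values.
#' @examples
#' cd4_preset("cascade_mvn_rs")
#' @export
cd4_preset <- function(name) {
  tab <- preset_table()
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  entry <- tab[[name]]
  do.call(lmm_params, c(list(entry$spec), entry$values))
}

#' @rdname cd4_preset
#' @export
cd4_presets <- function() {
  tab <- preset_table()
  purrr::map_dfr(names(tab), function(nm) {
    tibble::tibble(preset = nm,
                   marginal = tab[[nm]]$spec$marginal,
                   process = tab[[nm]]$spec$process,
                   param = names(tab[[nm]]$values),
                   value = unlist(tab[[nm]]$values, use.names = FALSE))
  })
}
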