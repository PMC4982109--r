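Package: fbmlmm
Title: Extended Linear Mixed Models with Fractional Brownian Motion and
    Multivariate-t Marginals for Longitudinal Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of linear mixed models for
    longitudinal biomarker data (motivated by pre-treatment CD4 cell counts
    in HIV seroconverters) extended with non-stationary Gaussian-process
    components (scaled Brownian motion and fractional Brownian motion) or an
    exponential-decay residual correlation, under either a marginal
    multivariate-normal or multivariate-t distribution.  Includes
    Cholesky-residual and latent-scale diagnostics, a cohort simulator with
    threshold-based antiretroviral-therapy initiation censoring, and drivers
    for treatment-initiation and slope-bias simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    nlme,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
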