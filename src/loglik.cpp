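// Grouped log-likelihood evaluation for the extended linear mixed models.
//
// Subjects sharing an identical (times, group) pattern are passed together:
// one scale matrix V = Z Psi Z' + Sigma + sigma^2 I (or Z Psi Z' + R for the
// exponential-decay structure) and one Cholesky factorisation then serve all
// columns of the stacked outcome matrix.  Returns -Inf when V is not
// positive definite at the supplied parameters, which the optimizer treats
// as a rejected step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int PROC_NONE = 0, PROC_BM = 1, PROC_FBM = 2, PROC_EXPCOR = 3;
static const int MARG_NORMAL = 0, MARG_T = 1;

static arma::mat scale_matrix(const arma::vec& t, double U00, double rho,
                              double U11, double sigma, int process,
                              double kappa, double hurst, double gamma) {
  const arma::uword n = t.n_elem;
  const double c01 = rho * std::sqrt(U00 * U11);
  arma::mat V(n, n);
  for (arma::uword j = 0; j < n; ++j) {
    for (arma::uword k = 0; k <= j; ++k) {
      double v = U00 + c01 * (t[j] + t[k]) + U11 * t[j] * t[k];
      switch (process) {
      case PROC_BM:
        v += kappa * std::min(t[j], t[k]);
        break;
      case PROC_FBM: {
        const double h2 = 2.0 * hurst;
        v += 0.5 * kappa * (std::pow(t[j], h2) + std::pow(t[k], h2) -
                            std::pow(std::abs(t[j] - t[k]), h2));
        break;
      }
      case PROC_EXPCOR:
        v += sigma * sigma * std::exp(-std::abs(t[j] - t[k]) / gamma);
        break;
      default:
        break;
      }
      if (j == k && process != PROC_EXPCOR) v += sigma * sigma;
      V(j, k) = v;
      V(k, j) = v;
    }
  }
  return V;
}

// [[Rcpp::export]]
double cpp_loglik(List groups, arma::vec beta, double U00, double rho,
                  double U11, double sigma, int process, double kappa,
                  double hurst, double gamma, int marginal, double df) {
  const double log2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  for (R_xlen_t gi = 0; gi < groups.size(); ++gi) {
    List grp = groups[gi];
    arma::vec t = as<arma::vec>(grp["times"]);
    arma::mat X = as<arma::mat>(grp["X"]);
    arma::mat Y = as<arma::mat>(grp["Y"]);
    const arma::uword n = t.n_elem;
    const arma::uword m = Y.n_cols;

    arma::mat V = scale_matrix(t, U00, rho, U11, sigma, process, kappa,
                               hurst, gamma);
    if (!V.is_finite()) return R_NegInf;
    arma::mat L;
    if (!arma::chol(L, V, "lower")) return R_NegInf;
    // reject numerically singular factorisations rather than letting the
    // triangular solve fall back to an approximate solution
    const double dmax = L.diag().max();
    if (!(L.diag().min() > 1e-8 * dmax)) return R_NegInf;
    double logdet = 0.0;
    for (arma::uword j = 0; j < n; ++j) logdet += std::log(L(j, j));
    logdet *= 2.0;

    arma::vec mu = X * beta;
    arma::mat E = Y;
    E.each_col() -= mu;
    arma::mat U = arma::solve(arma::trimatl(L), E,
                              arma::solve_opts::fast);
    arma::rowvec q = arma::sum(U % U, 0);  // delta^2 per subject

    if (marginal == MARG_NORMAL) {
      ll += -0.5 * (static_cast<double>(m) * (n * log2pi + logdet) +
                    arma::accu(q));
    } else {
      const double nd = static_cast<double>(n);
      const double cst = std::lgamma(0.5 * (df + nd)) -
                         std::lgamma(0.5 * df) -
                         0.5 * nd * std::log(df * M_PI);
      double s = 0.0;
      for (arma::uword c = 0; c < m; ++c) s += std::log1p(q[c] / df);
      ll += static_cast<double>(m) * (cst - 0.5 * logdet) -
            0.5 * (df + nd) * s;
    }
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}

// Per-subject Mahalanobis statistics delta^2 = r' V^{-1} r at fixed
// parameters, returned in the column order of the stacked groups.
// [[Rcpp::export]]
List cpp_delta2(List groups, arma::vec beta, double U00, double rho,
                double U11, double sigma, int process, double kappa,
                double hurst, double gamma) {
  List out(groups.size());
  for (R_xlen_t gi = 0; gi < groups.size(); ++gi) {
    List grp = groups[gi];
    arma::vec t = as<arma::vec>(grp["times"]);
    arma::mat X = as<arma::mat>(grp["X"]);
    arma::mat Y = as<arma::mat>(grp["Y"]);
    arma::mat V = scale_matrix(t, U00, rho, U11, sigma, process, kappa,
                               hurst, gamma);
    arma::mat L;
    if (!arma::chol(L, V, "lower")) stop("scale matrix not positive definite");
    arma::vec mu = X * beta;
    arma::mat E = Y;
    E.each_col() -= mu;
    arma::mat U = arma::solve(arma::trimatl(L), E,
                              arma::solve_opts::fast);
    out[gi] = NumericVector(wrap(arma::sum(U % U, 0).t()));
  }
  return out;
}
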