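#include <Rcpp.h>
using namespace Rcpp;

// Draw from a standard normal truncated to [alpha, Inf).
// Upper-tail inverse CDF evaluated in log space: accurate for any alpha,
// including far tails where 1 - Phi(alpha) underflows.
static double rtnorm_std_lower(double alpha) {
  double lq = R::pnorm(alpha, 0.0, 1.0, /*lower*/ 0, /*log*/ 1);
  double lt = std::log(unif_rand()) + lq;
  return R::qnorm(lt, 0.0, 1.0, /*lower*/ 0, /*log*/ 1);
}

// Gibbs sampler for a multivariate Gaussian with precision P and
// precision-weighted mean b (i.e. mean = P^{-1} b), truncated to the orthant
// { w : dir[j] * w[j] >= 0 }. Each full conditional is an exact univariate
// truncated normal. Uses R's RNG, so set.seed() on the R side governs
// reproducibility.
// [[Rcpp::export]]
NumericMatrix gibbs_orthant_gaussian(NumericMatrix P, NumericVector b,
                                     NumericVector dir, NumericVector init,
                                     int n_keep, int burn_in, int thin) {
  const int m = b.size();
  NumericMatrix out(n_keep, m);
  std::vector<double> w(init.begin(), init.end());
  const int total = burn_in + n_keep * thin;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < m; ++j) {
      const double pjj = P(j, j);
      double s = b[j];
      for (int k = 0; k < m; ++k) {
        if (k != j) s -= P(j, k) * w[k];
      }
      const double mu = s / pjj;
      const double sd = 1.0 / std::sqrt(pjj);
      if (dir[j] > 0) {
        // w_j >= 0
        w[j] = mu + sd * rtnorm_std_lower(-mu / sd);
      } else {
        // w_j <= 0: mirror through the mean
        w[j] = mu - sd * rtnorm_std_lower(mu / sd);
      }
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      const int r = (it - burn_in) / thin;
      for (int j = 0; j < m; ++j) out(r, j) = w[j];
    }
  }
  return out;
}
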