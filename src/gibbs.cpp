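#include <Rcpp.h>
using namespace Rcpp;

// Single-chain Gibbs sampler for a pairwise mixed graphical model with
// Gaussian conditionals for continuous nodes and logistic (Bernoulli)
// conditionals for binary nodes:
//   continuous j: x_j | rest ~ N(mu_j + sigma2_j * sum_k w_jk x_k, sigma2_j)
//   binary j:     P(x_j = 1 | rest) = plogis(theta_j + sum_k w_jk x_k)
// Uses R's RNG, so set.seed() on the R side makes draws reproducible.

// [[Rcpp::export]]
NumericMatrix gibbs_mgm_cpp(IntegerVector is_binary, NumericMatrix W,
                            NumericVector thresholds, NumericVector sigma2,
                            int n, int burn_in, int thin,
                            NumericVector init) {
  int p = W.nrow();
  NumericMatrix out(n, p);
  std::vector<double> x(p);
  for (int j = 0; j < p; ++j) x[j] = init[j];

  int total = burn_in + n * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) if (k != j) s += W(j, k) * x[k];
      if (is_binary[j]) {
        double pr = 1.0 / (1.0 + std::exp(-(thresholds[j] + s)));
        x[j] = (R::unif_rand() < pr) ? 1.0 : 0.0;
      } else {
        double mean = thresholds[j] + sigma2[j] * s;
        x[j] = R::norm_rand() * std::sqrt(sigma2[j]) + mean;
      }
    }
    if (sweep >= burn_in && ((sweep - burn_in + 1) % thin == 0)) {
      for (int j = 0; j < p; ++j) out(kept, j) = x[j];
      ++kept;
      if (kept == n) break;
    }
  }
  return out;
}
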