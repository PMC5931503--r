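#include <Rcpp.h>
using namespace Rcpp;

// Joint log posterior for one consumer observation.
//
// Parameters: f (K unconstrained reals -> diet proportions via softmax)
// and log_sigma (log residual SD per isotope).  Priors: f_k ~ N(0,1),
// sigma_j ~ half-Cauchy(0,1) (with the log-scale Jacobian).  Likelihood
// per isotope j: x_j ~ Normal(sum_k p_k (mu_kj + mu_TEF_j),
// sum_k p_k^2 (sd_kj^2 + sd_TEF_j^2) + sigma_j^2).
static double log_post(const NumericVector& f, const NumericVector& log_sigma,
                       const NumericVector& x, const NumericMatrix& mu,
                       const NumericMatrix& sd2, const NumericVector& tef_mu) {
  const int K = f.size(), J = x.size();
  // softmax
  double fmax = f[0];
  for (int k = 1; k < K; ++k) if (f[k] > fmax) fmax = f[k];
  std::vector<double> p(K);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { p[k] = std::exp(f[k] - fmax); tot += p[k]; }
  double lp = 0.0;
  for (int k = 0; k < K; ++k) {
    p[k] /= tot;
    lp += R::dnorm(f[k], 0.0, 1.0, 1);
  }
  for (int j = 0; j < J; ++j) {
    double sig = std::exp(log_sigma[j]);
    // half-Cauchy(0,1) on sigma plus Jacobian d sigma / d log sigma
    lp += std::log(M_2_PI) - std::log1p(sig * sig) + log_sigma[j];
    double m = 0.0, v = sig * sig;
    for (int k = 0; k < K; ++k) {
      m += p[k] * (mu(k, j) + tef_mu[j]);
      v += p[k] * p[k] * sd2(k, j);
    }
    lp += R::dnorm(x[j], m, std::sqrt(v), 1);
  }
  return lp;
}

// [[Rcpp::export(name = ".cpp_log_posterior")]]
double cpp_log_posterior(NumericVector f, NumericVector log_sigma,
                         NumericVector x, NumericMatrix mu, NumericMatrix sd2,
                         NumericVector tef_mu) {
  return log_post(f, log_sigma, x, mu, sd2, tef_mu);
}

// Adaptive random-walk Metropolis for one consumer and one chain.
// Uses R's RNG stream (seed it from R with set.seed before calling).
// Step size adapts towards `target_accept` during burn-in only.
//
// mu: K x 2 source means; sd2: K x 2 (source SD^2 + TEF SD^2).
// Returns kept p draws (n_keep x K), kept sigma draws (n_keep x 2),
// and the post-burn-in acceptance rate.
// [[Rcpp::export(name = ".cpp_sample_chain")]]
List cpp_sample_chain(NumericVector x, NumericMatrix mu, NumericMatrix sd2,
                      NumericVector tef_mu, int n_iter, int n_burnin,
                      NumericVector f_init, NumericVector log_sigma_init,
                      double target_accept = 0.3, bool sigma_fixed = false) {
  const int K = mu.nrow(), J = x.size();
  const int n_keep = n_iter - n_burnin;
  RNGScope scope;
  NumericVector f = clone(f_init), ls = clone(log_sigma_init);
  NumericVector f_prop(K), ls_prop(J);
  double lp = log_post(f, ls, x, mu, sd2, tef_mu);
  double log_step = std::log(0.5);
  NumericMatrix p_out(n_keep, K), sig_out(n_keep, J);
  int n_acc_post = 0;
  for (int t = 0; t < n_iter; ++t) {
    double step = std::exp(log_step);
    for (int k = 0; k < K; ++k) f_prop[k] = f[k] + step * norm_rand();
    for (int j = 0; j < J; ++j)
      ls_prop[j] = sigma_fixed ? ls[j] : ls[j] + step * norm_rand();
    double lp_prop = log_post(f_prop, ls_prop, x, mu, sd2, tef_mu);
    double lr = lp_prop - lp;
    bool accept = (lr >= 0.0) || (std::log(unif_rand()) < lr);
    if (accept) { f = clone(f_prop); ls = clone(ls_prop); lp = lp_prop; }
    if (t < n_burnin) {
      // Robbins-Monro adaptation, frozen at end of burn-in
      double acc_prob = std::min(1.0, std::exp(lr));
      log_step += (acc_prob - target_accept) / std::sqrt((double)(t + 1));
    } else {
      if (accept) ++n_acc_post;
      int r = t - n_burnin;
      double fmax = f[0];
      for (int k = 1; k < K; ++k) if (f[k] > fmax) fmax = f[k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { p_out(r, k) = std::exp(f[k] - fmax); tot += p_out(r, k); }
      for (int k = 0; k < K; ++k) p_out(r, k) /= tot;
      for (int j = 0; j < J; ++j) sig_out(r, j) = std::exp(ls[j]);
    }
  }
  return List::create(_["p"] = p_out, _["sigma"] = sig_out,
                      _["accept_rate"] = n_keep > 0 ? (double)n_acc_post / n_keep : NA_REAL,
                      _["step"] = std::exp(log_step));
}
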