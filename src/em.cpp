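#include <Rcpp.h>
using namespace Rcpp;

// One EM run for a univariate k-component Gaussian mixture.
// Returns the fitted parameters, the final log-likelihood, the per-iteration
// log-likelihood trace (used to assert EM monotonicity), and convergence info.
// Convergence: absolute log-likelihood improvement < tol, or maxit reached.
// [[Rcpp::export(name = ".em_run")]]
List em_run(NumericVector x, NumericVector w0, NumericVector mu0,
            NumericVector sd0, int maxit, double tol, double sd_floor) {
  const int n = x.size();
  const int k = mu0.size();
  const double log2pi = std::log(2.0 * M_PI);

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  NumericMatrix resp(n, k);
  std::vector<double> trace;
  trace.reserve(64);

  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  int iters = 0;

  for (int it = 0; it < maxit; ++it) {
    // E step: responsibilities and log-likelihood via log-sum-exp per point
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      double lp[64]; // k is small (<= 64 guarded in R wrapper)
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) / sd[j];
        lp[j] = std::log(w[j]) - std::log(sd[j]) - 0.5 * (log2pi + z * z);
        if (lp[j] > m) m = lp[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(lp[j] - m);
      double li = m + std::log(s);
      ll += li;
      for (int j = 0; j < k; ++j) resp(i, j) = std::exp(lp[j] - li);
    }
    trace.push_back(ll);
    iters = it + 1;
    if (it > 0 && ll - ll_old < tol) { converged = true; break; }
    ll_old = ll;

    // M step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nk += resp(i, j); sx += resp(i, j) * x[i]; }
      if (nk < 1e-12) nk = 1e-12;
      double m_new = sx / nk;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m_new;
        sv += resp(i, j) * d * d;
      }
      w[j] = nk / n;
      mu[j] = m_new;
      sd[j] = std::max(std::sqrt(sv / nk), sd_floor);
    }
  }

  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["means"] = NumericVector(mu.begin(), mu.end()),
    _["sds"] = NumericVector(sd.begin(), sd.end()),
    _["loglik"] = ll,
    _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
    _["iters"] = iters,
    _["converged"] = converged);
}
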