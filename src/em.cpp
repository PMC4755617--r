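#include <Rcpp.h>
using namespace Rcpp;

// One EM run for a univariate Gaussian mixture with unequal variances.
// Returns R_NilValue when a component collapses (responsibility mass ~ 0),
// so the caller can discard the start.
// [[Rcpp::export(name = ".em_run_cpp")]]
SEXP em_run_cpp(NumericVector d, NumericVector mu0, NumericVector v0,
                NumericVector w0, int max_iter, double tol,
                double variance_floor) {
  const int n = d.size(), k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> w(w0.begin(), w0.end());
  for (int j = 0; j < k; ++j) if (v[j] < variance_floor) v[j] = variance_floor;

  std::vector<double> r(static_cast<size_t>(n) * k);
  std::vector<double> nk(k), sum1(k), sum2(k);
  const double log2pi = std::log(2.0 * M_PI);

  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;

  while (true) {
    ++iter;
    // E step: log density + log weight, row-wise log-sum-exp
    ll = 0.0;
    for (int j = 0; j < k; ++j) {
      nk[j] = 0.0; sum1[j] = 0.0; sum2[j] = 0.0;
    }
    std::vector<double> lw(k), lv(k);
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(w[j]);
      lv[j] = 0.5 * (log2pi + std::log(v[j]));
    }
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double z = d[i] - mu[j];
        double lp = lw[j] - lv[j] - 0.5 * z * z / v[j];
        r[i + static_cast<size_t>(n) * j] = lp;
        if (lp > mx) mx = lp;
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j)
        s += std::exp(r[i + static_cast<size_t>(n) * j] - mx);
      ll += mx + std::log(s);
      for (int j = 0; j < k; ++j) {
        double rij = std::exp(r[i + static_cast<size_t>(n) * j] - mx) / s;
        r[i + static_cast<size_t>(n) * j] = rij;
      }
    }
    if (!R_finite(ll)) return R_NilValue;
    if (std::fabs(ll - ll_old) < tol) { converged = true; break; }
    if (iter > max_iter) break;
    ll_old = ll;
    // M step
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < n; ++i) {
        double rij = r[i + static_cast<size_t>(n) * j];
        nk[j] += rij;
        sum1[j] += rij * d[i];
      }
    for (int j = 0; j < k; ++j) {
      if (nk[j] < 1e-10) return R_NilValue;
      mu[j] = sum1[j] / nk[j];
    }
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < n; ++i) {
        double z = d[i] - mu[j];
        sum2[j] += r[i + static_cast<size_t>(n) * j] * z * z;
      }
      v[j] = sum2[j] / nk[j];
      if (v[j] < variance_floor) v[j] = variance_floor;
      w[j] = nk[j] / n;
    }
  }
  return List::create(_["weight"] = NumericVector(w.begin(), w.end()),
                      _["mean"] = NumericVector(mu.begin(), mu.end()),
                      _["variance"] = NumericVector(v.begin(), v.end()),
                      _["loglik"] = ll, _["converged"] = converged,
                      _["n_iter"] = iter);
}
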