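#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the linear L2-regularized L1-loss SVM
// (hinge loss, box-constrained dual). x already carries the bias column;
// y in {-1, +1}. Returns the primal weight vector.
// [[Rcpp::export]]
NumericVector svm_cd_solve(const NumericMatrix& x, const NumericVector& y,
                           const NumericVector& cost, int max_pass,
                           double tol) {
  const int n = x.nrow(), d = x.ncol();
  std::vector<double> alpha(n, 0.0), w(d, 0.0), q(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += x(i, j) * x(i, j);
    q[i] = s;
  }
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * x(i, j);
      double g = y[i] * wx - 1.0;
      const double ci = cost[i];
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= ci) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      if (std::fabs(pg) > 1e-12 && q[i] > 0.0) {
        double a_new = std::min(std::max(alpha[i] - g / q[i], 0.0), ci);
        double delta = a_new - alpha[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * y[i] * x(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
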