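#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear C-SVM (hinge loss) solved in the dual by cyclic coordinate descent,
// the standard solver for the L1-loss linear SVC dual. The intercept is
// handled as an augmented constant feature (and is therefore regularized),
// which keeps the problem strictly a box-constrained QP with no equality
// constraint. Deterministic: fixed visiting order, no shrinking heuristic.
//
//   min_w  1/2 (||w||^2 + b^2) + C sum_i max(0, 1 - y_i (w.x_i + b))
//
// [[Rcpp::export]]
List svm_linear_cpp(NumericMatrix X, NumericVector y, double cost,
                    double tol, int max_pass,
                    Nullable<NumericVector> alpha0 = R_NilValue) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("label length does not match rows of X");
  if (cost <= 0) stop("cost must be positive");

  // row-contiguous copy of X for cache-friendly dot products
  std::vector<double> Xr(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      Xr[static_cast<size_t>(i) * p + j] = X(i, j);

  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  double b = 0.0;
  if (alpha0.isNotNull()) {
    // warm start from a previous solution's dual variables (e.g. the next
    // smaller nested sub-ROI); w is rebuilt to stay consistent
    NumericVector a0(alpha0);
    if (a0.size() != n) stop("alpha0 length does not match rows of X");
    for (int i = 0; i < n; ++i) {
      alpha[i] = std::min(std::max(a0[i], 0.0), cost);
      if (alpha[i] != 0.0) {
        const double d = alpha[i] * y[i];
        const double *xi = &Xr[static_cast<size_t>(i) * p];
        for (int j = 0; j < p; ++j) w[j] += d * xi[j];
        b += d;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    const double *xi = &Xr[static_cast<size_t>(i) * p];
    double q = 1.0; // augmented intercept feature
    for (int j = 0; j < p; ++j) q += xi[j] * xi[j];
    qii[i] = q;
  }

  int pass = 0;
  bool converged = false;
  for (; pass < max_pass; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *xi = &Xr[static_cast<size_t>(i) * p];
      double dec = b;
      for (int j = 0; j < p; ++j) dec += w[j] * xi[j];
      const double G = y[i] * dec - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= cost && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (PG != 0.0) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > cost) a_new = cost;
        const double d = (a_new - alpha[i]) * y[i];
        if (d != 0.0) {
          alpha[i] = a_new;
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          b += d;
        }
      }
    }
    if (max_viol < tol) { converged = true; break; }
  }

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["bias"] = b,
                      _["passes"] = pass + 1,
                      _["converged"] = converged,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()));
}
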