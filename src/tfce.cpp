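#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// TFCE for the positive part of a 1D statistic curve: for every height step
// h, each point whose statistic reaches h accrues extent^E * h^H * dh, where
// extent is the length of the contiguous suprathreshold run containing it.
void tfce_positive(const std::vector<double> &t, double E, double H,
                   double dh, std::vector<double> &out) {
  const int n = static_cast<int>(t.size());
  double tmax = 0.0;
  for (int i = 0; i < n; ++i) if (t[i] > tmax) tmax = t[i];
  if (tmax <= 0.0 || dh <= 0.0) return;
  for (double h = dh; h <= tmax + 1e-12; h += dh) {
    const double hpow = std::pow(h, H) * dh;
    int i = 0;
    while (i < n) {
      if (t[i] >= h) {
        int j = i;
        while (j < n && t[j] >= h) ++j;
        const double add = std::pow(static_cast<double>(j - i), E) * hpow;
        for (int k = i; k < j; ++k) out[k] += add;
        i = j;
      } else {
        ++i;
      }
    }
  }
}

std::vector<double> tfce_1d_core(const std::vector<double> &t, double E,
                                 double H, double dh) {
  const int n = static_cast<int>(t.size());
  std::vector<double> out(n, 0.0), pos(n, 0.0), negv(n, 0.0), tneg(n);
  tfce_positive(t, E, H, dh, pos);
  for (int i = 0; i < n; ++i) tneg[i] = -t[i];
  tfce_positive(tneg, E, H, dh, negv);
  for (int i = 0; i < n; ++i) out[i] = pos[i] - negv[i];
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericVector tfce_curve_cpp(NumericVector t, double E, double H, double dh) {
  std::vector<double> tt(t.begin(), t.end());
  std::vector<double> out = tfce_1d_core(tt, E, H, dh);
  return NumericVector(out.begin(), out.end());
}

// Sign-flip null for the one-sample t curve across subjects: each permutation
// flips whole-subject curves, recomputes the t curve and its TFCE transform.
// Returns the n_perm x n_point matrix of enhanced null curves.
// [[Rcpp::export]]
NumericMatrix tfce_signflip_null_cpp(NumericMatrix curves, IntegerMatrix signs,
                                     double E, double H, double dh) {
  const int ns = curves.nrow(), np = curves.ncol();
  const int n_perm = signs.nrow();
  if (signs.ncol() != ns) stop("sign matrix does not match subject count");
  NumericMatrix out(n_perm, np);
  std::vector<double> tcur(np);
  const double sqn = std::sqrt(static_cast<double>(ns));
  for (int pm = 0; pm < n_perm; ++pm) {
    for (int k = 0; k < np; ++k) {
      double m = 0.0, m2 = 0.0;
      for (int s = 0; s < ns; ++s) {
        const double v = signs(pm, s) * curves(s, k);
        m += v;
        m2 += v * v;
      }
      m /= ns;
      double var = (m2 - ns * m * m) / (ns - 1);
      if (var < 0) var = 0;
      const double sd = std::sqrt(var);
      tcur[k] = (sd > 0) ? m / (sd / sqn) : 0.0;
    }
    std::vector<double> enh = tfce_1d_core(tcur, E, H, dh);
    for (int k = 0; k < np; ++k) out(pm, k) = enh[k];
  }
  return out;
}
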