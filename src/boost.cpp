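#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Componentwise gradient boosting for the binomial (logistic) loss with
// simple linear base learners, one per feature. Each iteration fits every
// base learner to the current negative gradient by least squares on the
// centred feature and takes a shrunken step (learning rate nu) along the best
// one. A feature counts as selected iff its base learner is picked in at
// least one iteration.
//
// The per-iteration gradient projections X^T u are one BLAS dgemv call.
// Returns coefficients on the original (uncentred) feature scale.
// [[Rcpp::export(name = ".cw_boost")]]
List cw_boost(NumericMatrix x, IntegerVector y, int mstop, double nu) {
  const int n = x.nrow(), p = x.ncol();
  std::vector<double> mean(p), ssq(p), xc((size_t)n * p);
  for (int j = 0; j < p; ++j) {
    const double* col = x.begin() + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i];
    mean[j] = s / n;
    double q = 0.0;
    double* cc = xc.data() + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      cc[i] = col[i] - mean[j];
      q += cc[i] * cc[i];
    }
    ssq[j] = q;
  }
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  // guard the offset against one-class folds
  ybar = std::min(std::max(ybar, 1e-12), 1.0 - 1e-12);
  const double offset = std::log(ybar / (1.0 - ybar));

  std::vector<double> f(n, offset), u(n), dots(p), beta(p, 0.0);
  std::vector<bool> used(p, false);
  const double one = 1.0, zero = 0.0;
  const int ione = 1;
  int iters = 0;
  for (int it = 0; it < mstop; ++it) {
    for (int i = 0; i < n; ++i) {
      u[i] = y[i] - 1.0 / (1.0 + std::exp(-f[i]));
    }
    F77_CALL(dgemv)("T", &n, &p, &one, xc.data(), &n, u.data(), &ione, &zero,
                    dots.data(), &ione FCONE);
    int best = -1;
    double best_red = 1e-12;
    for (int j = 0; j < p; ++j) {
      if (ssq[j] <= 0.0) continue;
      const double red = dots[j] * dots[j] / ssq[j];
      if (red > best_red) {
        best_red = red;
        best = j;
      }
    }
    if (best < 0) break; // gradient exhausted (saturation)
    const double step = nu * dots[best] / ssq[best];
    beta[best] += step;
    used[best] = true;
    const double* cc = xc.data() + (size_t)best * n;
    for (int i = 0; i < n; ++i) f[i] += step * cc[i];
    ++iters;
  }
  double intercept = offset;
  for (int j = 0; j < p; ++j) intercept -= beta[j] * mean[j];
  return List::create(
    _["intercept"] = intercept,
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["used"] = LogicalVector(used.begin(), used.end()),
    _["iterations"] = iters
  );
}
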