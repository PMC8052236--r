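// Soft-margin SVM with RBF kernel, trained by SMO with maximal-violating-pair
// working-set selection (the LIBSVM WSS-1 rule, no shrinking). Deterministic:
// no randomness enters training. The full kernel matrix is precomputed when it
// fits in a modest budget; otherwise the two active rows are recomputed per
// iteration (cheap for low-dimensional feature vectors).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double rbf(const double *xi, const double *xj, int d, double gamma) {
  double s = 0;
  for (int k = 0; k < d; ++k) {
    double t = xi[k] - xj[k];
    s += t * t;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".cpp_svm_train")]]
List cpp_svm_train(NumericMatrix X, NumericVector y, NumericVector Cw,
                   double gamma, double tol, double max_iter_mult) {
  const int n = X.nrow(), d = X.ncol();
  // row-major copy for cache-friendly kernel evaluation
  std::vector<double> xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k)
      xr[(size_t)i * d + k] = X(i, k);

  const bool full = (double)n * n <= 4.5e7; // <= ~360 MB of doubles
  std::vector<double> K;
  if (full) {
    K.resize((size_t)n * n);
    for (int i = 0; i < n; ++i) {
      K[(size_t)i * n + i] = 1.0;
      for (int j = i + 1; j < n; ++j) {
        double v = rbf(&xr[(size_t)i * d], &xr[(size_t)j * d], d, gamma);
        K[(size_t)i * n + j] = v;
        K[(size_t)j * n + i] = v;
      }
    }
  }
  std::vector<double> rowi(full ? 0 : n), rowj(full ? 0 : n);
  auto krow = [&](int i, std::vector<double> &buf) -> const double * {
    if (full) return &K[(size_t)i * n];
    for (int t = 0; t < n; ++t)
      buf[t] = rbf(&xr[(size_t)i * d], &xr[(size_t)t * d], d, gamma);
    return buf.data();
  };

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = grad of dual = (Qa)_i - 1
  const double *yy = REAL(y);
  long long max_iter = (long long)(max_iter_mult * std::max(n, 1000));
  long long it = 0;
  bool converged = false;

  for (; it < max_iter; ++it) {
    // i = argmax_{I_up} -y G ; j = argmin_{I_low} -y G
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -yy[t] * G[t];
      bool up = (yy[t] > 0) ? (alpha[t] < Cw[t]) : (alpha[t] > 0);
      bool low = (yy[t] > 0) ? (alpha[t] > 0) : (alpha[t] < Cw[t]);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { converged = true; break; }

    const double *Ki = krow(i, rowi);
    const double *Kj = krow(j, rowj);
    double eta = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (eta < 1e-12) eta = 1e-12;
    double step = (gmax - gmin) / eta; // unconstrained optimum along the pair
    double cap_i = (yy[i] > 0) ? (Cw[i] - alpha[i]) : alpha[i];
    double cap_j = (yy[j] > 0) ? alpha[j] : (Cw[j] - alpha[j]);
    if (step > cap_i) step = cap_i;
    if (step > cap_j) step = cap_j;
    alpha[i] += yy[i] * step;
    alpha[j] -= yy[j] * step;
    // d(alpha_i) = y_i*step, d(alpha_j) = -y_j*step keeps sum(y*alpha) = 0;
    // G_t += Q_ti d(alpha_i) + Q_tj d(alpha_j) with Q_ts = y_t y_s K_ts
    for (int t = 0; t < n; ++t)
      G[t] += step * yy[t] * (Ki[t] - Kj[t]);
  }

  // intercept: average y - F over free support vectors; fall back to the
  // midpoint of the violating-pair bounds
  double bsum = 0; int bn = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < Cw[t] - 1e-12) {
      // F_t = (Qa)_t * y_t = (G_t + 1) * y_t
      bsum += yy[t] - yy[t] * (G[t] + 1.0);
      ++bn;
    }
  }
  double b;
  if (bn > 0) {
    b = bsum / bn;
  } else {
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -yy[t] * G[t];
      bool up = (yy[t] > 0) ? (alpha[t] < Cw[t]) : (alpha[t] > 0);
      bool low = (yy[t] > 0) ? (alpha[t] > 0) : (alpha[t] < Cw[t]);
      if (up && v > gmax) gmax = v;
      if (low && v < gmin) gmin = v;
    }
    b = (gmax + gmin) / 2.0;
  }

  std::vector<int> sv;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12) sv.push_back(t);
  NumericMatrix Xsv((int)sv.size(), d);
  NumericVector coef((int)sv.size());
  IntegerVector svidx((int)sv.size());
  for (size_t s = 0; s < sv.size(); ++s) {
    int t = sv[s];
    for (int k = 0; k < d; ++k) Xsv((int)s, k) = X(t, k);
    coef[(R_xlen_t)s] = alpha[t] * yy[t];
    svidx[(R_xlen_t)s] = t + 1;
  }
  return List::create(_["sv"] = Xsv, _["coef"] = coef, _["b"] = b,
                      _["gamma"] = gamma, _["iterations"] = (double)it,
                      _["converged"] = converged, _["sv_index"] = svidx);
}

// decision(x) = sum_s coef_s K(sv_s, x) + b
// [[Rcpp::export(name = ".cpp_svm_decision")]]
NumericVector cpp_svm_decision(NumericMatrix Xsv, NumericVector coef, double b,
                               double gamma, NumericMatrix Xt) {
  const int ns = Xsv.nrow(), d = Xsv.ncol(), m = Xt.nrow();
  std::vector<double> sv((size_t)ns * d), xt((size_t)m * d);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < d; ++k) sv[(size_t)i * d + k] = Xsv(i, k);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) xt[(size_t)i * d + k] = Xt(i, k);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = b;
    for (int s = 0; s < ns; ++s)
      acc += coef[s] * rbf(&sv[(size_t)s * d], &xt[(size_t)i * d], d, gamma);
    out[i] = acc;
  }
  return out;
}
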