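// Dual solver for the soft-margin kernel SVM:
//   min_a  0.5 a' Q a - e' a   s.t.  0 <= a_i <= C,  y' a = 0,
// with Q_ij = y_i y_j K_ij, solved by SMO with second-order working-set
// selection on a precomputed kernel matrix. Stopping rule: maximal
// KKT violation below `eps`.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 200000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix must be square and match the label vector");
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // first index: largest KKT violation among the "up" set
    double Gmax = -INFINITY, Gmax2 = -INFINITY;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      if (y[t] == 1) {
        if (alpha[t] < C && -G[t] >= Gmax) { Gmax = -G[t]; i = t; }
      } else {
        if (alpha[t] > 0 && G[t] >= Gmax) { Gmax = G[t]; i = t; }
      }
    }
    if (i < 0) break;
    // second index: best second-order gain among the "low" set
    int j = -1;
    double obj_min = INFINITY;
    for (int t = 0; t < n; ++t) {
      double grad_diff;
      bool in_low;
      if (y[t] == 1) {
        in_low = alpha[t] > 0;
        if (in_low && G[t] >= Gmax2) Gmax2 = G[t];
        grad_diff = Gmax + G[t];
      } else {
        in_low = alpha[t] < C;
        if (in_low && -G[t] >= Gmax2) Gmax2 = -G[t];
        grad_diff = Gmax - G[t];
      }
      if (in_low && grad_diff > 0) {
        double quad = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (quad <= 0) quad = TAU;
        double obj = -(grad_diff * grad_diff) / quad;
        if (obj <= obj_min) { j = t; obj_min = obj; }
      }
    }
    if (Gmax + Gmax2 < eps || j < 0) break;

    const double old_ai = alpha[i], old_aj = alpha[j];
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = TAU;
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
  }

  // intercept from the free support vectors (midpoint of bounds otherwise)
  double ub = INFINITY, lb = -INFINITY, sum_free = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    const bool upper = alpha[t] >= C - 1e-12, lower = alpha[t] <= 1e-12;
    if (upper) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (lower) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nfree; sum_free += yG;
    }
  }
  const double rho = nfree > 0 ? sum_free / nfree : (ub + lb) / 2.0;

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj /= 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["objective"] = obj);
}
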