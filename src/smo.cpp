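#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Sequential minimal optimization for the soft-margin linear SVM dual
//
//   min_a  1/2 a' Q a - e' a    s.t. 0 <= a_i <= C,  y' a = 0
//
// with Q_ij = y_i y_j x_i . x_j. The bias is unregularized and recovered
// from the KKT conditions. Working-set selection follows the
// maximal-violating-pair scheme with a second-order gain criterion
// (the libsvm WSS2 rule); stopping rule is duality-gap style:
// m(a) - M(a) < eps.
//
// The linear kernel lets every gradient update run in O(n d) via the
// explicit weight-delta, so no kernel cache is needed.

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smoLinearSvm(NumericMatrix X, NumericVector y, double C,
                  double eps, int maxIter) {
  const int n = X.nrow();
  const int d = X.ncol();

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);       // gradient of the dual objective
  std::vector<double> Qd(n);            // diagonal of Q (= ||x_i||^2)
  // point-contiguous copy of X for cache-friendly dot products
  std::vector<double> P((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) P[(size_t)i * d + k] = X(i, k);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double *xi = &P[(size_t)i * d];
    for (int k = 0; k < d; ++k) s += xi[k] * xi[k];
    Qd[i] = s;
  }

  std::vector<double> dw(d);
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < maxIter; ++iter) {
    // i: argmax over I_up of -y_t G_t
    double Gmax = -std::numeric_limits<double>::infinity();
    int i = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (!up) continue;
      double v = -y[t] * G[t];
      if (v > Gmax) { Gmax = v; i = t; }
    }

    // j: over I_low, second-order gain given i; track M(a) for stopping
    double Gmin = std::numeric_limits<double>::infinity();
    double bestGain = -std::numeric_limits<double>::infinity();
    int j = -1;
    if (i >= 0) {
      const double *xi = &P[(size_t)i * d];
      for (int t = 0; t < n; ++t) {
        bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
        if (!low) continue;
        double v = -y[t] * G[t];
        if (v < Gmin) Gmin = v;
        double diff = Gmax - v;
        if (diff > 0) {
          const double *xt = &P[(size_t)t * d];
          double kit = 0.0;
          for (int k = 0; k < d; ++k) kit += xi[k] * xt[k];
          // curvature along the feasible direction: ||x_i - x_t||^2
          double quad = Qd[i] + Qd[t] - 2.0 * kit;
          if (quad <= TAU) quad = TAU;
          double gain = diff * diff / quad;
          if (gain > bestGain) { bestGain = gain; j = t; }
        }
      }
    }

    if (i < 0 || j < 0 || Gmax - Gmin < eps) { converged = true; break; }

    double kij = 0.0;
    for (int k = 0; k < d; ++k) kij += P[(size_t)i * d + k] * P[(size_t)j * d + k];

    double oldAi = alpha[i], oldAj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Qd[i] + Qd[j] - 2.0 * kij;
      if (quad <= TAU) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Qd[i] + Qd[j] - 2.0 * kij;
      if (quad <= TAU) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dAi = alpha[i] - oldAi, dAj = alpha[j] - oldAj;
    for (int k = 0; k < d; ++k)
      dw[k] = y[i] * dAi * P[(size_t)i * d + k] +
              y[j] * dAj * P[(size_t)j * d + k];
    for (int t = 0; t < n; ++t) {
      const double *xt = &P[(size_t)t * d];
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += xt[k] * dw[k];
      G[t] += y[t] * s;
    }
  }

  // w = sum_i alpha_i y_i x_i
  NumericVector w(d);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] == 0.0) continue;
    double c = alpha[t] * y[t];
    const double *xt = &P[(size_t)t * d];
    for (int k = 0; k < d; ++k) w[k] += c * xt[k];
  }

  // bias from free support vectors: b = -y_t G_t there; otherwise the
  // midpoint of the KKT-admissible interval.
  double bSum = 0.0; int nFree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0.0 && alpha[t] < C) { bSum += -y[t] * G[t]; ++nFree; }
  }
  double b;
  if (nFree > 0) {
    b = bSum / nFree;
  } else {
    // KKT: points in I_up bound b from below, points in I_low from
    // above; any b in [lb, ub] is optimal, take the midpoint
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > lb) lb = v;
      if (low && v < ub) ub = v;
    }
    b = (lb + ub) / 2.0;
    if (!std::isfinite(b)) b = 0.0;
  }

  // dual objective 1/2 a'Qa - e'a = 1/2 ||w||^2 - sum(a)
  double wn = 0.0; for (int k = 0; k < d; ++k) wn += w[k] * w[k];
  double sumA = 0.0; for (int t = 0; t < n; ++t) sumA += alpha[t];
  double dualObj = 0.5 * wn - sumA;

  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["dual_objective"] = dualObj);
}
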