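#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximal-violating-pair SMO for the C-SVC dual with a precomputed kernel:
//   min_a  0.5 a'Qa - e'a   s.t.  y'a = 0,  0 <= a <= C,   Q_ij = y_i y_j K_ij
// Small problems only (n of order tens); the kernel is dense in memory.

struct SmoFit {
  std::vector<double> alpha;
  double b;
  int iter;
};

static SmoFit smo_fit(const double* K, int n, const double* y, double C,
                      double eps, int max_iter) {
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0); // gradient of the dual objective
  int it = 0;
  double Gmax = 0.0, Gmin = 0.0;
  while (it < max_iter) {
    // first-order pick of i, second-order pick of j (libsvm-style WSS2)
    int i = -1, j = -1;
    Gmax = -1e300;
    Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) Gmin = v;
    }
    if (i < 0 || Gmax - Gmin < eps) break;
    double best_gain = -1.0;
    for (int t = 0; t < n; ++t) {
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!lo) continue;
      double diff = Gmax - (-y[t] * G[t]);
      if (diff <= 0) continue;
      double quad_t = K[i + n * i] + K[t + n * t] - 2.0 * K[i + n * t];
      if (quad_t <= 1e-12) quad_t = 1e-12;
      double gain = diff * diff / quad_t;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) break;
    // step t along d_alpha_i = +y_i, d_alpha_j = -y_j keeps y'a = 0
    double quad = K[i + n * i] + K[j + n * j] - 2.0 * K[i + n * j];
    if (quad <= 1e-12) quad = 1e-12;
    double t_star = (Gmax - (-y[j] * G[j])) / quad;
    double room_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double room_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    double t_step = std::min(t_star, std::min(room_i, room_j));
    alpha[i] += y[i] * t_step;
    alpha[j] -= y[j] * t_step;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * t_step * (K[t + n * i] - K[t + n * j]);
    }
    ++it;
  }
  // bias from the KKT conditions: b = -y_i G_i on free support vectors
  double tol = 1e-8 * (C > 1 ? C : 1);
  double bsum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > tol && alpha[t] < C - tol) {
      bsum += -y[t] * G[t];
      ++nfree;
    }
  }
  SmoFit fit;
  fit.alpha = alpha;
  fit.b = (nfree > 0) ? bsum / nfree : 0.5 * (Gmax + Gmin);
  fit.iter = it;
  return fit;
}

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C,
                   double eps = 1e-9, int max_iter = 1000000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label size mismatch");
  SmoFit fit = smo_fit(REAL(K), n, REAL(y), C, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b, _["iterations"] = fit.iter);
}

// Inner leave-one-out accuracy over a (beta, C) grid.
// kernels: list of M n x n kernel matrices (training samples only);
// betas: B x M matrix of kernel weights; Cs: vector of C values.
// Returns a B x length(Cs) matrix of LOO accuracies.
// [[Rcpp::export(name = ".mk_inner_loocv")]]
NumericMatrix mk_inner_loocv_cpp(List kernels, NumericVector y,
                                 NumericVector Cs, NumericMatrix betas,
                                 double eps = 1e-9, int max_iter = 1000000) {
  int M = kernels.size();
  if (betas.ncol() != M) stop("betas must have one column per kernel");
  NumericMatrix K0 = kernels[0];
  int n = K0.nrow();
  int B = betas.nrow(), nC = Cs.size();
  NumericMatrix acc(B, nC);
  std::vector<NumericMatrix> Kmats;
  std::vector<const double*> Kp(M);
  for (int m = 0; m < M; ++m) {
    Kmats.push_back(as<NumericMatrix>(kernels[m]));
    if (Kmats[m].nrow() != n || Kmats[m].ncol() != n)
      stop("kernel size mismatch");
    Kp[m] = REAL(Kmats[m]);
  }
  // combined kernel buffer and leave-one-out sub-kernel buffer
  std::vector<double> K(n * n), subK((n - 1) * (n - 1)), suby(n - 1);
  const double* yv = REAL(y);
  for (int bi = 0; bi < B; ++bi) {
    for (int p = 0; p < n * n; ++p) {
      double s = 0.0;
      for (int m = 0; m < M; ++m) s += betas(bi, m) * Kp[m][p];
      K[p] = s;
    }
    for (int ci = 0; ci < nC; ++ci) {
      double C = Cs[ci];
      int correct = 0;
      for (int out = 0; out < n; ++out) {
        int ns = n - 1, r = 0;
        for (int a = 0; a < n; ++a) {
          if (a == out) continue;
          suby[r] = yv[a];
          int c = 0;
          for (int bcol = 0; bcol < n; ++bcol) {
            if (bcol == out) continue;
            subK[r + ns * c] = K[a + n * bcol];
            ++c;
          }
          ++r;
        }
        SmoFit fit = smo_fit(subK.data(), ns, suby.data(), C, eps, max_iter);
        double f = fit.b;
        r = 0;
        for (int a = 0; a < n; ++a) {
          if (a == out) continue;
          f += fit.alpha[r] * suby[r] * K[a + n * out];
          ++r;
        }
        int pred = (f >= 0) ? 1 : -1;
        if (pred == (yv[out] > 0 ? 1 : -1)) ++correct;
      }
      acc(bi, ci) = (double)correct / n;
    }
  }
  return acc;
}
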