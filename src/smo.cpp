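#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin kernel SVM dual:
//   max_a  sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j K_ij
//   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0
// Working-set selection uses second-order information (the pair giving the
// largest guaranteed objective decrease), which copes with ill-conditioned
// kernels; the gradient is maintained incrementally.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  const double TAU = 1e-12;
  const double* Kp = REAL(K);   // column-major, symmetric
  std::vector<double> a(n, 0.0);
  // G_i = d/da_i of (1/2 a'Qa - e'a) with Q_ij = y_i y_j K_ij; a = 0 => -1
  std::vector<double> G(n, -1.0);

  int iter = 0;
  double gap = R_PosInf, thr = tol;
  while (iter < max_iter) {
    // i: maximal -y_i G_i over the "up" set
    int i = -1;
    double m = -R_PosInf, M = R_PosInf, gmax = 1.0;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1) ? (a[t] < C) : (a[t] > 0.0);
      bool lo = (y[t] == 1) ? (a[t] > 0.0) : (a[t] < C);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) M = v;
      if (std::abs(G[t]) > gmax) gmax = std::abs(G[t]);
    }
    gap = m - M;
    // tolerance is relative to the gradient scale (= decision-value units),
    // so unit-scale problems stop at an absolute gap of tol
    thr = tol * gmax;
    if (gap < thr || i < 0) break;

    // j: in the "down" set with -y_j G_j < m, minimizing -b^2/a
    const double* Ki = Kp + (size_t)i * n;
    const double Kii = Ki[i];
    int j = -1;
    double best = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool lo = (y[t] == 1) ? (a[t] > 0.0) : (a[t] < C);
      if (!lo) continue;
      double b = m + y[t] * G[t];
      if (b <= 0) continue;
      // curvature along the feasible pair direction: ||phi(x_i)-phi(x_t)||^2
      double quad = Kii + Kp[(size_t)t * n + t] - 2.0 * Ki[t];
      if (quad <= 0) quad = TAU;
      double score = -(b * b) / quad;
      if (score < best) { best = score; j = t; }
    }
    if (j < 0) break;

    const double* Kj = Kp + (size_t)j * n;
    double ai_old = a[i], aj_old = a[j];
    double Qii = Kii, Qjj = Kj[j], Kij = Ki[j];
    if (y[i] != y[j]) {
      double quad = Qii + Qjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) {
        if (a[j] < 0) { a[j] = 0; a[i] = diff; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = -diff; }
      }
      if (diff > 0) {
        if (a[i] > C) { a[i] = C; a[j] = C - diff; }
      } else {
        if (a[j] > C) { a[j] = C; a[i] = C + diff; }
      }
    } else {
      double quad = Qii + Qjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) {
        if (a[i] > C) { a[i] = C; a[j] = sum - C; }
      } else {
        if (a[j] < 0) { a[j] = 0; a[i] = sum; }
      }
      if (sum > C) {
        if (a[j] > C) { a[j] = C; a[i] = sum - C; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = sum; }
      }
    }

    double dai = y[i] * (a[i] - ai_old), daj = y[j] * (a[j] - aj_old);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (Ki[t] * dai + Kj[t] * daj);
    ++iter;
  }

  // objective on the maximization scale
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += a[t] * (1.0 - 0.5 * (G[t] + 1.0));

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["gap"] = gap,
                      _["converged"] = (gap < thr));
}
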