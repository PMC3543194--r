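#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the dual of the class-weighted
// soft-margin linear separator:
//   min_alpha  1/2 alpha' Q alpha - e' alpha
//   s.t.       0 <= alpha_i <= C_i,  sum_i y_i alpha_i = 0,
// with Q_ij = y_i y_j K_ij.  Maximal-violating-pair working-set selection;
// stops when the KKT gap m(alpha) - M(alpha) drops below tol.

static const double TAU = 1e-12;

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, NumericVector C,
               double tol = 1e-8, int max_iter = 10000000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n || C.size() != n)
    stop("inconsistent problem dimensions");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  std::vector<double> QD(n);
  for (int i = 0; i < n; ++i) QD[i] = K(i, i);

  int iter = 0;
  double gap = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: i in I_up maximizing -y G, j in I_low minimizing
    int i = -1, j = -1;
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1) ? (alpha[t] < C[t]) : (alpha[t] > 0.0);
      bool low = (y[t] == 1) ? (alpha[t] > 0.0) : (alpha[t] < C[t]);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (i == -1 || j == -1 || gap < tol) break;

    double Qij = y[i] * y[j] * K(i, j);
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = QD[i] + QD[j] + 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > C[i] - C[j]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; }
      } else {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; }
      }
    } else {
      double quad = QD[i] + QD[j] - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C[i]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C[j]) {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
  }

  // intercept b (decision function beta'x - b): midpoint of the feasible
  // interval given by the KKT conditions, matching the free-SV average
  // when free support vectors exist.
  double ub = R_PosInf, lb = -R_PosInf, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    bool at_lower = alpha[t] <= 0.0;
    bool at_upper = alpha[t] >= C[t];
    if (!at_lower && !at_upper) { sum_free += yG; ++n_free; }
    else if ((y[t] == 1 && at_upper) || (y[t] == -1 && at_lower)) {
      lb = std::max(lb, yG);
    } else {
      ub = std::min(ub, yG);
    }
  }
  double b;
  if (n_free > 0) b = sum_free / n_free;
  else b = (ub + lb) / 2.0;

  // dual objective 1/2 a'Qa - e'a = 1/2 sum a_t (G_t - 1)
  double dual = 0.0;
  for (int t = 0; t < n; ++t) dual += alpha[t] * (G[t] - 1.0);
  dual *= 0.5;

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["b"] = b,
    _["iterations"] = iter,
    _["kkt_gap"] = gap,
    _["converged"] = gap < tol,
    _["dual_objective"] = -dual  // value of the maximized dual
  );
}

// First-order Markov chain sampler used by the synthetic-data generator.
// init_cum: cumulative initial distribution (length 4); trans_cum: 4 x 4
// matrix of row-wise cumulative transition probabilities.  Uses R's RNG so
// results are reproducible under set.seed().

// [[Rcpp::export(name = ".markov_codes")]]
IntegerMatrix markov_codes(int n_seqs, int len, NumericVector init_cum,
                           NumericMatrix trans_cum) {
  IntegerMatrix out(n_seqs, len);
  for (int s = 0; s < n_seqs; ++s) {
    double u = unif_rand();
    int state = 0;
    while (state < 3 && u > init_cum[state]) ++state;
    out(s, 0) = state + 1;
    for (int p = 1; p < len; ++p) {
      u = unif_rand();
      int next = 0;
      while (next < 3 && u > trans_cum(state, next)) ++next;
      out(s, p) = next + 1;
      state = next;
    }
  }
  return out;
}
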