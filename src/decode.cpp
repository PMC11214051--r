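// Pairwise cross-validated linear-SVM decoding core.
//
// The decoding-accuracy dissimilarity requires on the order of 10^6
// tiny two-class SVM fits per participant (pairs x time points x
// permutations x folds), so the C-SVC dual is solved here with a
// working-set SMO specialized for the small training sets produced by
// split subaveraging (2 x (n_splits - 1) pseudo-trials per fit).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double TAU = 1e-12;

// Solve the C-SVC dual for a precomputed linear Gram matrix K and
// labels y (+1/-1).  Returns alpha and the intercept b so that the
// decision value of a point x is sum_t alpha_t y_t (x_t . x) + b.
static void smo_solve(const mat &K, const vec &y, double C,
                      vec &alpha, double &b,
                      int max_iter = 10000, double eps = 1e-3,
                      bool warm = false) {
  const int n = K.n_rows;
  if (!warm) alpha.zeros(n);
  // gradient of the dual objective at the (possibly warm) start
  vec G(n, fill::value(-1.0));
  if (warm)
    for (int t = 0; t < n; ++t) {
      double g = -1.0;
      for (int j = 0; j < n; ++j)
        g += alpha[j] * y[t] * y[j] * K(t, j);
      G[t] = g;
    }

  for (int iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    double Gmax = -datum::inf, Gmin = datum::inf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j) * y[i] * y[j];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0 && daj == 0) break;  // no progress possible (degenerate)
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * y[i] * K(t, i) * dai + y[t] * y[j] * K(t, j) * daj;
  }

  // intercept from free support vectors (KKT), else midpoint of the
  // feasible interval
  double rho_sum = 0; int nfree = 0;
  double ub = datum::inf, lb = -datum::inf;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { rho_sum += yG; ++nfree; }
    if (up && -yG < ub) ub = -yG;
    if (lo && -yG > lb) lb = -yG;
  }
  double rho;
  if (nfree > 0) rho = rho_sum / nfree;
  else if (std::isfinite(ub) && std::isfinite(lb)) rho = -(ub + lb) / 2.0;
  else rho = 0.0;
  b = -rho;
}

// Train a linear C-SVC on X (rows = samples) and return decision
// values for the rows of Xtest.
// [[Rcpp::export]]
Rcpp::List svm_train_cpp(const arma::mat &X, const arma::vec &y,
                         const arma::mat &Xtest, double C) {
  mat K = X * X.t();
  vec alpha; double b;
  smo_solve(K, y, C, alpha, b);
  vec dec = Xtest * (X.t() * (alpha % y));
  dec += b;
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("decision") = dec);
}

// Decode every unordered stimulus pair at every time point for one
// cross-validation fold.
//   train: channels x (ksplits * nstim) x time, columns grouped by
//          stimulus (split index fastest)
//   test:  channels x nstim x time (the held-out pseudo-trials)
// Returns pairs x time fold accuracies; pairs are ordered as the
// column-major strict lower triangle of an nstim x nstim matrix, i.e.
// (2,1), (3,1), ..., (n,1), (3,2), ...
// [[Rcpp::export]]
arma::mat decode_fold_cpp(const arma::cube &train, const arma::cube &test,
                          int ksplits, double C) {
  const int nT = train.n_slices;
  const int nstim = test.n_cols;
  const int npairs = nstim * (nstim - 1) / 2;
  const int m = 2 * ksplits;
  mat acc(npairs, nT);
  vec y(m);
  y.head(ksplits).fill(1.0);
  y.tail(ksplits).fill(-1.0);
  uvec cols(m);
  mat K(m, m);
  vec alpha; double b;

  // precompute training Grams and test-train inner products per slice
  std::vector<mat> Gram(nT), Gte(nT);
  for (int t = 0; t < nT; ++t) {
    const mat &Xtr = train.slice(t);
    Gram[t] = Xtr.t() * Xtr;
    Gte[t] = test.slice(t).t() * Xtr;
  }
  // pairs outer, time inner: the solution at the previous time point
  // warm-starts the SMO (adjacent samples carry similar geometry)
  int p = 0;
  for (int a = 0; a < nstim - 1; ++a) {
    for (int bst = a + 1; bst < nstim; ++bst) {
      for (int k = 0; k < ksplits; ++k) {
        cols[k] = a * ksplits + k;
        cols[ksplits + k] = bst * ksplits + k;
      }
      for (int t = 0; t < nT; ++t) {
        const mat &Gt = Gram[t];
        for (int r = 0; r < m; ++r)
          for (int c = 0; c < m; ++c)
            K(r, c) = Gt(cols[r], cols[c]);
        smo_solve(K, y, C, alpha, b, 10000, 1e-3, t > 0);
        double fa = b, fb = b;
        for (int k = 0; k < m; ++k) {
          double w = alpha[k] * y[k];
          fa += w * Gte[t](a, cols[k]);
          fb += w * Gte[t](bst, cols[k]);
        }
        double ca = fa > 0 ? 1.0 : (fa < 0 ? 0.0 : 0.5);
        double cb = fb < 0 ? 1.0 : (fb > 0 ? 0.0 : 0.5);
        acc(p, t) = 0.5 * (ca + cb);
      }
      ++p;
    }
  }
  return acc;
}
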