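// Radial-kernel support vector machines solved by sequential minimal
// optimization (SMO) with maximal-violating-pair working-set selection.
// One generic solver covers both C-classification (n variables) and
// epsilon-regression (2n variables via the alpha/alpha* stacking, with the
// kernel addressed modulo n).  Deterministic: no randomness in the solver.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat rbf_kernel(const arma::mat& A, const arma::mat& B,
                            double gamma) {
  arma::vec a2 = arma::sum(arma::square(A), 1);
  arma::vec b2 = arma::sum(arma::square(B), 1);
  arma::mat D = arma::repmat(a2, 1, B.n_rows) +
    arma::repmat(b2.t(), A.n_rows, 1) - 2.0 * A * B.t();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return arma::exp(-gamma * D);
}

// Generic SMO: minimize 1/2 a'Qa + p'a subject to 0 <= a_i <= C and
// sum_i y_i a_i = 0, where Q_ij = y_i y_j K(i mod n, j mod n).
// Returns alpha and the offset b of the decision function
// f(x) = sum_i y_i a_i K(x_i mod n, x) + b.
struct SmoResult { arma::vec alpha; double b; int iter; };

static SmoResult smo_solve(const arma::mat& K, const arma::vec& y,
                           const arma::vec& p, double C,
                           double tol, int max_iter) {
  const int m = y.n_elem;       // number of dual variables (n or 2n)
  const int n = K.n_rows;
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec g = p;              // gradient = Q alpha + p (alpha = 0)
  int it = 0;
  double b = 0.0;

  for (; it < max_iter; ++it) {
    // maximal violating pair on -y_t g_t
    int i = -1, j = -1;
    double gmax = -arma::datum::inf, gmin = arma::datum::inf;
    for (int t = 0; t < m; ++t) {
      const double v = -y[t] * g[t];
      const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    b = 0.5 * (gmax + gmin);
    if (gmax - gmin < tol || i < 0 || j < 0) break;

    const double Kii = K(i % n, i % n), Kjj = K(j % n, j % n),
                 Kij = K(i % n, j % n);
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 1e-12) eta = 1e-12;

    // two-variable subproblem along the constraint line
    const double Ei = y[i] * g[i], Ej = y[j] * g[j];
    double aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    aj_new = std::min(H, std::max(L, aj_new));
    const double dj = aj_new - alpha[j];
    if (std::fabs(dj) < 1e-14) break; // numerically stuck at optimum
    const double di = -y[i] * y[j] * dj;
    alpha[i] += di;
    alpha[j] += dj;

    // incremental gradient update: g += Q_col_i di + Q_col_j dj
    const double ci = y[i] * di, cj = y[j] * dj;
    for (int t = 0; t < m; ++t) {
      g[t] += y[t] * (ci * K(t % n, i % n) + cj * K(t % n, j % n));
    }
  }
  return {alpha, b, it};
}

// [[Rcpp::export]]
List cpp_svc_fit(const arma::mat& X, const arma::vec& y01, double C,
                 double gamma, double tol, int max_iter) {
  const int n = X.n_rows;
  arma::vec y = 2.0 * y01 - 1.0;
  arma::mat K = rbf_kernel(X, X, gamma);
  arma::vec p(n, arma::fill::value(-1.0));
  SmoResult res = smo_solve(K, y, p, C, tol, max_iter);
  arma::vec coef = res.alpha % y; // f(x) = sum coef_i K(x_i, x) + b
  return List::create(_["coef"] = coef, _["b"] = res.b,
                      _["iter"] = res.iter);
}

// [[Rcpp::export]]
List cpp_svr_fit(const arma::mat& X, const arma::vec& t, double C,
                 double gamma, double eps, double tol, int max_iter) {
  const int n = X.n_rows;
  arma::mat K = rbf_kernel(X, X, gamma);
  arma::vec y(2 * n), p(2 * n);
  for (int i = 0; i < n; ++i) {
    y[i] = 1.0;      p[i] = eps - t[i];     // alpha side
    y[n + i] = -1.0; p[n + i] = eps + t[i]; // alpha* side
  }
  SmoResult res = smo_solve(K, y, p, C, tol, max_iter);
  arma::vec coef(n);
  for (int i = 0; i < n; ++i) coef[i] = res.alpha[i] - res.alpha[n + i];
  return List::create(_["coef"] = coef, _["b"] = res.b,
                      _["iter"] = res.iter);
}

// [[Rcpp::export]]
arma::vec cpp_svm_decision(const arma::mat& Xtrain, const arma::vec& coef,
                           double b, double gamma, const arma::mat& Xnew) {
  arma::mat K = rbf_kernel(Xnew, Xtrain, gamma);
  return K * coef + b;
}
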