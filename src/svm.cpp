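// RBF-kernel C-SVC trained by sequential minimal optimization on a
// precomputed kernel. Working-set selection is the maximal violating
// pair; the dual is
//   min 1/2 a' Q a - e' a,  0 <= a <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& X, const arma::mat& Y, double gamma) {
  arma::vec sx = arma::sum(arma::square(X), 1);
  arma::vec sy = arma::sum(arma::square(Y), 1);
  arma::mat D = -2.0 * (X * Y.t());
  D.each_col() += sx;
  D.each_row() += sy.t();
  D.transform([gamma](double v) { return std::exp(-gamma * (v > 0 ? v : 0)); });
  return D;
}

// [[Rcpp::export]]
List smo_solve_cpp(const arma::mat& K, const arma::vec& y, double C,
                   double eps, int max_iter) {
  const int n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::value(-1.0)); // gradient of the dual
  int iter = 0;
  bool converged = false;
  double m_up = 0, m_low = 0;

  while (iter < max_iter) {
    // maximal violating pair
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) { converged = true; break; }

    double a = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a <= 0) a = 1e-12;
    double d = (m_up - m_low) / a; // optimal unconstrained step, > 0

    // box constraints: alpha_i += y_i d, alpha_j -= y_j d
    double hi = std::numeric_limits<double>::infinity();
    hi = std::min(hi, y[i] > 0 ? C - alpha[i] : alpha[i]);
    hi = std::min(hi, y[j] > 0 ? alpha[j] : C - alpha[j]);
    if (d > hi) d = hi;
    if (d <= 0) { converged = true; break; } // numerically stuck at a bound

    double dai = y[i] * d, daj = -y[j] * d;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
    ++iter;
  }

  // intercept: b = -y_t G_t averaged over free vectors, else midpoint
  double bsum = 0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      bsum += -y[t] * G[t];
      ++nfree;
    }
  }
  double b = nfree > 0 ? bsum / nfree : (m_up + m_low) / 2.0;

  double obj = 0.5 * arma::dot(alpha % y, K * (alpha % y)) - arma::sum(alpha);
  return List::create(_["alpha"] = alpha, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged, _["objective"] = obj);
}
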