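// Exact (O(n^2)) t-SNE gradient descent. The symmetrized input affinity
// matrix P is computed on the R side (perplexity calibration by binary
// search); this routine runs the standard optimization: early exaggeration,
// momentum switching, and per-coordinate adaptive gains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

// Conditional-affinity calibration: per-point binary search for the
// Gaussian precision matching the requested perplexity, then
// symmetrization P = (P + P^T) / (2n).
// [[Rcpp::export(name = ".tsne_affinities")]]
arma::mat tsne_affinities_cpp(const arma::mat& D2, double perplexity,
                              double tol = 1e-5, int max_iter = 50) {
  const int n = D2.n_rows;
  const double logU = std::log(perplexity);
  mat P(n, n, fill::zeros);
  vec w(n);
  for (int i = 0; i < n; ++i) {
    // bracketing flags instead of +-inf sentinels: the search must stay
    // correct under finite-math-only compilation
    double beta = 1.0, lo = 0.0, hi = 0.0;
    bool has_lo = false, has_hi = false;
    for (int it = 0; it < max_iter; ++it) {
      double sw = 0.0, sdw = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { w(j) = 0.0; continue; }
        w(j) = std::exp(-D2(i, j) * beta);
        sw += w(j);
        sdw += D2(i, j) * w(j);
      }
      if (sw <= 0) { w.fill(1.0 / (n - 1)); w(i) = 0; sw = 1.0; sdw = 0.0; }
      const double H = std::log(sw) + beta * sdw / sw;
      if (std::abs(H - logU) < tol) break;
      if (H > logU) {
        lo = beta; has_lo = true;
        beta = has_hi ? (beta + hi) / 2 : beta * 2;
      } else {
        hi = beta; has_hi = true;
        beta = has_lo ? (beta + lo) / 2 : beta / 2;
      }
    }
    P.row(i) = w.t() / accu(w);
  }
  P = (P + P.t()) / (2.0 * n);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  return P;
}

// [[Rcpp::export(name = ".tsne_optimize")]]
arma::mat tsne_optimize(const arma::mat& P, int seed, int n_iter = 1000,
                        double learning_rate = 1000.0,
                        double early_exaggeration = 12.0, int exag_iter = 250,
                        int mom_switch = 250) {
  const int n = P.n_rows;
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1e-4);
  mat Y(n, 2);
  for (uword i = 0; i < Y.n_elem; ++i) Y(i) = gauss(rng);

  mat dY(n, 2, fill::zeros), gains(n, 2, fill::ones), grad(n, 2);
  for (int it = 0; it < n_iter; ++it) {
    const double exag = (it < exag_iter) ? early_exaggeration : 1.0;
    // pairwise Student-t kernel
    double Z = 0.0;
    grad.zeros();
    // first pass: normalization constant
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double dx = Y(i, 0) - Y(j, 0), dy = Y(i, 1) - Y(j, 1);
        Z += 2.0 / (1.0 + dx * dx + dy * dy);
      }
    if (Z < 1e-300) Z = 1e-300;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double dx = Y(i, 0) - Y(j, 0), dy = Y(i, 1) - Y(j, 1);
        const double num = 1.0 / (1.0 + dx * dx + dy * dy);
        const double q = num / Z;
        const double m = 4.0 * (exag * P(i, j) - q) * num;
        grad(i, 0) += m * dx; grad(i, 1) += m * dy;
        grad(j, 0) -= m * dx; grad(j, 1) -= m * dy;
      }
    const double momentum = (it < mom_switch) ? 0.5 : 0.8;
    for (uword e = 0; e < gains.n_elem; ++e) {
      gains(e) = (std::signbit(grad(e)) != std::signbit(dY(e)))
                   ? gains(e) + 0.2 : gains(e) * 0.8;
      if (gains(e) < 0.01) gains(e) = 0.01;
    }
    dY = momentum * dY - learning_rate * (gains % grad);
    Y += dY;
    Y.each_row() -= mean(Y, 0);  // keep solution centred
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Y;
}
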