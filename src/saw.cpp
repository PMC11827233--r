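// Confined self-avoiding homopolymer walks: consecutive beads at bond
// length, non-bonded beads no closer than min_dist, all beads inside a
// sphere of radius R_max. Rejection sampling with per-step retries and
// whole-walk restarts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

// [[Rcpp::export(name = ".saw_walk")]]
arma::mat saw_walk(int n_beads, double bond, double min_dist, double R_max,
                   int seed, int max_tries = 100, int max_restarts = 10000) {
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double md2 = min_dist * min_dist, R2 = R_max * R_max;
  mat X(n_beads, 3);
  for (int restart = 0; restart < max_restarts; ++restart) {
    // random start inside the allowed sphere
    for (;;) {
      for (int d = 0; d < 3; ++d) X(0, d) = (2 * unif(rng) - 1) * R_max;
      if (dot(X.row(0), X.row(0)) <= R2) break;
    }
    bool ok = true;
    for (int i = 1; i < n_beads && ok; ++i) {
      bool placed = false;
      for (int t = 0; t < max_tries; ++t) {
        vec dir(3);
        for (int d = 0; d < 3; ++d) dir(d) = gauss(rng);
        dir /= norm(dir);
        rowvec cand = X.row(i - 1) + bond * dir.t();
        if (dot(cand, cand) > R2) continue;
        bool clash = false;
        for (int j = 0; j < i - 1; ++j) {
          rowvec dlt = cand - X.row(j);
          if (dot(dlt, dlt) < md2) { clash = true; break; }
        }
        if (!clash) { X.row(i) = cand; placed = true; break; }
      }
      if (!placed) ok = false;
    }
    if (ok) return X;
  }
  Rcpp::stop("self-avoiding walk failed; try a larger nucleus");
}
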