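// Watershed-like basin extraction on a density grid. For each detected peak
// the density level is raised through `nlevels` evenly spaced levels from 0
// to the grid maximum; the first (lowest) level at which the 8-connected
// super-level component containing the peak contains no other peak defines
// the peak's basin. Basins of different peaks are disjoint by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>

using namespace arma;

namespace {

// 8-connected component labelling of mask (>0), labels start at 1.
void label_components(const std::vector<char>& mask, int H, int W,
                      std::vector<int>& lab) {
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      const int s0 = c0 * H + r0;
      if (!mask[s0] || lab[s0]) continue;
      ++next;
      lab[s0] = next;
      stack.assign(1, s0);
      while (!stack.empty()) {
        const int s = stack.back(); stack.pop_back();
        const int r = s % H, c = s / H;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int r2 = r + dr, c2 = c + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            const int s2 = c2 * H + r2;
            if (mask[s2] && !lab[s2]) { lab[s2] = next; stack.push_back(s2); }
          }
      }
    }
}

} // namespace

// P: density grid; peaks: k x 2 matrix of 1-based (row, col) indices.
// Returns an integer matrix of the same shape as P with basin cells labelled
// 1..k (0 = no basin). Peaks that never isolate keep label 0.
// [[Rcpp::export(name = ".watershed_regions")]]
Rcpp::IntegerMatrix watershed_regions(const arma::mat& P,
                                      const arma::imat& peaks, int nlevels) {
  const int H = P.n_rows, W = P.n_cols, K = peaks.n_rows;
  const double pmax = P.max();
  Rcpp::IntegerMatrix out(H, W);
  std::vector<char> mask((size_t)H * W);
  std::vector<int> lab((size_t)H * W);
  std::vector<bool> resolved(K, false);
  std::vector<int> peak_site(K);
  for (int k = 0; k < K; ++k)
    peak_site[k] = ((int)peaks(k, 1) - 1) * H + ((int)peaks(k, 0) - 1);

  for (int t = 0; t < nlevels; ++t) {
    const double level = pmax * t / nlevels;
    bool all_done = true;
    for (int k = 0; k < K; ++k) if (!resolved[k]) { all_done = false; break; }
    if (all_done) break;
    for (size_t i = 0; i < mask.size(); ++i) mask[i] = P(i) > level;
    label_components(mask, H, W, lab);
    // count peaks per component
    std::vector<int> cnt;
    for (int k = 0; k < K; ++k) {
      const int comp = lab[peak_site[k]];
      if (comp >= (int)cnt.size()) cnt.resize(comp + 1, 0);
      if (comp > 0) ++cnt[comp];
    }
    for (int k = 0; k < K; ++k) {
      if (resolved[k]) continue;
      const int comp = lab[peak_site[k]];
      if (comp > 0 && cnt[comp] == 1) {
        for (size_t i = 0; i < lab.size(); ++i)
          if (lab[i] == comp && out[i] == 0) out[i] = k + 1;
        resolved[k] = true;
      }
    }
  }
  return out;
}
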