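// Convolutional autoencoder for square single-channel matrices.
//
// Architecture (configurable): encoder = [conv(k x k, same, ReLU) -> maxpool]
// repeated; decoder = [conv -> nearest-neighbour upsample] repeated, followed
// by a final 1-filter conv with sigmoid activation. Training minimizes MSE
// with Adadelta (rho 0.95, eps 1e-7, lr 1.0). 'same' padding for even
// kernels pads (k-1)/2 before and the remainder after, so output size equals
// input size at stride 1.
//
// Internals run in single precision with preallocated per-layer workspaces.
// Convolutions with a small im2col footprint go through im2col + GEMM;
// large ones (the full-resolution first and last layers) use a direct
// plane-sliding accumulation that keeps the working set in cache.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

namespace {

enum LayerKind { CONV, POOL, UPSAMP };
enum Act { RELU, SIGMOID };

const uword IM2COL_MAX = 2000000;  // elements; above this use the plane path

struct Layer {
  LayerKind kind;
  int cin = 0, cout = 0, k = 0;   // conv
  int factor = 0;                 // pool window / upsample factor
  Act act = RELU;
  fmat W;  fvec b;                // conv parameters
  fmat gW; fvec gb;               // gradient accumulators (per batch)
  fmat EgW, EdW; fvec Egb, Edb;   // Adadelta accumulators
  // workspaces (shapes fixed once the input side is known)
  int inH = 0, inW = 0, outC = 0;
  bool use_col = false;
  fmat col;                       // im2col buffer
  fmat dcol;                      // backward im2col buffer
  fcube out;                      // post-activation output
  fcube dIn;                      // gradient w.r.t. this layer's input
  uvec argmax;                    // maxpool winners
};

std::vector<Layer> build_layers(const Rcpp::List& arch) {
  Rcpp::IntegerVector encf = arch["enc_filters"], pools = arch["pools"],
                      decf = arch["dec_filters"], ups = arch["ups"];
  const int k = Rcpp::as<int>(arch["kernel"]);
  std::vector<Layer> ls;
  int prev = 1;
  for (int i = 0; i < encf.size(); ++i) {
    Layer c; c.kind = CONV; c.cin = prev; c.cout = encf[i]; c.k = k;
    ls.push_back(c);
    Layer p; p.kind = POOL; p.factor = pools[i];
    ls.push_back(p);
    prev = encf[i];
  }
  for (int i = 0; i < decf.size(); ++i) {
    Layer c; c.kind = CONV; c.cin = prev; c.cout = decf[i]; c.k = k;
    ls.push_back(c);
    Layer u; u.kind = UPSAMP; u.factor = ups[i];
    ls.push_back(u);
    prev = decf[i];
  }
  Layer fin; fin.kind = CONV; fin.cin = prev; fin.cout = 1; fin.k = k;
  fin.act = SIGMOID;
  ls.push_back(fin);
  return ls;
}

// Fix shapes and allocate all workspaces for a given input side.
void setup(std::vector<Layer>& ls, int side) {
  int H = side, W = side, C = 1;
  for (auto& l : ls) {
    l.inH = H; l.inW = W;
    if (l.kind == CONV) {
      l.outC = l.cout;
      l.use_col = (uword)H * W * l.k * l.k * l.cin <= IM2COL_MAX;
      if (l.use_col) {
        l.col.zeros((uword)H * W, (uword)l.k * l.k * l.cin);
        l.dcol.set_size((uword)H * W, (uword)l.k * l.k * l.cin);
      }
      C = l.cout;
    } else if (l.kind == POOL) {
      l.outC = C;
      l.argmax.set_size((uword)(H / l.factor) * (W / l.factor) * C);
      H /= l.factor; W /= l.factor;
    } else {
      l.outC = C;
      H *= l.factor; W *= l.factor;
    }
    l.out.set_size(H, W, l.outC);
    l.dIn.set_size(l.inH, l.inW, l.kind == CONV ? l.cin : l.outC);
  }
}

void init_params(std::vector<Layer>& ls, std::mt19937& rng) {
  for (auto& l : ls) {
    if (l.kind != CONV) continue;
    const int fan_in = l.k * l.k * l.cin, fan_out = l.k * l.k * l.cout;
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> u(-lim, lim);
    l.W.set_size(fan_in, l.cout);
    for (uword i = 0; i < l.W.n_elem; ++i) l.W(i) = (float)u(rng);
    l.b.zeros(l.cout);
    l.gW.zeros(fan_in, l.cout); l.gb.zeros(l.cout);
    l.EgW.zeros(fan_in, l.cout); l.EdW.zeros(fan_in, l.cout);
    l.Egb.zeros(l.cout); l.Edb.zeros(l.cout);
  }
}

void set_params(std::vector<Layer>& ls, const Rcpp::List& Ws,
                const Rcpp::List& bs) {
  int j = 0;
  for (auto& l : ls) {
    if (l.kind != CONV) continue;
    l.W = conv_to<fmat>::from(Rcpp::as<mat>(Ws[j]));
    l.b = conv_to<fvec>::from(Rcpp::as<vec>(bs[j]));
    l.gW.zeros(l.W.n_rows, l.W.n_cols);
    l.gb.zeros(l.b.n_elem);
    ++j;
  }
}

// im2col into the preallocated buffer (column j holds the (kr, kc, ci) tap).
void fill_col(const fcube& X, int k, fmat& col) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int padb = (k - 1) / 2;
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const fmat& S = X.slice(ci);
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int j = ci * k * k + kc * k + kr;
        const int roff = kr - padb, coff = kc - padb;
        float* dst = col.colptr(j);
        for (int c = 0; c < W; ++c) {
          const int c2 = c + coff;
          if (c2 < 0 || c2 >= W) continue;
          const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
          const float* src = S.colptr(c2);
          for (int r = r0; r < r1; ++r) dst[c * H + r] = src[r + roff];
        }
      }
  }
}

void col2im_add(const fmat& dcol, int k, fcube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  const int padb = (k - 1) / 2;
  dX.zeros();
  for (int ci = 0; ci < C; ++ci) {
    fmat& S = dX.slice(ci);
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int j = ci * k * k + kc * k + kr;
        const int roff = kr - padb, coff = kc - padb;
        const float* src = dcol.colptr(j);
        for (int c = 0; c < W; ++c) {
          const int c2 = c + coff;
          if (c2 < 0 || c2 >= W) continue;
          const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
          float* dst = S.colptr(c2);
          for (int r = r0; r < r1; ++r) dst[r + roff] += src[c * H + r];
        }
      }
  }
}

// Direct plane convolution for layers whose im2col would be large. Each
// (input channel, kernel column, output channel) triple is one vertical
// 1-D convolution per image column, with the k row-taps held in registers:
// one pass over the column instead of k.
void conv_forward_plane(const fcube& X, const fmat& W_, const fvec& b,
                        int k, fcube& Y) {
  const int H = X.n_rows, W = X.n_cols;
  const int padb = (k - 1) / 2;
  const int Co = Y.n_slices;
  for (int co = 0; co < Co; ++co) Y.slice(co).fill(b(co));
  for (int ci = 0; ci < (int)X.n_slices; ++ci) {
    const fmat& Xs = X.slice(ci);
    for (int kc = 0; kc < k; ++kc) {
      const int coff = kc - padb;
      const int c0 = std::max(0, -coff), c1 = std::min(W, W - coff);
      // x and y columns stay in L1 across the co / kr sweeps
      for (int c = c0; c < c1; ++c) {
        const float* xp = Xs.colptr(c + coff);
        for (int co = 0; co < Co; ++co) {
          float* yp = Y.slice(co).colptr(c);
          const float* wp = W_.colptr(co) + ci * k * k + kc * k;
          for (int kr = 0; kr < k; ++kr) {
            const float w = wp[kr];
            const int roff = kr - padb;
            const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
            const float* xq = xp + roff;
            for (int r = r0; r < r1; ++r) yp[r] += w * xq[r];
          }
        }
      }
    }
  }
}

void conv_backward_plane(const fcube& X, const fmat& W_, const fcube& dY,
                         int k, fmat& gW, fvec& gb, fcube* dX) {
  const int H = X.n_rows, W = X.n_cols;
  const int padb = (k - 1) / 2;
  const int Co = dY.n_slices;
  for (int co = 0; co < Co; ++co) gb(co) += accu(dY.slice(co));
  if (dX) dX->zeros();
  for (int ci = 0; ci < (int)X.n_slices; ++ci) {
    const fmat& Xs = X.slice(ci);
    for (int kc = 0; kc < k; ++kc) {
      const int coff = kc - padb;
      const int c0 = std::max(0, -coff), c1 = std::min(W, W - coff);
      for (int c = c0; c < c1; ++c) {
        const float* xp = Xs.colptr(c + coff);
        float* dxp = dX ? dX->slice(ci).colptr(c + coff) : nullptr;
        for (int co = 0; co < Co; ++co) {
          const float* dp = dY.slice(co).colptr(c);
          const float* wp = W_.colptr(co) + ci * k * k + kc * k;
          float* gp = gW.colptr(co) + ci * k * k + kc * k;
          for (int kr = 0; kr < k; ++kr) {
            const int roff = kr - padb;
            const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
            const float* xq = xp + roff;
            float acc = 0.0f;
            for (int r = r0; r < r1; ++r) acc += xq[r] * dp[r];
            gp[kr] += acc;
            if (dxp) {
              const float w = wp[kr];
              float* dq = dxp + roff;
              for (int r = r0; r < r1; ++r) dq[r] += w * dp[r];
            }
          }
        }
      }
    }
  }
}

// Forward pass; `x` must have the side the workspaces were set up for.
// Caches the intermediates needed for backprop.
const fcube& forward(std::vector<Layer>& ls, const fcube& x) {
  const fcube* cur = &x;
  for (auto& l : ls) {
    if (l.kind == CONV) {
      const uword HW = (uword)l.inH * l.inW;
      if (l.use_col) {
        fill_col(*cur, l.k, l.col);
        fmat outm(l.out.memptr(), HW, l.cout, false, true);
        outm = l.col * l.W;
        outm.each_row() += l.b.t();
      } else {
        conv_forward_plane(*cur, l.W, l.b, l.k, l.out);
      }
      fmat outm(l.out.memptr(), HW, l.cout, false, true);
      if (l.act == RELU)
        outm.transform([](float v) { return v > 0 ? v : 0.0f; });
      else
        outm.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
    } else if (l.kind == POOL) {
      const int p = l.factor, H = cur->n_rows, W = cur->n_cols,
                C = cur->n_slices;
      const int Ho = H / p, Wo = W / p;
      for (int ci = 0; ci < C; ++ci)
        for (int c = 0; c < Wo; ++c)
          for (int r = 0; r < Ho; ++r) {
            uword bidx = (uword)ci * H * W + (uword)(c * p) * H + (r * p);
            float best = (*cur)(bidx);
            for (int dc = 0; dc < p; ++dc)
              for (int dr = 0; dr < p; ++dr) {
                const uword idx = (uword)ci * H * W + (uword)(c * p + dc) * H +
                                  (r * p + dr);
                const float v = (*cur)(idx);
                if (v > best) { best = v; bidx = idx; }
              }
            l.out(r, c, ci) = best;
            l.argmax((uword)ci * Ho * Wo + (uword)c * Ho + r) = bidx;
          }
    } else { // UPSAMP
      const int f = l.factor, H = cur->n_rows, W = cur->n_cols,
                C = cur->n_slices;
      for (int ci = 0; ci < C; ++ci)
        for (int c = 0; c < W * f; ++c) {
          const float* src = cur->slice(ci).colptr(c / f);
          float* dst = l.out.slice(ci).colptr(c);
          for (int r = 0; r < H * f; ++r) dst[r] = src[r / f];
        }
    }
    cur = &l.out;
  }
  return *cur;
}

// Backward from dTop (gradient w.r.t. the network output, pre-activation
// handling included here). Accumulates gW / gb; per-layer dIn buffers carry
// the gradient towards the input (the first layer's dIn is skipped).
void backward(std::vector<Layer>& ls, const fcube& x, fcube& dTop) {
  fcube* dOut = &dTop;
  for (int li = (int)ls.size() - 1; li >= 0; --li) {
    Layer& l = ls[li];
    const fcube& input = (li == 0) ? x : ls[li - 1].out;
    if (l.kind == CONV) {
      const uword HW = (uword)l.inH * l.inW;
      fmat dY(dOut->memptr(), HW, l.cout, false, true);
      fmat outm(l.out.memptr(), HW, l.cout, false, true);
      if (l.act == RELU) {
        for (uword i = 0; i < dY.n_elem; ++i)
          if (outm(i) <= 0) dY(i) = 0;
      } else {
        for (uword i = 0; i < dY.n_elem; ++i)
          dY(i) *= outm(i) * (1.0f - outm(i));
      }
      if (l.use_col) {
        l.gW += l.col.t() * dY;
        l.gb += sum(dY, 0).t();
        if (li > 0) {
          l.dcol = dY * l.W.t();
          col2im_add(l.dcol, l.k, l.dIn);
        }
      } else {
        conv_backward_plane(input, l.W, *dOut, l.k, l.gW, l.gb,
                            li > 0 ? &l.dIn : nullptr);
      }
    } else if (l.kind == POOL) {
      l.dIn.zeros();
      for (uword i = 0; i < dOut->n_elem; ++i)
        l.dIn(l.argmax(i)) += (*dOut)(i);
    } else { // UPSAMP
      const int f = l.factor;
      l.dIn.zeros();
      for (uword ci = 0; ci < dOut->n_slices; ++ci)
        for (uword c = 0; c < dOut->n_cols; ++c) {
          const float* src = dOut->slice(ci).colptr(c);
          float* dst = l.dIn.slice(ci).colptr(c / f);
          for (uword r = 0; r < dOut->n_rows; ++r) dst[r / f] += src[r];
        }
    }
    if (li > 0) dOut = &l.dIn;
  }
}

void adadelta_step(std::vector<Layer>& ls, float rho, float eps) {
  for (auto& l : ls) {
    if (l.kind != CONV) continue;
    l.EgW = rho * l.EgW + (1 - rho) * square(l.gW);
    fmat dW = -(sqrt(l.EdW + eps) / sqrt(l.EgW + eps)) % l.gW;
    l.EdW = rho * l.EdW + (1 - rho) * square(dW);
    l.W += dW;
    l.Egb = rho * l.Egb + (1 - rho) * square(l.gb);
    fvec db = -(sqrt(l.Edb + eps) / sqrt(l.Egb + eps)) % l.gb;
    l.Edb = rho * l.Edb + (1 - rho) * square(db);
    l.b += db;
    l.gW.zeros(); l.gb.zeros();
  }
}

Rcpp::List export_params(const std::vector<Layer>& ls) {
  Rcpp::List Ws, bs;
  for (const auto& l : ls)
    if (l.kind == CONV) {
      Ws.push_back(Rcpp::wrap(conv_to<mat>::from(l.W)));
      bs.push_back(Rcpp::wrap(conv_to<vec>::from(l.b)));
    }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

} // namespace

// data: (side*side) x n matrix, each column one input image (column-major).
// [[Rcpp::export(name = ".cae_train")]]
Rcpp::List cae_train(const arma::mat& data, int side, Rcpp::List arch,
                     int epochs, int batch, int seed) {
  std::vector<Layer> ls = build_layers(arch);
  std::mt19937 rng((unsigned)seed);
  init_params(ls, rng);
  setup(ls, side);
  const fmat fdata = conv_to<fmat>::from(data);
  const int n = fdata.n_cols;
  const double npix = (double)side * side;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> losses;
  fcube diff(side, side, 1);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double eploss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch) {
      const int bend = std::min(n, start + batch);
      const int bs = bend - start;
      double bloss = 0.0;
      for (int s = start; s < bend; ++s) {
        fcube x(const_cast<float*>(fdata.colptr(idx[s])), side, side, 1,
                false, true);
        const fcube& y = forward(ls, x);
        diff = y - x;
        bloss += accu(square(diff)) / npix;
        diff *= (float)(2.0 / (npix * bs));
        backward(ls, x, diff);
      }
      adadelta_step(ls, 0.95f, 1e-7f);
      eploss += bloss / bs;
      ++nb;
      Rcpp::checkUserInterrupt();
    }
    losses.push_back(eploss / nb);
  }
  Rcpp::List params = export_params(ls);
  params["loss"] = losses;
  return params;
}

// Analytic MSE gradient at given parameters, accumulated over the provided
// samples (batch-mean convention). The oracle hook for gradient tests.
// [[Rcpp::export(name = ".cae_gradient")]]
Rcpp::List cae_gradient(const arma::mat& data, int side, Rcpp::List arch,
                        Rcpp::List W, Rcpp::List b) {
  std::vector<Layer> ls = build_layers(arch);
  set_params(ls, W, b);
  setup(ls, side);
  const fmat fdata = conv_to<fmat>::from(data);
  const int n = fdata.n_cols;
  const double npix = (double)side * side;
  double loss = 0.0;
  fcube diff(side, side, 1);
  for (int s = 0; s < n; ++s) {
    fcube x(const_cast<float*>(fdata.colptr(s)), side, side, 1, false, true);
    const fcube& y = forward(ls, x);
    diff = y - x;
    loss += accu(square(diff)) / npix;
    diff *= (float)(2.0 / (npix * n));
    backward(ls, x, diff);
  }
  Rcpp::List gW, gb;
  for (const auto& l : ls)
    if (l.kind == CONV) {
      gW.push_back(Rcpp::wrap(conv_to<mat>::from(l.gW)));
      gb.push_back(Rcpp::wrap(conv_to<vec>::from(l.gb)));
    }
  return Rcpp::List::create(Rcpp::Named("gW") = gW, Rcpp::Named("gb") = gb,
                            Rcpp::Named("loss") = loss / n);
}

// Forward pass with fixed parameters. Returns latent vectors
// (n x latent_dim; latent cube vectorised column-major: rows, cols,
// channels) and optionally reconstructed images ((side*side) x n).
// [[Rcpp::export(name = ".cae_forward")]]
Rcpp::List cae_forward(const arma::mat& data, int side, Rcpp::List arch,
                       Rcpp::List W, Rcpp::List b, bool latent_only) {
  std::vector<Layer> ls = build_layers(arch);
  set_params(ls, W, b);
  setup(ls, side);
  const int latent_at = 2 * Rcpp::IntegerVector(arch["enc_filters"]).size();
  const fmat fdata = conv_to<fmat>::from(data);
  const int n = fdata.n_cols;
  mat latents, recon;
  for (int s = 0; s < n; ++s) {
    fcube x(const_cast<float*>(fdata.colptr(s)), side, side, 1, false, true);
    const fcube& y = forward(ls, x);
    const fcube& lat = ls[latent_at - 1].out;
    if (s == 0) {
      latents.set_size(n, lat.n_elem);
      if (!latent_only) recon.set_size(fdata.n_rows, n);
    }
    latents.row(s) = conv_to<rowvec>::from(vectorise(lat).t());
    if (!latent_only) recon.col(s) = conv_to<vec>::from(vectorise(y));
  }
  return Rcpp::List::create(Rcpp::Named("latent") = latents,
                            Rcpp::Named("recon") = recon);
}
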