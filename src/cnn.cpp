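// Native convolutional map-to-map network: same-padded k x k convolutions,
// ReLU hidden layers, additive skip connections between equal-width layers,
// inverted dropout, MSE loss, Adam with L2 regularization.
//
// Layout: an activation is a (H*W x channels) matrix whose columns are
// channel images (column-major over pixels p = h + H*w).  A convolution is
// an im2col GEMM: patches (np x k*k*cin) times the transposed weight matrix
// (cout x k*k*cin), tiled over image columns so memory stays bounded for
// large grids.  All randomness (dropout masks, shuffling) comes from a
// std::mt19937_64 seeded explicitly, so runs are reproducible.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Layer {
  mat Wt;     // (k*k*cin) x cout  (transposed weights for the GEMM)
  rowvec b;   // cout
  int k, cin, cout;
  int skip_from;  // 0-based earlier layer whose output adds to this
                  // pre-activation; -1 for none
};

static std::vector<Layer> unpack_layers(const Rcpp::List& weights,
                                        const Rcpp::IntegerVector& kernels,
                                        const Rcpp::IntegerVector& skips) {
  std::vector<Layer> out;
  for (int l = 0; l < weights.size(); ++l) {
    Rcpp::List wl = weights[l];
    Layer L;
    mat W = Rcpp::as<mat>(wl["W"]);  // cout x (k*k*cin)
    L.Wt = W.t();
    L.b = Rcpp::as<rowvec>(wl["b"]);
    L.k = kernels[l];
    L.cout = (int)W.n_rows;
    L.cin = (int)(W.n_cols / (L.k * L.k));
    L.skip_from = skips[l];
    out.push_back(L);
  }
  return out;
}

// patches for image columns [w0, w1): A is (H*(w1-w0)) x (k*k*cin),
// patch entry r = (c*k + dw)*k + dh
static void im2col_tile(const mat& x, int H, int W, int C, int k, int w0,
                        int w1, mat& A) {
  const int pad = k / 2, nw = w1 - w0;
  A.zeros((uword)(H * nw), (uword)(k * k * C));
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = (c * k + dw) * k + dh;
        double* dst0 = A.colptr(r);
        const int h0 = dh - pad, woff = dw - pad;
        const int hlo = std::max(0, -h0), hhi = std::min(H, H - h0);
        if (hhi <= hlo) continue;
        for (int w = w0; w < w1; ++w) {
          const int ws = w + woff;
          if (ws < 0 || ws >= W) continue;
          std::memcpy(dst0 + (size_t)(w - w0) * H + hlo,
                      xc + (size_t)ws * H + hlo + h0,
                      sizeof(double) * (size_t)(hhi - hlo));
        }
      }
    }
  }
}

// adjoint: scatter dA (tile patches gradient) back onto dx (H*W x C)
static void col2im_tile(const mat& dA, int H, int W, int C, int k, int w0,
                        int w1, mat& dx) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx.colptr(c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = (c * k + dw) * k + dh;
        const double* src0 = dA.colptr(r);
        const int h0 = dh - pad, woff = dw - pad;
        const int hlo = std::max(0, -h0), hhi = std::min(H, H - h0);
        if (hhi <= hlo) continue;
        for (int w = w0; w < w1; ++w) {
          const int ws = w + woff;
          if (ws < 0 || ws >= W) continue;
          const double* s = src0 + (size_t)(w - w0) * H + hlo;
          double* d = xc + (size_t)ws * H + hlo + h0;
          for (int h = 0; h < hhi - hlo; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// image columns per tile: bounded scratch (~32 MB at 512-pixel height)
static int tile_cols(int H, int k, int cin) {
  double budget = 4.0e6;  // doubles
  int nw = (int)(budget / ((double)H * k * k * cin));
  return std::max(1, nw);
}

// z = conv(x) + b, tiled
static void conv_forward(const mat& x, int H, int W, const Layer& ly,
                         mat& z) {
  z.set_size((uword)H * W, ly.cout);
  const int tw = tile_cols(H, ly.k, ly.cin);
  mat A;
  for (int w0 = 0; w0 < W; w0 += tw) {
    const int w1 = std::min(W, w0 + tw);
    im2col_tile(x, H, W, ly.cin, ly.k, w0, w1, A);
    z.rows((uword)H * w0, (uword)H * w1 - 1) = A * ly.Wt;
  }
  z.each_row() += ly.b;
}

// gradients: dWt += sum_tiles A^T dz_tile ; db += colsum dz ; dx = scatter
static void conv_backward(const mat& x, const mat& dz, int H, int W,
                          const Layer& ly, mat& dWt, rowvec& db, mat& dx,
                          bool want_dx) {
  const int tw = tile_cols(H, ly.k, ly.cin);
  if (want_dx) dx.zeros((uword)H * W, ly.cin);
  mat A, dA;
  for (int w0 = 0; w0 < W; w0 += tw) {
    const int w1 = std::min(W, w0 + tw);
    im2col_tile(x, H, W, ly.cin, ly.k, w0, w1, A);
    const mat dzt = dz.rows((uword)H * w0, (uword)H * w1 - 1);
    dWt += A.t() * dzt;
    if (want_dx) {
      dA = dzt * ly.Wt.t();
      col2im_tile(dA, H, W, ly.cin, ly.k, w0, w1, dx);
    }
  }
  db += sum(dz, 0);
}

struct ForwardCache {
  std::vector<mat> act;       // act[0] = input, act[l+1] = output of layer l
  std::vector<mat> preact;    // pre-activation of each layer
  std::vector<mat> dropmask;  // inverted-dropout mask on act[l+1]
};

static std::vector<bool> dropout_flags(int L) {
  // dropout after every hidden layer except the last hidden layer; never
  // after the output layer
  std::vector<bool> f((size_t)L, false);
  for (int l = 0; l < L - 2; ++l) f[l] = true;
  return f;
}

static mat forward_pass(const mat& x, int H, int W,
                        const std::vector<Layer>& layers, double drop_rate,
                        const std::vector<bool>& dropout_layers,
                        bool stochastic, std::mt19937_64& rng,
                        ForwardCache* cache) {
  const int L = (int)layers.size();
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat a = x;
  if (cache) {
    cache->act.assign(1, x);
    cache->preact.clear();
    cache->dropmask.assign((size_t)L, mat());
  }
  mat z;
  std::vector<mat> kept;  // post-activation outputs, for skips
  kept.reserve((size_t)L + 1);
  kept.push_back(x);
  for (int l = 0; l < L; ++l) {
    const Layer& ly = layers[l];
    conv_forward(a, H, W, ly, z);
    if (ly.skip_from >= 0) z += kept[(size_t)ly.skip_from + 1];
    if (cache) cache->preact.push_back(z);
    mat anew = (l < L - 1) ? clamp(z, 0.0, datum::inf) : z;
    if (stochastic && drop_rate > 0 && dropout_layers[l]) {
      mat m(anew.n_rows, anew.n_cols);
      const double inv = 1.0 / (1.0 - drop_rate);
      for (uword i = 0; i < m.n_elem; ++i) {
        m(i) = unif(rng) < drop_rate ? 0.0 : inv;
      }
      anew %= m;
      if (cache) cache->dropmask[l] = m;
    }
    kept.push_back(anew);
    if (cache) cache->act.push_back(anew);
    a = std::move(anew);
  }
  return a;
}

struct Grads {
  std::vector<mat> dWt;
  std::vector<rowvec> db;
};

// accumulates gradients into g; returns this example's MSE
static double backward_pass(const mat& target, int H, int W,
                            const std::vector<Layer>& layers,
                            const ForwardCache& cache, double drop_rate,
                            const std::vector<bool>& dropout_layers,
                            Grads& g) {
  const int L = (int)layers.size();
  const double npix = (double)target.n_elem;
  mat err = cache.act[L] - target;
  double mse = accu(square(err)) / npix;
  mat da = (2.0 / npix) * err;
  std::vector<mat> skip_accum((size_t)L + 1);
  for (int l = L - 1; l >= 0; --l) {
    const Layer& ly = layers[l];
    mat da_l = da;
    if (skip_accum[(size_t)l + 1].n_elem) da_l += skip_accum[(size_t)l + 1];
    if (drop_rate > 0 && dropout_layers[l] && cache.dropmask[l].n_elem) {
      da_l %= cache.dropmask[l];
    }
    mat dz = std::move(da_l);
    if (l < L - 1) {
      const mat& zpre = cache.preact[l];
      for (uword i = 0; i < dz.n_elem; ++i) if (zpre(i) <= 0) dz(i) = 0;
    }
    // the pre-activation skip addition passes gradient through unchanged
    if (ly.skip_from >= 0) {
      size_t s = (size_t)ly.skip_from + 1;
      if (skip_accum[s].n_elem) skip_accum[s] += dz;
      else skip_accum[s] = dz;
    }
    mat dx;
    conv_backward(cache.act[l], dz, H, W, ly, g.dWt[l], g.db[l], dx, l > 0);
    if (l > 0) da = std::move(dx);
  }
  return mse;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const Rcpp::NumericVector& inputs,
                         const Rcpp::NumericVector& targets,
                         Rcpp::List weights,
                         const Rcpp::IntegerVector& kernels,
                         const Rcpp::IntegerVector& skips, double drop_rate,
                         double l2, double lr, int epochs, int batch_size,
                         int seed, Rcpp::List adam_state) {
  Rcpp::IntegerVector din = inputs.attr("dim");   // H, W, Cin, N
  const int H = din[0], W = din[1], Cin = din[2], N = din[3];
  std::vector<Layer> layers = unpack_layers(weights, kernels, skips);
  const int L = (int)layers.size();
  std::vector<bool> dflags = dropout_flags(L);
  std::mt19937_64 rng((uint64_t)seed);

  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  int tstep = 0;
  if (adam_state.size()) {
    Rcpp::List ms = adam_state["m"], vs = adam_state["v"];
    tstep = Rcpp::as<int>(adam_state["t"]);
    for (int l = 0; l < L; ++l) {
      Rcpp::List ml = ms[l], vl = vs[l];
      mW[l] = Rcpp::as<mat>(ml["W"]);
      mb[l] = Rcpp::as<rowvec>(ml["b"]);
      vW[l] = Rcpp::as<mat>(vl["W"]);
      vb[l] = Rcpp::as<rowvec>(vl["b"]);
    }
  } else {
    for (int l = 0; l < L; ++l) {
      mW[l].zeros(size(layers[l].Wt)); vW[l].zeros(size(layers[l].Wt));
      mb[l].zeros(layers[l].b.n_elem); vb[l].zeros(layers[l].b.n_elem);
    }
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  const double* ip = inputs.begin();
  const double* tp = targets.begin();
  const size_t in_stride = (size_t)H * W * Cin;
  const size_t tg_stride = (size_t)H * W;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> loss_hist;

  Grads g;
  g.dWt.resize(L); g.db.resize(L);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < N; start += batch_size) {
      int nb = std::min(batch_size, N - start);
      for (int l = 0; l < L; ++l) {
        g.dWt[l].zeros(size(layers[l].Wt));
        g.db[l].zeros(layers[l].b.n_elem);
      }
      double batch_loss = 0.0;
      for (int j = 0; j < nb; ++j) {
        int idx = order[(size_t)start + j];
        mat x(const_cast<double*>(ip + (size_t)idx * in_stride),
              (uword)H * W, Cin, false, true);
        mat y(const_cast<double*>(tp + (size_t)idx * tg_stride),
              (uword)H * W, 1, false, true);
        ForwardCache cache;
        forward_pass(x, H, W, layers, drop_rate, dflags, true, rng, &cache);
        batch_loss += backward_pass(y, H, W, layers, cache, drop_rate,
                                    dflags, g);
      }
      batch_loss /= nb;
      loss_hist.push_back(batch_loss);
      if (!std::isfinite(batch_loss)) {
        Rcpp::stop("NaN/Inf loss at epoch %d, batch starting %d", ep + 1,
                   start);
      }
      ++tstep;
      const double corr =
          std::sqrt(1.0 - std::pow(b2, tstep)) / (1.0 - std::pow(b1, tstep));
      for (int l = 0; l < L; ++l) {
        mat gW = g.dWt[l] / nb + 2.0 * l2 * layers[l].Wt;
        rowvec gb = g.db[l] / nb;
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * square(gW);
        layers[l].Wt -= lr * corr * mW[l] / (sqrt(vW[l]) + eps);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * square(gb);
        layers[l].b -= lr * corr * mb[l] / (sqrt(vb[l]) + eps);
      }
      Rcpp::checkUserInterrupt();
    }
  }

  Rcpp::List wout(L), mout(L), vout(L);
  for (int l = 0; l < L; ++l) {
    wout[l] = Rcpp::List::create(Rcpp::Named("W") = mat(layers[l].Wt.t()),
                                 Rcpp::Named("b") = vec(layers[l].b.t()));
    mout[l] = Rcpp::List::create(Rcpp::Named("W") = mW[l],
                                 Rcpp::Named("b") = mb[l]);
    vout[l] = Rcpp::List::create(Rcpp::Named("W") = vW[l],
                                 Rcpp::Named("b") = vb[l]);
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = wout,
      Rcpp::Named("loss") = loss_hist,
      Rcpp::Named("adam") = Rcpp::List::create(
          Rcpp::Named("m") = mout, Rcpp::Named("v") = vout,
          Rcpp::Named("t") = tstep));
}

// Forward passes (optionally stochastic, for MC dropout).
// Returns an H x W x n_passes cube.
// [[Rcpp::export]]
arma::cube cnn_predict_cpp(const arma::cube& input, Rcpp::List weights,
                           const Rcpp::IntegerVector& kernels,
                           const Rcpp::IntegerVector& skips,
                           double drop_rate, int n_passes, bool stochastic,
                           int seed) {
  const int H = (int)input.n_rows, W = (int)input.n_cols,
            C = (int)input.n_slices;
  std::vector<Layer> layers = unpack_layers(weights, kernels, skips);
  std::vector<bool> dflags = dropout_flags((int)layers.size());
  std::mt19937_64 rng((uint64_t)seed);
  mat x(const_cast<double*>(input.memptr()), (uword)H * W, C, false, true);
  cube out((uword)H, (uword)W, (uword)n_passes);
  for (int p = 0; p < n_passes; ++p) {
    mat y = forward_pass(x, H, W, layers, drop_rate, dflags, stochastic,
                         rng, nullptr);
    std::memcpy(out.slice(p).memptr(), y.colptr(0),
                sizeof(double) * (size_t)H * W);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Per-example MSE of deterministic forward passes over a set.
// [[Rcpp::export]]
Rcpp::NumericVector cnn_mse_cpp(const Rcpp::NumericVector& inputs,
                                const Rcpp::NumericVector& targets,
                                Rcpp::List weights,
                                const Rcpp::IntegerVector& kernels,
                                const Rcpp::IntegerVector& skips) {
  Rcpp::IntegerVector din = inputs.attr("dim");
  const int H = din[0], W = din[1], Cin = din[2], N = din[3];
  std::vector<Layer> layers = unpack_layers(weights, kernels, skips);
  std::vector<bool> dflags = dropout_flags((int)layers.size());
  std::mt19937_64 rng(0);
  const double* ip = inputs.begin();
  const double* tp = targets.begin();
  const size_t in_stride = (size_t)H * W * Cin;
  const size_t tg_stride = (size_t)H * W;
  Rcpp::NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    mat x(const_cast<double*>(ip + (size_t)i * in_stride), (uword)H * W,
          Cin, false, true);
    mat y = forward_pass(x, H, W, layers, 0.0, dflags, false, rng, nullptr);
    mat t(const_cast<double*>(tp + (size_t)i * tg_stride), (uword)H * W, 1,
          false, true);
    out[i] = accu(square(y - t)) / (double)t.n_elem;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
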