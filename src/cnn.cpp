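// Native VGG-style convolutional classifier for GAF images.
//
// Layer sequence (fixed shape, configurable widths):
//   stem:  conv-conv-pool repeated twice (filters s1 then s2)
//   core:  L x conv (3x3, ReLU, coreFilters)
//   max-pool -> global average pool -> dropout -> dense(ReLU)
//   -> dropout -> dense(softmax)
// Training: softmax cross-entropy, Adam with a deterministic step decay
// (rate halves every 50 epochs), early stopping on validation loss with
// best-weight restore. A whole minibatch moves through each layer as one
// im2col + GEMM in single precision — standard for network training and
// ~2x the throughput of doubles on one CPU; weights cross the R boundary
// as doubles. All randomness (init, shuffling, dropout, augmentation)
// comes from one mt19937_64 stream, so runs are reproducible
// bit-for-bit on one device per seed.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Config {
  int inputSize = 64;
  int channels = 1;
  int stem1 = 8, stem2 = 16;
  int coreLayers = 5, coreFilters = 32;
  int hidden = 64;
  int numClasses = 2;
  double dropCore = 0.25, dropHead = 0.10;
  double lr = 1e-3;
  int batch = 32;
  int maxEpochs = 40;
  int patience = 6;
  bool augmentShift = false;

  int nConv = 9;
  std::vector<int> inC, outC, dimIn;  // per conv layer
  std::vector<bool> poolAfter;
  int finalDim = 8;  // spatial size after the last pool

  void build() {
    nConv = 4 + coreLayers;
    inC.assign(nConv, 0); outC.assign(nConv, 0);
    dimIn.assign(nConv, 0); poolAfter.assign(nConv, false);
    inC[0] = channels;       outC[0] = stem1;
    inC[1] = stem1;          outC[1] = stem1;   poolAfter[1] = true;
    inC[2] = stem1;          outC[2] = stem2;
    inC[3] = stem2;          outC[3] = stem2;   poolAfter[3] = true;
    for (int l = 4; l < nConv; ++l) {
      inC[l] = (l == 4) ? stem2 : coreFilters;
      outC[l] = coreFilters;
    }
    poolAfter[nConv - 1] = true;
    int d = inputSize;
    for (int l = 0; l < nConv; ++l) {
      dimIn[l] = d;
      if (poolAfter[l]) d /= 2;
    }
    finalDim = d;
  }
};

Config parseConfig(const Rcpp::List& cfg) {
  Config c;
  c.inputSize   = Rcpp::as<int>(cfg["inputSize"]);
  c.channels    = Rcpp::as<int>(cfg["channels"]);
  Rcpp::IntegerVector stem = cfg["stemFilters"];
  c.stem1 = stem[0]; c.stem2 = stem[1];
  c.coreLayers  = Rcpp::as<int>(cfg["coreConvLayers"]);
  c.coreFilters = Rcpp::as<int>(cfg["coreFilters"]);
  c.hidden      = Rcpp::as<int>(cfg["hiddenUnits"]);
  c.numClasses  = Rcpp::as<int>(cfg["numClasses"]);
  c.dropCore    = Rcpp::as<double>(cfg["dropoutCore"]);
  c.dropHead    = Rcpp::as<double>(cfg["dropoutHead"]);
  c.lr          = Rcpp::as<double>(cfg["learningRate"]);
  c.batch       = Rcpp::as<int>(cfg["batchSize"]);
  c.maxEpochs   = Rcpp::as<int>(cfg["maxEpochs"]);
  c.patience    = Rcpp::as<int>(cfg["patience"]);
  c.augmentShift = Rcpp::as<bool>(cfg["augmentShift"]);
  if (c.inputSize < 16 || c.inputSize % 8 != 0)
    Rcpp::stop("inputSize must be a multiple of 8 and at least 16 for the pooling cascade");
  c.build();
  return c;
}

struct Params {
  std::vector<fmat> Wc;
  std::vector<fvec> bc;
  fmat W1, W2;
  fvec b1, b2;
};

Params paramsFromList(const Rcpp::List& w, const Config& cfg) {
  Params p;
  Rcpp::List Wc = w["Wc"], bc = w["bc"];
  if (static_cast<int>(Wc.size()) != cfg.nConv)
    Rcpp::stop("weight list does not match the configured architecture");
  for (int l = 0; l < cfg.nConv; ++l) {
    p.Wc.push_back(conv_to<fmat>::from(Rcpp::as<mat>(Wc[l])));
    p.bc.push_back(conv_to<fvec>::from(Rcpp::as<vec>(bc[l])));
  }
  p.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
  p.b1 = conv_to<fvec>::from(Rcpp::as<vec>(w["b1"]));
  p.W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["W2"]));
  p.b2 = conv_to<fvec>::from(Rcpp::as<vec>(w["b2"]));
  return p;
}

Rcpp::List paramsToList(const Params& p) {
  Rcpp::List Wc(p.Wc.size()), bc(p.bc.size());
  for (size_t l = 0; l < p.Wc.size(); ++l) {
    Wc[l] = conv_to<mat>::from(p.Wc[l]);
    bc[l] = conv_to<vec>::from(p.bc[l]);
  }
  return Rcpp::List::create(
      Rcpp::Named("Wc") = Wc, Rcpp::Named("bc") = bc,
      Rcpp::Named("W1") = conv_to<mat>::from(p.W1),
      Rcpp::Named("b1") = conv_to<vec>::from(p.b1),
      Rcpp::Named("W2") = conv_to<mat>::from(p.W2),
      Rcpp::Named("b2") = conv_to<vec>::from(p.b2));
}

// Batch layout: a stage with C channels and B samples is an fcube with
// C*B slices, sample-major (sample k occupies slices [k*C, (k+1)*C)).
// Patch matrices are stored transposed — (HW*B) x (9C), row = pixel
// k*H*W + (i + j*H), column = c*9 + (dj+1)*3 + (di+1) — so every hot
// loop below reads and writes contiguous memory.
void im2colBatch(const fcube& X, int C, int B, fmat& cols) {
  const int H = X.n_rows, W = X.n_cols, HW = H * W;
  cols.set_size(static_cast<uword>(HW) * B, 9 * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        float* col = cols.colptr(c * 9 + (dj + 1) * 3 + (di + 1));
        for (int k = 0; k < B; ++k) {
          const fmat& S = X.slice(k * C + c);
          float* dst = col + static_cast<uword>(k) * HW;
          for (int j = 0; j < W; ++j, dst += H) {
            const int js = j + dj;
            if (js < 0 || js >= W) {
              std::fill(dst, dst + H, 0.0f);
              continue;
            }
            const float* src = S.colptr(js) + di;
            if (di < 0) {
              dst[0] = 0.0f;
              std::copy(src + 1, src + H, dst + 1);
            } else if (di > 0) {
              std::copy(src, src + H - 1, dst);
              dst[H - 1] = 0.0f;
            } else {
              std::copy(src, src + H, dst);
            }
          }
        }
      }
    }
  }
}

void col2imBatch(const fmat& cols, int C, int B, fcube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, HW = H * W;
  dX.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const float* col = cols.colptr(c * 9 + (dj + 1) * 3 + (di + 1));
        for (int k = 0; k < B; ++k) {
          fmat& S = dX.slice(k * C + c);
          const float* src = col + static_cast<uword>(k) * HW;
          for (int j = 0; j < W; ++j, src += H) {
            const int js = j + dj;
            if (js < 0 || js >= W) continue;
            float* dst = S.colptr(js) + di;
            const int lo = (di < 0) ? 1 : 0;
            const int hi = (di > 0) ? H - 1 : H;
            for (int i = lo; i < hi; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
}

// conv output ((HW*B) x F, filters in columns) -> batch cube (F channels)
fcube colsToCube(const fmat& out, int d, int F, int B) {
  const int HW = d * d;
  fcube X(d, d, static_cast<uword>(F) * B);
  for (int k = 0; k < B; ++k)
    for (int f = 0; f < F; ++f)
      std::copy(out.colptr(f) + static_cast<uword>(k) * HW,
                out.colptr(f) + static_cast<uword>(k) * HW + HW,
                X.slice_memptr(k * F + f));
  return X;
}

fmat cubeToCols(const fcube& X, int F, int B) {
  const int HW = X.n_rows * X.n_cols;
  fmat out(static_cast<uword>(HW) * B, F);
  for (int k = 0; k < B; ++k)
    for (int f = 0; f < F; ++f)
      std::copy(X.slice_memptr(k * F + f), X.slice_memptr(k * F + f) + HW,
                out.colptr(f) + static_cast<uword>(k) * HW);
  return out;
}

fcube maxpool2(const fcube& X, Cube<uword>& argmax) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  const int HX = X.n_rows;
  fcube Y(H, W, C);
  argmax.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const float* S = X.slice_memptr(c);
    float* y = Y.slice_memptr(c);
    uword* a = argmax.slice_memptr(c);
    for (int j = 0; j < W; ++j) {
      const float* c0 = S + (2 * j) * HX;
      const float* c1 = S + (2 * j + 1) * HX;
      for (int i = 0; i < H; ++i) {
        const int i0 = 2 * i;
        float best = c0[i0];
        uword arg = i0 + (2 * j) * HX;
        if (c0[i0 + 1] > best) { best = c0[i0 + 1]; arg = i0 + 1 + (2 * j) * HX; }
        if (c1[i0] > best) { best = c1[i0]; arg = i0 + (2 * j + 1) * HX; }
        if (c1[i0 + 1] > best) { best = c1[i0 + 1]; arg = i0 + 1 + (2 * j + 1) * HX; }
        y[i + j * H] = best;
        a[i + j * H] = arg;
      }
    }
  }
  return Y;
}

fcube unpool2(const fcube& dY, const Cube<uword>& argmax, int H, int W) {
  const int C = dY.n_slices, Hp = dY.n_rows, Wp = dY.n_cols;
  fcube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* S = dX.slice_memptr(c);
    const float* d = dY.slice_memptr(c);
    const uword* a = argmax.slice_memptr(c);
    const int n = Hp * Wp;
    for (int e = 0; e < n; ++e) S[a[e]] += d[e];
  }
  return dX;
}

struct Cache {
  std::vector<fmat> cols;   // per conv layer: batch patches ((HW*B) x 9C)
  std::vector<fmat> post;   // per conv layer: post-ReLU output ((HW*B) x F)
  std::vector<Cube<uword>> poolArg;
  fmat gap, gapDropped, coreMask, hpre, hDropped, headMask, probs;  // cols = samples

  // buffers persist across batches; set_size() is a no-op when the batch
  // shape repeats, so steady-state training does no per-batch allocation
  void init(int nConv, int nPool) {
    if (cols.empty()) {
      cols.resize(nConv);
      post.resize(nConv);
      poolArg.resize(nPool);
    }
  }
};

// forward pass for one minibatch of B samples; fills the cache
void forwardBatch(const Params& P, const Config& cfg, const fcube& X, int B,
                  bool train, std::mt19937_64& rng, Cache& cc) {
  cc.init(cfg.nConv, 3);
  fcube cur = X;
  int pc = 0;
  for (int l = 0; l < cfg.nConv; ++l) {
    im2colBatch(cur, cfg.inC[l], B, cc.cols[l]);
    fmat& out = cc.post[l];
    out = cc.cols[l] * P.Wc[l].t();
    for (int f = 0; f < cfg.outC[l]; ++f) out.col(f) += P.bc[l](f);
    out.for_each([](float& v) { if (v < 0) v = 0; });
    fcube nxt = colsToCube(out, cfg.dimIn[l], cfg.outC[l], B);
    if (cfg.poolAfter[l]) {
      cur = maxpool2(nxt, cc.poolArg[pc]);
      ++pc;
    } else {
      cur = nxt;
    }
  }
  const int F = cfg.coreFilters, hw = cur.n_rows * cur.n_cols;
  cc.gap.set_size(F, B);
  for (int k = 0; k < B; ++k)
    for (int f = 0; f < F; ++f)
      cc.gap(f, k) = accu(cur.slice(k * F + f)) / hw;

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  cc.coreMask.ones(F, B);
  if (train && cfg.dropCore > 0)
    cc.coreMask.for_each([&](float& v) {
      v = (unif(rng) < 1.0 - cfg.dropCore)
              ? static_cast<float>(1.0 / (1.0 - cfg.dropCore)) : 0.0f;
    });
  cc.gapDropped = cc.gap % cc.coreMask;
  cc.hpre = P.W1 * cc.gapDropped;
  cc.hpre.each_col() += P.b1;
  fmat h = cc.hpre;
  h.for_each([](float& v) { if (v < 0) v = 0; });
  cc.headMask.ones(cfg.hidden, B);
  if (train && cfg.dropHead > 0)
    cc.headMask.for_each([&](float& v) {
      v = (unif(rng) < 1.0 - cfg.dropHead)
              ? static_cast<float>(1.0 / (1.0 - cfg.dropHead)) : 0.0f;
    });
  cc.hDropped = h % cc.headMask;
  fmat o = P.W2 * cc.hDropped;
  o.each_col() += P.b2;
  o.each_row() -= max(o, 0);
  fmat e = exp(o);
  cc.probs = e;
  cc.probs.each_row() /= sum(e, 0);
}

double batchLoss(const Cache& cc, const ivec& y, const uvec& idx, int* correct) {
  double loss = 0;
  for (uword k = 0; k < idx.n_elem; ++k) {
    const int yk = y(idx(k));
    loss += -std::log(std::max(static_cast<double>(cc.probs(yk, k)), 1e-30));
    if (correct && cc.probs.col(k).index_max() == static_cast<uword>(yk))
      ++(*correct);
  }
  return loss;
}

// gradient of the summed (not averaged) batch loss, accumulated into G
void backwardBatch(const Params& P, const Config& cfg, const Cache& cc,
                   const ivec& y, const uvec& idx, Params& G) {
  const int B = idx.n_elem;
  fmat dout2 = cc.probs;
  for (int k = 0; k < B; ++k) dout2(y(idx(k)), k) -= 1.0f;
  G.W2 += dout2 * cc.hDropped.t();
  G.b2 += sum(dout2, 1);
  fmat dh = (P.W2.t() * dout2) % cc.headMask;
  dh.elem(find(cc.hpre <= 0)).zeros();
  G.W1 += dh * cc.gapDropped.t();
  G.b1 += sum(dh, 1);
  fmat dg = (P.W1.t() * dh) % cc.coreMask;

  const int fd = cfg.finalDim, F = cfg.coreFilters;
  fcube dcur(fd, fd, static_cast<uword>(F) * B);
  for (int k = 0; k < B; ++k)
    for (int f = 0; f < F; ++f)
      dcur.slice(k * F + f).fill(dg(f, k) / (fd * fd));

  int pc = static_cast<int>(cc.poolArg.size()) - 1;
  for (int l = cfg.nConv - 1; l >= 0; --l) {
    const int d = cfg.dimIn[l];
    if (cfg.poolAfter[l]) {
      dcur = unpool2(dcur, cc.poolArg[pc], d, d);
      --pc;
    }
    fmat doutm = cubeToCols(dcur, cfg.outC[l], B);
    {
      // ReLU gate: units that output 0 pass no gradient
      const float* post = cc.post[l].memptr();
      float* dm = doutm.memptr();
      const uword n = doutm.n_elem;
      for (uword e = 0; e < n; ++e) if (post[e] == 0) dm[e] = 0;
    }
    G.Wc[l] += (cc.cols[l].t() * doutm).t();
    G.bc[l] += sum(doutm, 0).t();
    if (l > 0) {
      fmat dcols = doutm * P.Wc[l];
      fcube dprev(d, d, static_cast<uword>(cfg.inC[l]) * B);
      col2imBatch(dcols, cfg.inC[l], B, dprev);
      dcur = dprev;
    }
  }
}

struct Adam {
  std::vector<fmat> mWc, vWc;
  std::vector<fvec> mbc, vbc;
  fmat mW1, vW1, mW2, vW2;
  fvec mb1, vb1, mb2, vb2;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;

  explicit Adam(const Params& p) {
    for (const auto& w : p.Wc) { mWc.push_back(zeros<fmat>(size(w)));
                                 vWc.push_back(zeros<fmat>(size(w))); }
    for (const auto& b : p.bc) { mbc.push_back(zeros<fvec>(size(b)));
                                 vbc.push_back(zeros<fvec>(size(b))); }
    mW1 = zeros<fmat>(size(p.W1)); vW1 = mW1;
    mW2 = zeros<fmat>(size(p.W2)); vW2 = mW2;
    mb1 = zeros<fvec>(size(p.b1)); vb1 = mb1;
    mb2 = zeros<fvec>(size(p.b2)); vb2 = mb2;
  }

  template <class T>
  void upd(T& w, const T& g, T& m, T& v, float lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const float c1 = 1 - std::pow(b1, static_cast<float>(t));
    const float c2 = 1 - std::pow(b2, static_cast<float>(t));
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }

  void step(Params& p, const Params& g, float lr) {
    ++t;
    for (size_t l = 0; l < p.Wc.size(); ++l) {
      upd(p.Wc[l], g.Wc[l], mWc[l], vWc[l], lr);
      upd(p.bc[l], g.bc[l], mbc[l], vbc[l], lr);
    }
    upd(p.W1, g.W1, mW1, vW1, lr);
    upd(p.b1, g.b1, mb1, vb1, lr);
    upd(p.W2, g.W2, mW2, vW2, lr);
    upd(p.b2, g.b2, mb2, vb2, lr);
  }
};

Params zeroLike(const Params& p) {
  Params g;
  for (const auto& w : p.Wc) g.Wc.push_back(zeros<fmat>(size(w)));
  for (const auto& b : p.bc) g.bc.push_back(zeros<fvec>(size(b)));
  g.W1 = zeros<fmat>(size(p.W1)); g.b1 = zeros<fvec>(size(p.b1));
  g.W2 = zeros<fmat>(size(p.W2)); g.b2 = zeros<fvec>(size(p.b2));
  return g;
}

// re-zero an existing gradient accumulator without reallocating
void zeroInto(Params& g, const Params& p) {
  if (g.Wc.empty()) { g = zeroLike(p); return; }
  for (auto& w : g.Wc) w.zeros();
  for (auto& b : g.bc) b.zeros();
  g.W1.zeros(); g.b1.zeros(); g.W2.zeros(); g.b2.zeros();
}

void scaleParams(Params& g, float s) {
  for (auto& w : g.Wc) w *= s;
  for (auto& b : g.bc) b *= s;
  g.W1 *= s; g.b1 *= s; g.W2 *= s; g.b2 *= s;
}

// gather samples idx (C slices each) from the full stack into one batch cube
fcube gatherBatch(const fcube& X, const uvec& idx, int C, int H) {
  fcube out(H, H, static_cast<uword>(C) * idx.n_elem);
  for (uword k = 0; k < idx.n_elem; ++k)
    for (int c = 0; c < C; ++c)
      out.slice(k * C + c) = X.slice(idx(k) * C + c);
  return out;
}

// circular-shift augmentation: shifting the encoded time window by s
// samples permutes the GASF's rows and columns by the same rotation
// (G_ij depends only on the pair of series values), so the augmented
// image is exactly the image of the wrapped window
fcube gatherBatchShifted(const fcube& X, const uvec& idx, int C, int H,
                         std::mt19937_64& rng) {
  fcube out(H, H, static_cast<uword>(C) * idx.n_elem);
  std::uniform_int_distribution<int> shiftDist(0, H - 1);
  for (uword k = 0; k < idx.n_elem; ++k) {
    const int s = shiftDist(rng);
    for (int c = 0; c < C; ++c) {
      const fmat& S = X.slice(idx(k) * C + c);
      fmat& D = out.slice(k * C + c);
      for (int j = 0; j < H; ++j) {
        const float* src = S.colptr((j + s) % H);
        float* dst = D.colptr(j);
        // dst[i] = src[(i + s) % H]: two contiguous segments
        std::copy(src + s, src + H, dst);
        std::copy(src, src + s, dst + (H - s));
      }
    }
  }
  return out;
}

fcube toFloatCube(const cube& X) {
  fcube out(X.n_rows, X.n_cols, X.n_slices);
  const double* src = X.memptr();
  float* dst = out.memptr();
  for (uword e = 0; e < X.n_elem; ++e) dst[e] = static_cast<float>(src[e]);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cnnInit")]]
Rcpp::List cnnInit(Rcpp::List config, int seed) {
  Config cfg = parseConfig(config);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  Params p;
  for (int l = 0; l < cfg.nConv; ++l) {
    const int fanIn = 9 * cfg.inC[l];
    const float sd = std::sqrt(2.0f / fanIn);
    fmat W(cfg.outC[l], fanIn);
    for (uword k = 0; k < W.n_elem; ++k)
      W(k) = sd * static_cast<float>(norm(rng));
    p.Wc.push_back(W);
    p.bc.push_back(zeros<fvec>(cfg.outC[l]));
  }
  {
    const float sd = std::sqrt(2.0f / cfg.coreFilters);
    p.W1.set_size(cfg.hidden, cfg.coreFilters);
    for (uword k = 0; k < p.W1.n_elem; ++k)
      p.W1(k) = sd * static_cast<float>(norm(rng));
    p.b1 = zeros<fvec>(cfg.hidden);
  }
  {
    const float sd = std::sqrt(2.0f / cfg.hidden);
    p.W2.set_size(cfg.numClasses, cfg.hidden);
    for (uword k = 0; k < p.W2.n_elem; ++k)
      p.W2(k) = sd * static_cast<float>(norm(rng));
    p.b2 = zeros<fvec>(cfg.numClasses);
  }
  return paramsToList(p);
}

// [[Rcpp::export(name = ".cnnTrain")]]
Rcpp::List cnnTrain(Rcpp::List weights, Rcpp::List config,
                    arma::cube Xtr, arma::ivec ytr,
                    arma::cube Xval, arma::ivec yval,
                    int seed, bool verbose) {
  Config cfg = parseConfig(config);
  Params p = paramsFromList(weights, cfg);
  const int nTr = ytr.n_elem, nVal = yval.n_elem;
  const int C = cfg.channels, H = cfg.inputSize;
  if (static_cast<int>(Xtr.n_slices) != nTr * C)
    Rcpp::stop("training stack size does not match labels");
  fcube Xtrf = toFloatCube(Xtr), Xvalf = toFloatCube(Xval);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);
  Adam adam(p);
  Cache cc;
  Params g;

  std::vector<double> trLoss, trAcc, vLoss, vAcc;
  double bestVal = std::numeric_limits<double>::infinity();
  Params best = p;
  int bestEpoch = 0, wait = 0, stoppedEpoch = 0;

  std::vector<uword> order(nTr);
  for (int i = 0; i < nTr; ++i) order[i] = i;
  uvec valIdx = regspace<uvec>(0, nVal > 0 ? nVal - 1 : 0);
  if (nVal == 0) valIdx.reset();

  for (int epoch = 1; epoch <= cfg.maxEpochs; ++epoch) {
    // deterministic step decay: halve the rate every 50 epochs
    const float lr = static_cast<float>(cfg.lr) *
        std::pow(0.5f, (epoch - 1) / 50);
    std::shuffle(order.begin(), order.end(), rng);
    double lossSum = 0; int correct = 0;
    for (int b0 = 0; b0 < nTr; b0 += cfg.batch) {
      const int bN = std::min(cfg.batch, nTr - b0);
      uvec idx(bN);
      for (int k = 0; k < bN; ++k) idx(k) = order[b0 + k];
      fcube xb = cfg.augmentShift ? gatherBatchShifted(Xtrf, idx, C, H, rng)
                                  : gatherBatch(Xtrf, idx, C, H);
      forwardBatch(p, cfg, xb, bN, true, rng, cc);
      lossSum += batchLoss(cc, ytr, idx, &correct);
      zeroInto(g, p);
      backwardBatch(p, cfg, cc, ytr, idx, g);
      scaleParams(g, 1.0f / bN);
      adam.step(p, g, lr);
    }
    trLoss.push_back(lossSum / nTr);
    trAcc.push_back(static_cast<double>(correct) / nTr);

    double vLossSum = 0; int vCorrect = 0;
    for (int b0 = 0; b0 < nVal; b0 += cfg.batch) {
      const int bN = std::min(cfg.batch, nVal - b0);
      uvec idx = valIdx.subvec(b0, b0 + bN - 1);
      fcube xb = gatherBatch(Xvalf, idx, C, H);
      forwardBatch(p, cfg, xb, bN, false, rng, cc);
      vLossSum += batchLoss(cc, yval, idx, &vCorrect);
    }
    const double vl = vLossSum / std::max(1, nVal);
    vLoss.push_back(vl);
    vAcc.push_back(nVal ? static_cast<double>(vCorrect) / nVal : NA_REAL);
    stoppedEpoch = epoch;

    if (verbose)
      Rcpp::Rcout << "epoch " << epoch << ": train loss " << trLoss.back()
                  << " acc " << trAcc.back() << " | val loss " << vl
                  << " acc " << vAcc.back() << "\n";

    if (vl < bestVal - 1e-9) {
      bestVal = vl; best = p; bestEpoch = epoch; wait = 0;
    } else {
      ++wait;
      if (wait > cfg.patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (bestEpoch == 0) { best = p; bestEpoch = stoppedEpoch; }

  return Rcpp::List::create(
      Rcpp::Named("weights") = paramsToList(best),
      Rcpp::Named("trainLoss") = trLoss,
      Rcpp::Named("trainAcc") = trAcc,
      Rcpp::Named("valLoss") = vLoss,
      Rcpp::Named("valAcc") = vAcc,
      Rcpp::Named("stoppedEpoch") = stoppedEpoch,
      Rcpp::Named("bestEpoch") = bestEpoch);
}

// [[Rcpp::export(name = ".cnnPredict")]]
arma::mat cnnPredict(Rcpp::List weights, Rcpp::List config, arma::cube X,
                     int nSamples) {
  Config cfg = parseConfig(config);
  Params p = paramsFromList(weights, cfg);
  std::mt19937_64 rng(1);
  Cache cc;
  fcube Xf = toFloatCube(X);
  mat out(nSamples, cfg.numClasses);
  for (int b0 = 0; b0 < nSamples; b0 += cfg.batch) {
    const int bN = std::min(cfg.batch, nSamples - b0);
    uvec idx = regspace<uvec>(b0, b0 + bN - 1);
    fcube xb = gatherBatch(Xf, idx, cfg.channels, cfg.inputSize);
    forwardBatch(p, cfg, xb, bN, false, rng, cc);
    out.rows(b0, b0 + bN - 1) = conv_to<mat>::from(cc.probs.t());
  }
  // renormalise in double precision so each row sums to 1 exactly
  for (int i = 0; i < nSamples; ++i) out.row(i) /= accu(out.row(i));
  return out;
}
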