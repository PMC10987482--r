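// A small residual convolutional regression network for single-tile defocus
// (dZ) prediction, with Adam, step-decayed learning rate, L2 weight decay,
// early stopping on a validation split, and sharpness-preserving geometric
// augmentation (translation, rotation, reflection, scale, intensity jitter).
//
// Architecture ("reduced-depth" residual CNN, single-channel 64x64 input):
//   avgpool2 -> conv3x3(1->c1) relu -> avgpool2
//   -> [conv3x3(c1->c1) relu -> conv3x3(c1->c1) + skip] relu -> avgpool2
//   -> conv3x3(c1->c2) relu
//   -> [conv3x3(c2->c2) relu -> conv3x3(c2->c2) + skip] relu
//   -> global average pool -> dense(c2->h) relu -> dense(h->1)
//
// Activations for a batch are stored as fmat (C x H*W*B), column-major per
// sample; im2col produces (9C x H*W*B) so every convolution is one GEMM.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const int NPAR = 8; // weight matrices (and bias vectors)

struct Net {
  int c1, c2, hid;
  int stem = 0;       // 0: 2x prepool of the 64 px tile; 1: central 32 px crop
  fmat W[NPAR];
  fvec b[NPAR];
  float g_in;        // fixed input gain set from training-data statistics
  float label_scale; // labels are regressed on y / label_scale
};

struct Adam {
  fmat mW[NPAR], vW[NPAR];
  fvec mb[NPAR], vb[NPAR];
  long t = 0;
  void init(const Net& n) {
    for (int i = 0; i < NPAR; ++i) {
      mW[i].zeros(arma::size(n.W[i]));
      vW[i].zeros(arma::size(n.W[i]));
      mb[i].zeros(arma::size(n.b[i]));
      vb[i].zeros(arma::size(n.b[i]));
    }
  }
};

static void he_init(fmat& W, std::mt19937& rng) {
  std::normal_distribution<float> g(0.0f, 1.0f);
  float s = std::sqrt(2.0f / (float)W.n_cols);
  for (auto& v : W) v = g(rng) * s;
}

static Net net_init(int c1, int c2, int hid, std::mt19937& rng) {
  Net n;
  n.c1 = c1; n.c2 = c2; n.hid = hid;
  n.W[0].set_size(c1, 9);        // conv_in (1 channel)
  n.W[1].set_size(c1, 9 * c1);   // res1 a
  n.W[2].set_size(c1, 9 * c1);   // res1 b
  n.W[3].set_size(c2, 9 * c1);   // conv_mid
  n.W[4].set_size(c2, 9 * c2);   // res2 a
  n.W[5].set_size(c2, 9 * c2);   // res2 b
  n.W[6].set_size(hid, c2);      // fc1
  n.W[7].set_size(1, hid);       // fc2
  for (int i = 0; i < NPAR; ++i) {
    he_init(n.W[i], rng);
    n.b[i].zeros(n.W[i].n_rows);
  }
  n.g_in = 1.0f;
  n.label_scale = 1.0f;
  return n;
}

// im2col for 3x3 pad-1 convolution over batch activations act (C x H*W*B)
static void im2col(const fmat& act, int C, int H, int W, int B, fmat& col) {
  col.set_size(9 * C, H * W * B);
  for (int bb = 0; bb < B; ++bb) {
    int off = bb * H * W;
    for (int c = 0; c < C; ++c) {
      for (int k = 0; k < 9; ++k) {
        int di = k % 3 - 1, dj = k / 3 - 1;
        int r = c * 9 + k;
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          float* dst = col.colptr(off + j * H) ; // column stride H below
          if (js < 0 || js >= W) {
            for (int i = 0; i < H; ++i) col(r, off + j * H + i) = 0.0f;
            continue;
          }
          for (int i = 0; i < H; ++i) {
            int is = i + di;
            col(r, off + j * H + i) =
                (is >= 0 && is < H) ? act(c, off + js * H + is) : 0.0f;
          }
          (void)dst;
        }
      }
    }
  }
}

// accumulate col gradients back to activation gradient (C x H*W*B)
static void col2im(const fmat& dcol, int C, int H, int W, int B, fmat& dact) {
  dact.zeros(C, H * W * B);
  for (int bb = 0; bb < B; ++bb) {
    int off = bb * H * W;
    for (int c = 0; c < C; ++c) {
      for (int k = 0; k < 9; ++k) {
        int di = k % 3 - 1, dj = k / 3 - 1;
        int r = c * 9 + k;
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            int is = i + di;
            if (is < 0 || is >= H) continue;
            dact(c, off + js * H + is) += dcol(r, off + j * H + i);
          }
        }
      }
    }
  }
}

static fmat avgpool2(const fmat& act, int C, int H, int W, int B) {
  int Ho = H / 2, Wo = W / 2;
  fmat out(C, Ho * Wo * B);
  for (int bb = 0; bb < B; ++bb) {
    int off = bb * H * W, offo = bb * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int p00 = off + (2 * j) * H + 2 * i;
        int p01 = off + (2 * j + 1) * H + 2 * i;
        int po = offo + j * Ho + i;
        for (int c = 0; c < C; ++c) {
          out(c, po) = 0.25f * (act(c, p00) + act(c, p00 + 1) +
                                act(c, p01) + act(c, p01 + 1));
        }
      }
    }
  }
  return out;
}

static fmat avgpool2_back(const fmat& dout, int C, int H, int W, int B) {
  // H, W: input (pre-pool) dims
  int Ho = H / 2, Wo = W / 2;
  fmat dact(C, H * W * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    int off = bb * H * W, offo = bb * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int p00 = off + (2 * j) * H + 2 * i;
        int p01 = off + (2 * j + 1) * H + 2 * i;
        int po = offo + j * Ho + i;
        for (int c = 0; c < C; ++c) {
          float g = 0.25f * dout(c, po);
          dact(c, p00) += g;
          dact(c, p00 + 1) += g;
          dact(c, p01) += g;
          dact(c, p01 + 1) += g;
        }
      }
    }
  }
  return dact;
}

struct Cache {
  int B;
  fmat x0;                       // 1 x 1024*B input after prepool and gain
  fmat col0, a1, p1;             // conv_in
  fmat col1, r1a, col2, r1b, r1; // res1
  fmat p2, col3, a2;             // conv_mid
  fmat col4, r2a, col5, r2b, r2; // res2
  fmat g;                        // c2 x B
  fmat h1;                       // hid x B
  arma::frowvec pred;            // 1 x B (scaled)
};

static void forward(const Net& n, const fmat& x0, Cache& cc) {
  int B = x0.n_cols / 1024;
  cc.B = B;
  cc.x0 = x0;
  im2col(cc.x0, 1, 32, 32, B, cc.col0);
  cc.a1 = n.W[0] * cc.col0;
  cc.a1.each_col() += n.b[0];
  cc.a1.clamp(0.0f, std::numeric_limits<float>::max());
  cc.p1 = avgpool2(cc.a1, n.c1, 32, 32, B);
  im2col(cc.p1, n.c1, 16, 16, B, cc.col1);
  cc.r1a = n.W[1] * cc.col1;
  cc.r1a.each_col() += n.b[1];
  cc.r1a.clamp(0.0f, std::numeric_limits<float>::max());
  im2col(cc.r1a, n.c1, 16, 16, B, cc.col2);
  cc.r1b = n.W[2] * cc.col2;
  cc.r1b.each_col() += n.b[2];
  cc.r1 = cc.p1 + cc.r1b;
  cc.r1.clamp(0.0f, std::numeric_limits<float>::max());
  cc.p2 = avgpool2(cc.r1, n.c1, 16, 16, B);
  im2col(cc.p2, n.c1, 8, 8, B, cc.col3);
  cc.a2 = n.W[3] * cc.col3;
  cc.a2.each_col() += n.b[3];
  cc.a2.clamp(0.0f, std::numeric_limits<float>::max());
  im2col(cc.a2, n.c2, 8, 8, B, cc.col4);
  cc.r2a = n.W[4] * cc.col4;
  cc.r2a.each_col() += n.b[4];
  cc.r2a.clamp(0.0f, std::numeric_limits<float>::max());
  im2col(cc.r2a, n.c2, 8, 8, B, cc.col5);
  cc.r2b = n.W[5] * cc.col5;
  cc.r2b.each_col() += n.b[5];
  cc.r2 = cc.a2 + cc.r2b;
  cc.r2.clamp(0.0f, std::numeric_limits<float>::max());
  // global average pool
  cc.g.set_size(n.c2, B);
  for (int bb = 0; bb < B; ++bb)
    cc.g.col(bb) = arma::mean(cc.r2.cols(bb * 64, bb * 64 + 63), 1);
  cc.h1 = n.W[6] * cc.g;
  cc.h1.each_col() += n.b[6];
  cc.h1.clamp(0.0f, std::numeric_limits<float>::max());
  cc.pred = n.W[7] * cc.h1;
  cc.pred += n.b[7](0);
}

struct Grads {
  fmat dW[NPAR];
  fvec db[NPAR];
  void init(const Net& n) {
    for (int i = 0; i < NPAR; ++i) {
      dW[i].zeros(arma::size(n.W[i]));
      db[i].zeros(arma::size(n.b[i]));
    }
  }
};

static void backward(const Net& n, const Cache& cc, const arma::frowvec& dpred,
                     Grads& g) {
  int B = cc.B;
  // fc2
  g.dW[7] = dpred * cc.h1.t();
  g.db[7](0) = arma::accu(dpred);
  fmat dh1 = n.W[7].t() * dpred;
  dh1 %= arma::conv_to<fmat>::from(cc.h1 > 0.0f);
  // fc1
  g.dW[6] = dh1 * cc.g.t();
  g.db[6] = arma::sum(dh1, 1);
  fmat dg = n.W[6].t() * dh1;
  // GAP backward
  fmat dr2(n.c2, 64 * B);
  for (int bb = 0; bb < B; ++bb)
    dr2.cols(bb * 64, bb * 64 + 63) = arma::repmat(dg.col(bb) / 64.0f, 1, 64);
  dr2 %= arma::conv_to<fmat>::from(cc.r2 > 0.0f);
  // res2: r2 = relu(a2 + conv5(relu(conv4(a2))))
  g.dW[5] = dr2 * cc.col5.t();
  g.db[5] = arma::sum(dr2, 1);
  fmat dcol5 = n.W[5].t() * dr2;
  fmat dr2a;
  col2im(dcol5, n.c2, 8, 8, B, dr2a);
  dr2a %= arma::conv_to<fmat>::from(cc.r2a > 0.0f);
  g.dW[4] = dr2a * cc.col4.t();
  g.db[4] = arma::sum(dr2a, 1);
  fmat dcol4 = n.W[4].t() * dr2a;
  fmat da2;
  col2im(dcol4, n.c2, 8, 8, B, da2);
  da2 += dr2; // skip connection
  da2 %= arma::conv_to<fmat>::from(cc.a2 > 0.0f);
  // conv_mid
  g.dW[3] = da2 * cc.col3.t();
  g.db[3] = arma::sum(da2, 1);
  fmat dcol3 = n.W[3].t() * da2;
  fmat dp2;
  col2im(dcol3, n.c1, 8, 8, B, dp2);
  fmat dr1 = avgpool2_back(dp2, n.c1, 16, 16, B);
  dr1 %= arma::conv_to<fmat>::from(cc.r1 > 0.0f);
  // res1
  g.dW[2] = dr1 * cc.col2.t();
  g.db[2] = arma::sum(dr1, 1);
  fmat dcol2 = n.W[2].t() * dr1;
  fmat dr1a;
  col2im(dcol2, n.c1, 16, 16, B, dr1a);
  dr1a %= arma::conv_to<fmat>::from(cc.r1a > 0.0f);
  g.dW[1] = dr1a * cc.col1.t();
  g.db[1] = arma::sum(dr1a, 1);
  fmat dcol1 = n.W[1].t() * dr1a;
  fmat dp1;
  col2im(dcol1, n.c1, 16, 16, B, dp1);
  dp1 += dr1; // skip
  fmat da1 = avgpool2_back(dp1, n.c1, 32, 32, B);
  da1 %= arma::conv_to<fmat>::from(cc.a1 > 0.0f);
  g.dW[0] = da1 * cc.col0.t();
  g.db[0] = arma::sum(da1, 1);
}

// ---- input assembly: augmentation, normalization, gain, 2x prepool ----

struct AugParams {
  bool flip;
  float theta, scale, tx, ty, jitter;
};

// bilinear sample with reflected border from a 64x64 tile (column-major)
static inline float sample_reflect(const float* im, float x, float y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  float fx = x - x0, fy = y - y0;
  auto refl = [](int v) {
    while (v < 0 || v > 63) {
      if (v < 0) v = -v;
      if (v > 63) v = 126 - v;
    }
    return v;
  };
  int xa = refl(x0), xb = refl(x0 + 1), ya = refl(y0), yb = refl(y0 + 1);
  float v00 = im[xa * 64 + ya], v10 = im[xb * 64 + ya];
  float v01 = im[xa * 64 + yb], v11 = im[xb * 64 + yb];
  return (1 - fx) * ((1 - fy) * v00 + fy * v01) +
         fx * ((1 - fy) * v10 + fy * v11);
}

static void augment_tile(const float* in, float* out, const AugParams& ap) {
  const float c = 31.5f;
  float ct = std::cos(ap.theta), st = std::sin(ap.theta);
  for (int j = 0; j < 64; ++j) {
    for (int i = 0; i < 64; ++i) {
      // output pixel (x=j, y=i); invert translate/rotate/scale about center
      float px = j - c - ap.tx, py = i - c - ap.ty;
      float sx = (ct * px + st * py) / ap.scale + c;
      float sy = (-st * px + ct * py) / ap.scale + c;
      if (ap.flip) sx = 63.0f - sx;
      float v = sample_reflect(in, sx, sy) * ap.jitter;
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      out[j * 64 + i] = v;
    }
  }
}

// normalization modes: 0 none, 1 zscore, 2 zerocenter, 3 avg_background
static void normalize_tile_inplace(float* t, int mode, float bg) {
  if (mode == 0) return;
  if (mode == 3) {
    float inv = 1.0f / std::max(bg, 1e-6f);
    for (int k = 0; k < 4096; ++k) t[k] *= inv;
    return;
  }
  double m = 0;
  for (int k = 0; k < 4096; ++k) m += t[k];
  m /= 4096.0;
  if (mode == 2) {
    for (int k = 0; k < 4096; ++k) t[k] -= (float)m;
    return;
  }
  double ss = 0;
  for (int k = 0; k < 4096; ++k) {
    double d = t[k] - m;
    ss += d * d;
  }
  float sd = (float)std::sqrt(ss / 4096.0);
  if (sd < 1e-6f) sd = 1.0f;
  for (int k = 0; k < 4096; ++k) t[k] = (t[k] - (float)m) / sd;
}

// assemble batch input: (1 x 1024*B) after augmentation and normalization.
// Stem 0: 2x average prepool of the full 64 px tile (whole-tile context).
// Stem 1: central 32 px crop at full resolution (the bead plus halo ring;
// preserves the sub-pixel blur detail that average pooling discards).
static fmat make_input(const arma::fmat& X, const arma::uvec& idx,
                       const arma::fvec& bg, int mode, float g_in,
                       int stem, const std::vector<AugParams>* aug) {
  int B = idx.n_elem;
  fmat x0(1, 1024 * B);
  std::vector<float> buf(4096), abuf(4096);
  for (int bb = 0; bb < B; ++bb) {
    // X rows are tiles; copy to buffer
    for (int k = 0; k < 4096; ++k) buf[k] = X(idx[bb], k);
    float* dst = buf.data();
    if (aug) {
      augment_tile(buf.data(), abuf.data(), (*aug)[bb]);
      dst = abuf.data();
    }
    normalize_tile_inplace(dst, mode, (float)bg[idx[bb]]);
    if (stem == 1) {
      for (int j = 0; j < 32; ++j)
        for (int i = 0; i < 32; ++i)
          x0(0, bb * 1024 + j * 32 + i) = dst[(16 + j) * 64 + 16 + i] * g_in;
    } else {
      for (int j = 0; j < 32; ++j) {
        for (int i = 0; i < 32; ++i) {
          float s = dst[(2 * j) * 64 + 2 * i] +
                    dst[(2 * j) * 64 + 2 * i + 1] +
                    dst[(2 * j + 1) * 64 + 2 * i] +
                    dst[(2 * j + 1) * 64 + 2 * i + 1];
          x0(0, bb * 1024 + j * 32 + i) = 0.25f * s * g_in;
        }
      }
    }
  }
  return x0;
}

static arma::fvec predict_scaled(const Net& n, const arma::fmat& X,
                                 const arma::uvec& idx, const arma::fvec& bg,
                                 int mode) {
  arma::fvec out(idx.n_elem);
  Cache cc;
  int pos = 0;
  while (pos < (int)idx.n_elem) {
    int B = std::min(64, (int)idx.n_elem - pos);
    arma::uvec sub = idx.subvec(pos, pos + B - 1);
    fmat x0 = make_input(X, sub, bg, mode, n.g_in, n.stem, nullptr);
    forward(n, x0, cc);
    for (int bb = 0; bb < B; ++bb) out[pos + bb] = cc.pred(bb);
    pos += B;
  }
  return out;
}

static List net_to_list(const Net& n) {
  List Ws(NPAR), bs(NPAR);
  for (int i = 0; i < NPAR; ++i) {
    Ws[i] = arma::conv_to<arma::mat>::from(n.W[i]);
    bs[i] = arma::conv_to<arma::vec>::from(n.b[i]);
  }
  return List::create(_["W"] = Ws, _["b"] = bs, _["c1"] = n.c1,
                      _["c2"] = n.c2, _["hidden"] = n.hid,
                      _["stem"] = n.stem, _["g_in"] = (double)n.g_in,
                      _["label_scale"] = (double)n.label_scale);
}

static Net net_from_list(const List& m) {
  Net n;
  n.c1 = as<int>(m["c1"]);
  n.c2 = as<int>(m["c2"]);
  n.hid = as<int>(m["hidden"]);
  n.stem = m.containsElementNamed("stem") ? as<int>(m["stem"]) : 0;
  List Ws = m["W"], bs = m["b"];
  for (int i = 0; i < NPAR; ++i) {
    n.W[i] = arma::conv_to<fmat>::from(as<arma::mat>(Ws[i]));
    n.b[i] = arma::conv_to<fvec>::from(as<arma::vec>(bs[i]));
  }
  n.g_in = (float)as<double>(m["g_in"]);
  n.label_scale = (float)as<double>(m["label_scale"]);
  return n;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::mat& Xd, const arma::vec& yd,
                   const arma::vec& bgd, List cfg, int seed) {
  arma::fmat X = arma::conv_to<arma::fmat>::from(Xd);
  arma::fvec y = arma::conv_to<arma::fvec>::from(yd);
  arma::fvec bg = arma::conv_to<arma::fvec>::from(bgd);
  int n = X.n_rows;
  if ((int)y.n_elem != n) stop("labels length mismatch");

  double lr0 = as<double>(cfg["initial_learning_rate"]);
  int drop_period = as<int>(cfg["lr_drop_period_epochs"]);
  double drop_factor = as<double>(cfg["lr_drop_factor"]);
  int batch = as<int>(cfg["batch_size"]);
  int val_freq = as<int>(cfg["validation_frequency_steps"]);
  int patience = as<int>(cfg["validation_patience"]);
  double l2 = as<double>(cfg["l2_weight_decay"]);
  double val_frac = as<double>(cfg["validation_fraction"]);
  int max_epochs = as<int>(cfg["max_epochs"]);
  int mode = as<int>(cfg["norm_mode"]);
  int c1 = as<int>(cfg["c1"]), c2 = as<int>(cfg["c2"]),
      hid = as<int>(cfg["hidden"]);
  bool augment = as<bool>(cfg["augment"]);
  int stem = cfg.containsElementNamed("stem") ? as<int>(cfg["stem"]) : 0;
  double tr_px = as<double>(cfg["translate_px"]);
  double rot = as<double>(cfg["rotate_deg"]) * M_PI / 180.0;
  double sc_lo = as<double>(cfg["scale_lo"]), sc_hi = as<double>(cfg["scale_hi"]);
  bool reflect = as<bool>(cfg["reflection"]);
  double jit = as<double>(cfg["jitter_amplitude"]);

  if (n < batch) stop("training set smaller than one batch");

  std::mt19937 rng(seed);
  Net net = net_init(c1, c2, hid, rng);
  net.stem = stem;

  // validation split
  arma::uvec perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  int n_val = std::max(1, (int)std::round(val_frac * n));
  if (n_val >= n) n_val = n - 1;
  arma::uvec val_idx = perm.subvec(0, n_val - 1);
  arma::uvec tr_idx = perm.subvec(n_val, n - 1);
  int n_tr = tr_idx.n_elem;

  // label scale and input gain from training data statistics
  float ls = arma::abs(y).max();
  if (ls < 1e-6f) ls = 1.0f;
  net.label_scale = ls;
  {
    arma::uvec probe = tr_idx.head(std::min(n_tr, 128));
    fmat x0 = make_input(X, probe, bg, mode, 1.0f, net.stem, nullptr);
    float sd = arma::stddev(arma::vectorise(x0));
    float rms = std::sqrt(arma::mean(arma::square(arma::vectorise(x0))));
    float denom = std::max(std::max(sd, rms * 0.1f), 1e-6f);
    net.g_in = 1.0f / denom;
  }

  Adam opt;
  opt.init(net);
  std::uniform_real_distribution<float> u01(0.0f, 1.0f);

  long step = 0;
  float best_rmse = std::numeric_limits<float>::infinity();
  int bad = 0;
  bool stop_now = false;
  Net best = net;
  bool has_best = false;
  std::vector<double> log_step, log_epoch, log_rmse;
  Cache cc;
  Grads gr;
  gr.init(net);
  int epochs_run = 0;

  auto validate = [&](int epoch) {
    arma::fvec p = predict_scaled(net, X, val_idx, bg, mode);
    arma::fvec t = y.elem(val_idx) / net.label_scale;
    float rmse = std::sqrt(arma::mean(arma::square(p - t))) * net.label_scale;
    log_step.push_back((double)step);
    log_epoch.push_back((double)epoch);
    log_rmse.push_back((double)rmse);
    if (rmse < best_rmse - 1e-6f) {
      best_rmse = rmse;
      best = net;
      has_best = true;
      bad = 0;
    } else {
      ++bad;
      if (bad > patience) stop_now = true;
    }
  };

  for (int epoch = 0; epoch < max_epochs && !stop_now; ++epoch) {
    epochs_run = epoch + 1;
    float lr = (float)(lr0 * std::pow(drop_factor, epoch / drop_period));
    std::shuffle(tr_idx.begin(), tr_idx.end(), rng);
    for (int pos = 0; pos + 1 < n_tr && !stop_now; pos += batch) {
      int B = std::min(batch, n_tr - pos);
      arma::uvec bidx = tr_idx.subvec(pos, pos + B - 1);
      std::vector<AugParams> aug(B);
      for (int bb = 0; bb < B; ++bb) {
        AugParams& a = aug[bb];
        if (augment) {
          a.flip = reflect && (u01(rng) < 0.5f);
          a.theta = (u01(rng) * 2 - 1) * (float)rot;
          a.scale = (float)sc_lo + u01(rng) * (float)(sc_hi - sc_lo);
          a.tx = (u01(rng) * 2 - 1) * (float)tr_px;
          a.ty = (u01(rng) * 2 - 1) * (float)tr_px;
          a.jitter = 1.0f + (u01(rng) * 2 - 1) * (float)jit;
        } else {
          a = {false, 0.0f, 1.0f, 0.0f, 0.0f, 1.0f};
        }
      }
      fmat x0 = make_input(X, bidx, bg, mode, net.g_in, net.stem,
                           augment ? &aug : nullptr);
      forward(net, x0, cc);
      arma::frowvec t(B);
      for (int bb = 0; bb < B; ++bb) t(bb) = y[bidx[bb]] / net.label_scale;
      arma::frowvec dpred = 2.0f * (cc.pred - t) / (float)B;
      float loss = arma::mean(arma::square(cc.pred - t));
      if (!std::isfinite(loss)) stop("training diverged: non-finite loss");
      backward(net, cc, dpred, gr);
      // Adam with L2 weight decay on weights
      ++opt.t;
      float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
      float bc1 = 1.0f - std::pow(b1, (float)opt.t);
      float bc2 = 1.0f - std::pow(b2, (float)opt.t);
      for (int i = 0; i < NPAR; ++i) {
        fmat gW = gr.dW[i] + (float)l2 * net.W[i];
        opt.mW[i] = b1 * opt.mW[i] + (1 - b1) * gW;
        opt.vW[i] = b2 * opt.vW[i] + (1 - b2) * arma::square(gW);
        net.W[i] -= lr * (opt.mW[i] / bc1) /
                    (arma::sqrt(opt.vW[i] / bc2) + eps);
        opt.mb[i] = b1 * opt.mb[i] + (1 - b1) * gr.db[i];
        opt.vb[i] = b2 * opt.vb[i] + (1 - b2) * arma::square(gr.db[i]);
        net.b[i] -= lr * (opt.mb[i] / bc1) /
                    (arma::sqrt(opt.vb[i] / bc2) + eps);
      }
      ++step;
      if (val_freq > 0 && step % val_freq == 0) validate(epoch);
    }
    Rcpp::checkUserInterrupt();
  }
  // final validation so every model reports a validation RMSE; the returned
  // model is the best-on-validation snapshot
  validate(std::max(0, epochs_run - 1));
  Net& fin = has_best ? best : net;

  List out = net_to_list(fin);
  out["log"] = DataFrame::create(_["step"] = log_step, _["epoch"] = log_epoch,
                                 _["val_rmse"] = log_rmse);
  out["best_val_rmse"] = (double)best_rmse;
  out["epochs_run"] = epochs_run;
  out["n_train"] = (int)n_tr;
  out["n_val"] = (int)n_val;
  return out;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::vec cnn_predict_cpp(List model, const arma::mat& Xd,
                          const arma::vec& bgd, int mode) {
  Net n = net_from_list(model);
  arma::fmat X = arma::conv_to<arma::fmat>::from(Xd);
  arma::fvec bg = arma::conv_to<arma::fvec>::from(bgd);
  arma::uvec idx(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) idx[i] = i;
  arma::fvec p = predict_scaled(n, X, idx, bg, mode);
  return arma::conv_to<arma::vec>::from(p) * (double)n.label_scale;
}

// [[Rcpp::export(name = ".augment_tile_cpp")]]
arma::mat augment_tile_cpp(const arma::mat& tile, bool flip, double theta_deg,
                           double scale, double tx, double ty, double jitter) {
  if (tile.n_rows != 64 || tile.n_cols != 64) stop("tile must be 64 x 64");
  arma::fmat in = arma::conv_to<arma::fmat>::from(tile);
  std::vector<float> out(4096);
  AugParams a{flip, (float)(theta_deg * M_PI / 180.0), (float)scale,
              (float)tx, (float)ty, (float)jitter};
  augment_tile(in.memptr(), out.data(), a);
  arma::fmat o(out.data(), 64, 64);
  return arma::conv_to<arma::mat>::from(o);
}
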