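// Hybrid convolutional / bidirectional-LSTM / self-attention network
// with two softmax heads, implemented directly on Armadillo.
//
// Layout conventions:
//   input        : cube (F, T, N)  -- feature rows x time frames x batch
//   feature maps : cube (C, F*T, N), spatial index s = f + F*t
//   sequences    : per-sample mat (D, T'), batched as cube (D, N, T')
// All forward caches needed by the backward pass are kept in a Cache
// struct; forward() is shared between training and inference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
// Large Armadillo buffers are allocated afresh on every training step;
// with the default mmap threshold glibc returns them to the kernel on
// free and the next step pays the full page-fault cost again (very
// expensive under some hypervisors). Serving them from the main arena
// keeps the pages warm across steps.
static struct MallocTuner {
  MallocTuner() {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
  }
} malloc_tuner;
#endif
using namespace Rcpp;
using mat = arma::fmat;
using vec = arma::fvec;
using cube = arma::fcube;
using rowvec = arma::frowvec;
using arma::uword;
typedef float real_t;

struct Config {
  int F, T, C1, C2, H, D, heads, FF, FC, nem, ntx;
  real_t drop_lstm, drop_fc, bn_eps, bn_momentum;
  int F2() const { return F / 2; }
  int T2() const { return T / 2; }
  int F4() const { return F / 4; }
  int T4() const { return T / 4; }
  int Dseq() const { return C2 * F4(); }
};

static Config read_config(const List& cfg) {
  Config c;
  c.F = as<int>(cfg["n_feature_rows"]);
  c.T = as<int>(cfg["n_frames"]);
  c.C1 = as<int>(cfg["conv_channels1"]);
  c.C2 = as<int>(cfg["conv_channels2"]);
  c.H = as<int>(cfg["lstm_units"]);
  c.D = as<int>(cfg["attn_dim"]);
  c.heads = as<int>(cfg["attn_heads"]);
  c.FF = as<int>(cfg["ff_dim"]);
  c.FC = as<int>(cfg["fc_units"]);
  c.nem = as<int>(cfg["n_emotions"]);
  c.ntx = as<int>(cfg["n_texts"]);
  c.drop_lstm = as<real_t>(cfg["dropout_lstm"]);
  c.drop_fc = as<real_t>(cfg["dropout_fc"]);
  c.bn_eps = as<real_t>(cfg["bn_eps"]);
  c.bn_momentum = as<real_t>(cfg["bn_momentum"]);
  if (c.F % 4 || c.T % 4)
    stop("feature rows and frames must be divisible by 4");
  if (c.D % c.heads) stop("attn_dim must be divisible by attn_heads");
  return c;
}

struct Params {
  mat conv1_w; vec conv1_b, bn1_g, bn1_b, bn1_rm, bn1_rv;
  mat conv2_w; vec conv2_b, bn2_g, bn2_b, bn2_rm, bn2_rv;
  // lstm[layer][dir]: W (4H x Din), U (4H x H), b (4H)
  mat lstm_w[2][2], lstm_u[2][2]; vec lstm_b[2][2];
  mat proj_w; vec proj_b;
  mat wq, wk, wv, wo; vec bq, bk, bv, bo;
  vec ln1_g, ln1_b, ln2_g, ln2_b;
  mat ff1_w; vec ff1_b; mat ff2_w; vec ff2_b;
  mat fc_w; vec fc_b; mat em_w; vec em_b; mat tx_w; vec tx_b;
};

static const char* lstm_name(const char* what, int layer, int dir,
                             char* buf) {
  snprintf(buf, 64, "lstm%d_%s_%s", layer + 1, dir == 0 ? "fwd" : "bwd",
           what);
  return buf;
}

static Params read_params(const List& p) {
  Params w;
  char buf[64];
  w.conv1_w = as<mat>(p["conv1_w"]); w.conv1_b = as<vec>(p["conv1_b"]);
  w.bn1_g = as<vec>(p["bn1_gamma"]); w.bn1_b = as<vec>(p["bn1_beta"]);
  w.bn1_rm = as<vec>(p["bn1_run_mean"]); w.bn1_rv = as<vec>(p["bn1_run_var"]);
  w.conv2_w = as<mat>(p["conv2_w"]); w.conv2_b = as<vec>(p["conv2_b"]);
  w.bn2_g = as<vec>(p["bn2_gamma"]); w.bn2_b = as<vec>(p["bn2_beta"]);
  w.bn2_rm = as<vec>(p["bn2_run_mean"]); w.bn2_rv = as<vec>(p["bn2_run_var"]);
  for (int l = 0; l < 2; ++l) for (int d = 0; d < 2; ++d) {
    w.lstm_w[l][d] = as<mat>(p[lstm_name("w", l, d, buf)]);
    w.lstm_u[l][d] = as<mat>(p[lstm_name("u", l, d, buf)]);
    w.lstm_b[l][d] = as<vec>(p[lstm_name("b", l, d, buf)]);
  }
  w.proj_w = as<mat>(p["proj_w"]); w.proj_b = as<vec>(p["proj_b"]);
  w.wq = as<mat>(p["attn_wq"]); w.bq = as<vec>(p["attn_bq"]);
  w.wk = as<mat>(p["attn_wk"]); w.bk = as<vec>(p["attn_bk"]);
  w.wv = as<mat>(p["attn_wv"]); w.bv = as<vec>(p["attn_bv"]);
  w.wo = as<mat>(p["attn_wo"]); w.bo = as<vec>(p["attn_bo"]);
  w.ln1_g = as<vec>(p["ln1_gamma"]); w.ln1_b = as<vec>(p["ln1_beta"]);
  w.ln2_g = as<vec>(p["ln2_gamma"]); w.ln2_b = as<vec>(p["ln2_beta"]);
  w.ff1_w = as<mat>(p["ff1_w"]); w.ff1_b = as<vec>(p["ff1_b"]);
  w.ff2_w = as<mat>(p["ff2_w"]); w.ff2_b = as<vec>(p["ff2_b"]);
  w.fc_w = as<mat>(p["fc_w"]); w.fc_b = as<vec>(p["fc_b"]);
  w.em_w = as<mat>(p["head_em_w"]); w.em_b = as<vec>(p["head_em_b"]);
  w.tx_w = as<mat>(p["head_tx_w"]); w.tx_b = as<vec>(p["head_tx_b"]);
  return w;
}

// ---- primitive ops -------------------------------------------------

// 3x3 same-padding im2col; input (C, F*T) -> (C*9, F*T).
// Patch rows are laid out offset-major (row = o*C + c, o = 3*(kf+1) +
// (kt+1)) so that for each spatial position the C source and C
// destination real_ts are contiguous and can be block-copied. The
// convolution weights use the same column convention.
static mat im2col3x3(const mat& in, int C, int F, int T) {
  mat col(C * 9, F * T, arma::fill::zeros);
  const real_t* src = in.memptr();
  real_t* dst = col.memptr();
  const uword CR = (uword)C * 9;
  for (int kf = -1; kf <= 1; ++kf) {
    for (int kt = -1; kt <= 1; ++kt) {
      uword o = (uword)((kf + 1) * 3 + (kt + 1)) * C;
      int f_lo = std::max(0, -kf), f_hi = std::min(F, F - kf);
      for (int t = 0; t < T; ++t) {
        int ts = t + kt;
        if (ts < 0 || ts >= T) continue;
        for (int f = f_lo; f < f_hi; ++f) {
          std::memcpy(dst + CR * (uword)(f + F * t) + o,
                      src + (uword)C * (uword)((f + kf) + F * ts),
                      sizeof(real_t) * C);
        }
      }
    }
  }
  return col;
}

// scatter-add the im2col gradient back to the input gradient
static void col2im3x3(mat& gin, const mat& gcol, int C, int F, int T) {
  const real_t* src = gcol.memptr();
  real_t* dst = gin.memptr();
  const uword CR = (uword)C * 9;
  for (int kf = -1; kf <= 1; ++kf) {
    for (int kt = -1; kt <= 1; ++kt) {
      uword o = (uword)((kf + 1) * 3 + (kt + 1)) * C;
      int f_lo = std::max(0, -kf), f_hi = std::min(F, F - kf);
      for (int t = 0; t < T; ++t) {
        int ts = t + kt;
        if (ts < 0 || ts >= T) continue;
        for (int f = f_lo; f < f_hi; ++f) {
          real_t* d = dst + (uword)C * (uword)((f + kf) + F * ts);
          const real_t* s = src + CR * (uword)(f + F * t) + o;
          for (int c = 0; c < C; ++c) d[c] += s[c];
        }
      }
    }
  }
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---- caches --------------------------------------------------------

struct Cache {
  int N;
  cube x;                         // input (F, T, N)
  std::vector<mat> col1;          // cached conv1 patches per sample
  cube a1, a2;                    // conv outputs pre-BN
  vec bn1_mu, bn1_var, bn2_mu, bn2_var;
  cube r1, r2;                    // post-BN+ReLU maps
  arma::ucube pool1_idx, pool2_idx;
  cube p1, p2;                    // pooled maps
  // lstm caches: [layer][dir] cubes (H, N, T') and gate cube (4H, N, T')
  cube lstm_h[2][2], lstm_c[2][2], lstm_g[2][2];
  cube seq_in[2];                 // inputs to lstm layer (Din, N, T')
  cube drop_mask[2];              // dropout masks on lstm outputs
  cube lstm_out[2];               // (2H, N, T') after dropout
  cube z0;                        // projected (D, N, T')
  // attention
  std::vector<mat> attn_A;        // per sample*head (Tq x Tk)
  cube q, k, v, attn_cat;         // (D, N, T')
  cube attn_res;                  // z0 + attn out (pre-LN1)
  vec ln1_mu, ln1_sd, ln2_mu, ln2_sd;   // per (sample, t) flattened
  cube z1;                        // after LN1 (D, N, T')
  cube ff_h;                      // (FF, N, T') post-ReLU
  cube ff_res;                    // z1 + ff out (pre-LN2)
  cube z2;                        // after LN2
  mat gap;                        // (D, N)
  mat fc_h;                       // (FC, N) post-ReLU
  mat fc_mask;                    // dropout mask
  mat em_p, tx_p;                 // softmax probs
};

// maxpool 2x2 on (C, F*T) -> (C, (F/2)*(T/2)); records argmax
static void maxpool(const mat& in, mat& out, arma::umat& idx,
                    int C, int F, int T) {
  int F2 = F / 2, T2 = T / 2;
  for (int c = 0; c < C; ++c) {
    for (int t2 = 0; t2 < T2; ++t2) {
      for (int f2 = 0; f2 < F2; ++f2) {
        real_t best = -1e300; uword bi = 0;
        for (int dt = 0; dt < 2; ++dt) for (int df = 0; df < 2; ++df) {
          uword s = (2 * f2 + df) + F * (2 * t2 + dt);
          real_t val = in(c, s);
          if (val > best) { best = val; bi = s; }
        }
        out(c, f2 + F2 * t2) = best;
        idx(c, f2 + F2 * t2) = bi;
      }
    }
  }
}

// ---- forward -------------------------------------------------------

static void forward(const Params& w, const Config& cf, const cube& X,
                    bool training, uint64_t seed, Cache& cc,
                    vec* bn1_rm_new = nullptr, vec* bn1_rv_new = nullptr,
                    vec* bn2_rm_new = nullptr, vec* bn2_rv_new = nullptr) {
  const int N = X.n_slices;
  cc.N = N; cc.x = X;
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // conv1 + BN + ReLU + pool
  cc.a1.set_size(cf.C1, cf.F * cf.T, N);
  cc.col1.assign(N, mat());
  for (int n = 0; n < N; ++n) {
    mat in(1, cf.F * cf.T);
    in.row(0) = arma::vectorise(X.slice(n)).t();
    cc.col1[n] = im2col3x3(in, 1, cf.F, cf.T);
    cc.a1.slice(n) = w.conv1_w * cc.col1[n];
    cc.a1.slice(n).each_col() += w.conv1_b;
  }
  // batch norm over batch x spatial, per channel
  vec mu1(cf.C1), var1(cf.C1);
  if (training) {
    real_t M = (real_t)N * cf.F * cf.T;
    vec s(cf.C1, arma::fill::zeros), s2(cf.C1, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      s += arma::sum(cc.a1.slice(n), 1);
      s2 += arma::sum(arma::square(cc.a1.slice(n)), 1);
    }
    mu1 = s / M; var1 = s2 / M - arma::square(mu1);
    if (bn1_rm_new) {
      *bn1_rm_new = (1 - cf.bn_momentum) * w.bn1_rm + cf.bn_momentum * mu1;
      *bn1_rv_new = (1 - cf.bn_momentum) * w.bn1_rv + cf.bn_momentum * var1;
    }
  } else { mu1 = w.bn1_rm; var1 = w.bn1_rv; }
  cc.bn1_mu = mu1; cc.bn1_var = var1;
  cc.r1.set_size(cf.C1, cf.F * cf.T, N);
  {
    vec sc1 = w.bn1_g / arma::sqrt(var1 + cf.bn_eps);
    vec sh1 = w.bn1_b - mu1 % sc1;
    for (int n = 0; n < N; ++n) {
      mat tmp = cc.a1.slice(n);
      tmp.each_col() %= sc1;
      tmp.each_col() += sh1;
      cc.r1.slice(n) = arma::clamp(tmp, 0.0, arma::datum::inf);
    }
  }
  cc.p1.set_size(cf.C1, cf.F2() * cf.T2(), N);
  cc.pool1_idx.set_size(cf.C1, cf.F2() * cf.T2(), N);
  for (int n = 0; n < N; ++n) {
    mat out(cf.C1, cf.F2() * cf.T2());
    arma::umat idx(cf.C1, cf.F2() * cf.T2());
    maxpool(cc.r1.slice(n), out, idx, cf.C1, cf.F, cf.T);
    cc.p1.slice(n) = out; cc.pool1_idx.slice(n) = idx;
  }

  // conv2 + BN + ReLU + pool
  cc.a2.set_size(cf.C2, cf.F2() * cf.T2(), N);
  for (int n = 0; n < N; ++n) {
    mat col2 = im2col3x3(cc.p1.slice(n), cf.C1, cf.F2(), cf.T2());
    cc.a2.slice(n) = w.conv2_w * col2;
    cc.a2.slice(n).each_col() += w.conv2_b;
  }
  vec mu2(cf.C2), var2(cf.C2);
  if (training) {
    real_t M = (real_t)N * cf.F2() * cf.T2();
    vec s(cf.C2, arma::fill::zeros), s2(cf.C2, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      s += arma::sum(cc.a2.slice(n), 1);
      s2 += arma::sum(arma::square(cc.a2.slice(n)), 1);
    }
    mu2 = s / M; var2 = s2 / M - arma::square(mu2);
    if (bn2_rm_new) {
      *bn2_rm_new = (1 - cf.bn_momentum) * w.bn2_rm + cf.bn_momentum * mu2;
      *bn2_rv_new = (1 - cf.bn_momentum) * w.bn2_rv + cf.bn_momentum * var2;
    }
  } else { mu2 = w.bn2_rm; var2 = w.bn2_rv; }
  cc.bn2_mu = mu2; cc.bn2_var = var2;
  cc.r2.set_size(cf.C2, cf.F2() * cf.T2(), N);
  {
    vec sc2 = w.bn2_g / arma::sqrt(var2 + cf.bn_eps);
    vec sh2 = w.bn2_b - mu2 % sc2;
    for (int n = 0; n < N; ++n) {
      mat tmp = cc.a2.slice(n);
      tmp.each_col() %= sc2;
      tmp.each_col() += sh2;
      cc.r2.slice(n) = arma::clamp(tmp, 0.0, arma::datum::inf);
    }
  }
  cc.p2.set_size(cf.C2, cf.F4() * cf.T4(), N);
  cc.pool2_idx.set_size(cf.C2, cf.F4() * cf.T4(), N);
  for (int n = 0; n < N; ++n) {
    mat out(cf.C2, cf.F4() * cf.T4());
    arma::umat idx(cf.C2, cf.F4() * cf.T4());
    maxpool(cc.r2.slice(n), out, idx, cf.C2, cf.F2(), cf.T2());
    cc.p2.slice(n) = out; cc.pool2_idx.slice(n) = idx;
  }

  // to sequence: (Dseq, N, T'); feature = (c + C2*f), time = t
  const int Tp = cf.T4(), Ds = cf.Dseq();
  cc.seq_in[0].set_size(Ds, N, Tp);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < Tp; ++t)
      for (int f = 0; f < cf.F4(); ++f)
        for (int c = 0; c < cf.C2; ++c)
          cc.seq_in[0](c + cf.C2 * f, n, t) = cc.p2(c, f + cf.F4() * t, n);

  // two bidirectional LSTM layers
  for (int l = 0; l < 2; ++l) {
    int Din = (l == 0) ? Ds : 2 * cf.H;
    const cube& in = cc.seq_in[l];
    cube out(2 * cf.H, N, Tp, arma::fill::zeros);
    for (int d = 0; d < 2; ++d) {
      cc.lstm_h[l][d].set_size(cf.H, N, Tp);
      cc.lstm_c[l][d].set_size(cf.H, N, Tp);
      cc.lstm_g[l][d].set_size(4 * cf.H, N, Tp);
      mat h(cf.H, N, arma::fill::zeros), c(cf.H, N, arma::fill::zeros);
      for (int step = 0; step < Tp; ++step) {
        int t = (d == 0) ? step : (Tp - 1 - step);
        mat xt(Din, N);
        for (int n = 0; n < N; ++n) xt.col(n) = in.slice(t).col(n);
        mat z = w.lstm_w[l][d] * xt + w.lstm_u[l][d] * h;
        z.each_col() += w.lstm_b[l][d];
        mat ig = sigmoid(z.rows(0, cf.H - 1));
        mat fg = sigmoid(z.rows(cf.H, 2 * cf.H - 1));
        mat gg = arma::tanh(z.rows(2 * cf.H, 3 * cf.H - 1));
        mat og = sigmoid(z.rows(3 * cf.H, 4 * cf.H - 1));
        c = fg % c + ig % gg;
        h = og % arma::tanh(c);
        cc.lstm_g[l][d].slice(t).rows(0, cf.H - 1) = ig;
        cc.lstm_g[l][d].slice(t).rows(cf.H, 2 * cf.H - 1) = fg;
        cc.lstm_g[l][d].slice(t).rows(2 * cf.H, 3 * cf.H - 1) = gg;
        cc.lstm_g[l][d].slice(t).rows(3 * cf.H, 4 * cf.H - 1) = og;
        cc.lstm_c[l][d].slice(t) = c;
        cc.lstm_h[l][d].slice(t) = h;
        out.slice(t).rows(d * cf.H, (d + 1) * cf.H - 1) = h;
      }
    }
    // dropout between stacked LSTM layers only (framework semantics:
    // the last layer's output is not dropped)
    cc.drop_mask[l].set_size(2 * cf.H, N, Tp);
    if (training && cf.drop_lstm > 0 && l == 0) {
      real_t keep = 1.0 - cf.drop_lstm;
      for (uword i = 0; i < cc.drop_mask[l].n_elem; ++i)
        cc.drop_mask[l](i) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      out %= cc.drop_mask[l];
    } else cc.drop_mask[l].fill(1.0);
    cc.lstm_out[l] = out;
    if (l == 0) cc.seq_in[1] = out;
  }

  // linear projection to model width
  cc.z0.set_size(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat m = w.proj_w * cc.lstm_out[1].slice(t);
    m.each_col() += w.proj_b;
    cc.z0.slice(t) = m;
  }

  // multi-head self-attention (post-LN transformer block)
  const int dk = cf.D / cf.heads;
  const real_t scale = 1.0 / std::sqrt((real_t)dk);
  // pre-LN: attention operates on the layer-normalized projection
  cc.ln1_mu.set_size((uword)N * Tp); cc.ln1_sd.set_size((uword)N * Tp);
  cc.z1.set_size(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    for (int n = 0; n < N; ++n) {
      vec xcol = cc.z0.slice(t).col(n);
      real_t mu = arma::mean(xcol);
      real_t sd = std::sqrt(arma::mean(arma::square(xcol - mu)) + (real_t)cf.bn_eps);
      cc.ln1_mu(n + (uword)N * t) = mu;
      cc.ln1_sd(n + (uword)N * t) = sd;
      cc.z1.slice(t).col(n) = w.ln1_g % ((xcol - mu) / sd) + w.ln1_b;
    }
  }
  cc.q.set_size(cf.D, N, Tp); cc.k.set_size(cf.D, N, Tp);
  cc.v.set_size(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat zt = cc.z1.slice(t);
    cc.q.slice(t) = w.wq * zt; cc.q.slice(t).each_col() += w.bq;
    cc.k.slice(t) = w.wk * zt; cc.k.slice(t).each_col() += w.bk;
    cc.v.slice(t) = w.wv * zt; cc.v.slice(t).each_col() += w.bv;
  }
  cc.attn_A.assign((size_t)N * cf.heads, mat());
  cc.attn_cat.set_size(cf.D, N, Tp);
  for (int n = 0; n < N; ++n) {
    // gather (D, T') for this sample
    mat Q(cf.D, Tp), K(cf.D, Tp), V(cf.D, Tp);
    for (int t = 0; t < Tp; ++t) {
      Q.col(t) = cc.q.slice(t).col(n);
      K.col(t) = cc.k.slice(t).col(n);
      V.col(t) = cc.v.slice(t).col(n);
    }
    for (int h = 0; h < cf.heads; ++h) {
      mat Qh = Q.rows(h * dk, (h + 1) * dk - 1);
      mat Kh = K.rows(h * dk, (h + 1) * dk - 1);
      mat Vh = V.rows(h * dk, (h + 1) * dk - 1);
      mat S = (Qh.t() * Kh) * scale;        // (Tq, Tk)
      S.each_col() -= arma::max(S, 1);
      mat A = arma::exp(S);
      A.each_col() /= arma::sum(A, 1);
      cc.attn_A[(size_t)n * cf.heads + h] = A;
      mat Oh = Vh * A.t();                   // (dk, Tq)
      for (int t = 0; t < Tp; ++t)
        cc.attn_cat.slice(t).submat(h * dk, n, (h + 1) * dk - 1, n) =
          Oh.col(t);
    }
  }
  cc.attn_res.set_size(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat o = w.wo * cc.attn_cat.slice(t);
    o.each_col() += w.bo;
    cc.attn_res.slice(t) = cc.z0.slice(t) + o;
  }

  // pre-LN feed-forward branch
  cc.ln2_mu.set_size((uword)N * Tp); cc.ln2_sd.set_size((uword)N * Tp);
  cc.z2.set_size(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    for (int n = 0; n < N; ++n) {
      vec xcol = cc.attn_res.slice(t).col(n);
      real_t mu = arma::mean(xcol);
      real_t sd = std::sqrt(arma::mean(arma::square(xcol - mu)) + (real_t)cf.bn_eps);
      cc.ln2_mu(n + (uword)N * t) = mu;
      cc.ln2_sd(n + (uword)N * t) = sd;
      cc.z2.slice(t).col(n) = w.ln2_g % ((xcol - mu) / sd) + w.ln2_b;
    }
  }
  cc.ff_h.set_size(cf.FF, N, Tp);
  cc.ff_res.set_size(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat hdd = w.ff1_w * cc.z2.slice(t);
    hdd.each_col() += w.ff1_b;
    hdd = arma::clamp(hdd, 0.0, arma::datum::inf);
    cc.ff_h.slice(t) = hdd;
    mat o = w.ff2_w * hdd;
    o.each_col() += w.ff2_b;
    cc.ff_res.slice(t) = cc.attn_res.slice(t) + o;
  }

  // global average pooling over time, FC, dropout, heads
  cc.gap.zeros(cf.D, N);
  for (int t = 0; t < Tp; ++t) cc.gap += cc.ff_res.slice(t);
  cc.gap /= (real_t)Tp;
  mat fca = w.fc_w * cc.gap;
  fca.each_col() += w.fc_b;
  cc.fc_h = arma::clamp(fca, 0.0, arma::datum::inf);
  cc.fc_mask.set_size(cf.FC, N);
  if (training && cf.drop_fc > 0) {
    real_t keep = 1.0 - cf.drop_fc;
    for (uword i = 0; i < cc.fc_mask.n_elem; ++i)
      cc.fc_mask(i) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
  } else cc.fc_mask.fill(1.0);
  mat fcd = cc.fc_h % cc.fc_mask;
  mat em_l = w.em_w * fcd; em_l.each_col() += w.em_b;
  mat tx_l = w.tx_w * fcd; tx_l.each_col() += w.tx_b;
  em_l.each_row() -= arma::max(em_l, 0);
  tx_l.each_row() -= arma::max(tx_l, 0);
  cc.em_p = arma::exp(em_l); cc.em_p.each_row() /= arma::sum(cc.em_p, 0);
  cc.tx_p = arma::exp(tx_l); cc.tx_p.each_row() /= arma::sum(cc.tx_p, 0);
}

// ---- backward ------------------------------------------------------

struct Grads {
  mat conv1_w; vec conv1_b, bn1_g, bn1_b;
  mat conv2_w; vec conv2_b, bn2_g, bn2_b;
  mat lstm_w[2][2], lstm_u[2][2]; vec lstm_b[2][2];
  mat proj_w; vec proj_b;
  mat wq, wk, wv, wo; vec bq, bk, bv, bo;
  vec ln1_g, ln1_b, ln2_g, ln2_b;
  mat ff1_w; vec ff1_b; mat ff2_w; vec ff2_b;
  mat fc_w; vec fc_b; mat em_w; vec em_b; mat tx_w; vec tx_b;
};

static void backward(const Params& w, const Config& cf, const Cache& cc,
                     const arma::ivec& y_em, const arma::ivec& y_tx,
                     Grads& g) {
  const int N = cc.N, Tp = cf.T4(), Ds = cf.Dseq();
  const int dk = cf.D / cf.heads;
  const real_t scale = 1.0 / std::sqrt((real_t)dk);

  // heads
  mat dem = cc.em_p, dtx = cc.tx_p;
  for (int n = 0; n < N; ++n) { dem(y_em(n), n) -= 1.0; dtx(y_tx(n), n) -= 1.0; }
  dem /= (real_t)N; dtx /= (real_t)N;
  mat fcd = cc.fc_h % cc.fc_mask;
  g.em_w = dem * fcd.t(); g.em_b = arma::sum(dem, 1);
  g.tx_w = dtx * fcd.t(); g.tx_b = arma::sum(dtx, 1);
  mat dfcd = w.em_w.t() * dem + w.tx_w.t() * dtx;
  mat dfch = dfcd % cc.fc_mask;
  dfch.elem(arma::find(cc.fc_h == 0)).zeros();
  g.fc_w = dfch * cc.gap.t(); g.fc_b = arma::sum(dfch, 1);
  mat dgap = w.fc_w.t() * dfch;

  // back through FF / LN2 / attention / LN1 (pre-LN block)
  cube dffres(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) dffres.slice(t) = dgap / (real_t)Tp;

  // feed-forward branch
  g.ff1_w.zeros(cf.FF, cf.D); g.ff1_b.zeros(cf.FF);
  g.ff2_w.zeros(cf.D, cf.FF); g.ff2_b.zeros(cf.D);
  cube dz2(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat dout = dffres.slice(t);
    g.ff2_w += dout * cc.ff_h.slice(t).t();
    g.ff2_b += arma::sum(dout, 1);
    mat dh = w.ff2_w.t() * dout;
    dh.elem(arma::find(cc.ff_h.slice(t) == 0)).zeros();
    g.ff1_w += dh * cc.z2.slice(t).t();
    g.ff1_b += arma::sum(dh, 1);
    dz2.slice(t) = w.ff1_w.t() * dh;
  }
  // LN2 backward (input: attn_res); residual path adds dffres directly
  g.ln2_g.zeros(cf.D); g.ln2_b.zeros(cf.D);
  cube dattnres = dffres;
  for (int t = 0; t < Tp; ++t) {
    for (int n = 0; n < N; ++n) {
      vec dy = dz2.slice(t).col(n);
      real_t mu = cc.ln2_mu(n + (uword)N * t), sd = cc.ln2_sd(n + (uword)N * t);
      vec xc = cc.attn_res.slice(t).col(n);
      vec xh = (xc - mu) / sd;
      g.ln2_g += dy % xh; g.ln2_b += dy;
      vec dxh = dy % w.ln2_g;
      real_t m1 = arma::mean(dxh), m2 = arma::mean(dxh % xh);
      dattnres.slice(t).col(n) += (dxh - m1 - xh * m2) / sd;
    }
  }
  // attention output projection
  g.wo.zeros(cf.D, cf.D); g.bo.zeros(cf.D);
  cube dcat(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat dout = dattnres.slice(t);
    g.wo += dout * cc.attn_cat.slice(t).t();
    g.bo += arma::sum(dout, 1);
    dcat.slice(t) = w.wo.t() * dout;
  }
  cube dq(cf.D, N, Tp, arma::fill::zeros), dkc(cf.D, N, Tp, arma::fill::zeros),
       dv(cf.D, N, Tp, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat Q(cf.D, Tp), K(cf.D, Tp), V(cf.D, Tp), dO(cf.D, Tp);
    for (int t = 0; t < Tp; ++t) {
      Q.col(t) = cc.q.slice(t).col(n);
      K.col(t) = cc.k.slice(t).col(n);
      V.col(t) = cc.v.slice(t).col(n);
      dO.col(t) = dcat.slice(t).col(n);
    }
    for (int h = 0; h < cf.heads; ++h) {
      mat Qh = Q.rows(h * dk, (h + 1) * dk - 1);
      mat Kh = K.rows(h * dk, (h + 1) * dk - 1);
      mat Vh = V.rows(h * dk, (h + 1) * dk - 1);
      mat dOh = dO.rows(h * dk, (h + 1) * dk - 1);   // (dk, Tq)
      const mat& A = cc.attn_A[(size_t)n * cf.heads + h]; // (Tq, Tk)
      mat dVh = dOh * A;                              // (dk, Tk)
      // dA(qi, ki) = dOh(:,qi) . Vh(:,ki)
      mat dA = (Vh.t() * dOh).t();                    // (Tq, Tk)
      mat dS(Tp, Tp);
      for (int qi = 0; qi < Tp; ++qi) {
        rowvec a = A.row(qi);
        rowvec da = dA.row(qi);
        real_t dot = arma::dot(a, da);
        dS.row(qi) = a % (da - dot);
      }
      dS *= scale;
      mat dQh = Kh * dS.t();                          // (dk, Tq)
      mat dKh = Qh * dS;                              // (dk, Tk)
      for (int t = 0; t < Tp; ++t) {
        dq.slice(t).submat(h * dk, n, (h + 1) * dk - 1, n) += dQh.col(t);
        dkc.slice(t).submat(h * dk, n, (h + 1) * dk - 1, n) += dKh.col(t);
        dv.slice(t).submat(h * dk, n, (h + 1) * dk - 1, n) += dVh.col(t);
      }
    }
  }
  g.wq.zeros(cf.D, cf.D); g.bq.zeros(cf.D);
  g.wk.zeros(cf.D, cf.D); g.bk.zeros(cf.D);
  g.wv.zeros(cf.D, cf.D); g.bv.zeros(cf.D);
  cube dz1(cf.D, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    mat zt = cc.z1.slice(t);
    g.wq += dq.slice(t) * zt.t(); g.bq += arma::sum(dq.slice(t), 1);
    g.wk += dkc.slice(t) * zt.t(); g.bk += arma::sum(dkc.slice(t), 1);
    g.wv += dv.slice(t) * zt.t(); g.bv += arma::sum(dv.slice(t), 1);
    dz1.slice(t) = w.wq.t() * dq.slice(t) + w.wk.t() * dkc.slice(t) +
      w.wv.t() * dv.slice(t);
  }
  // LN1 backward (input: z0); residual path adds dattnres directly
  g.ln1_g.zeros(cf.D); g.ln1_b.zeros(cf.D);
  cube dz0 = dattnres;
  for (int t = 0; t < Tp; ++t) {
    for (int n = 0; n < N; ++n) {
      vec dy = dz1.slice(t).col(n);
      real_t mu = cc.ln1_mu(n + (uword)N * t), sd = cc.ln1_sd(n + (uword)N * t);
      vec xc = cc.z0.slice(t).col(n);
      vec xh = (xc - mu) / sd;
      g.ln1_g += dy % xh; g.ln1_b += dy;
      vec dxh = dy % w.ln1_g;
      real_t m1 = arma::mean(dxh), m2 = arma::mean(dxh % xh);
      dz0.slice(t).col(n) += (dxh - m1 - xh * m2) / sd;
    }
  }

  // projection
  g.proj_w.zeros(cf.D, 2 * cf.H); g.proj_b.zeros(cf.D);
  cube dlstm2(2 * cf.H, N, Tp);
  for (int t = 0; t < Tp; ++t) {
    g.proj_w += dz0.slice(t) * cc.lstm_out[1].slice(t).t();
    g.proj_b += arma::sum(dz0.slice(t), 1);
    dlstm2.slice(t) = w.proj_w.t() * dz0.slice(t);
  }

  // LSTM layers backward (layer 2 then 1)
  cube dlayer_out = dlstm2;
  for (int l = 1; l >= 0; --l) {
    int Din = (l == 0) ? Ds : 2 * cf.H;
    cube dout = dlayer_out;
    dout %= cc.drop_mask[l];          // dropout backward
    cube din(Din, N, Tp, arma::fill::zeros);
    for (int d = 0; d < 2; ++d) {
      g.lstm_w[l][d].zeros(4 * cf.H, Din);
      g.lstm_u[l][d].zeros(4 * cf.H, cf.H);
      g.lstm_b[l][d].zeros(4 * cf.H);
      mat dh_next(cf.H, N, arma::fill::zeros);
      mat dc_next(cf.H, N, arma::fill::zeros);
      for (int step = Tp - 1; step >= 0; --step) {
        int t = (d == 0) ? step : (Tp - 1 - step);
        mat dh = dout.slice(t).rows(d * cf.H, (d + 1) * cf.H - 1) + dh_next;
        const mat& gall = cc.lstm_g[l][d].slice(t);
        mat ig = gall.rows(0, cf.H - 1);
        mat fg = gall.rows(cf.H, 2 * cf.H - 1);
        mat gg = gall.rows(2 * cf.H, 3 * cf.H - 1);
        mat og = gall.rows(3 * cf.H, 4 * cf.H - 1);
        mat ct = cc.lstm_c[l][d].slice(t);
        mat tc = arma::tanh(ct);
        mat dc = dh % og % (1.0 - tc % tc) + dc_next;
        // previous cell state
        mat c_prev(cf.H, N, arma::fill::zeros);
        int t_prev = (d == 0) ? t - 1 : t + 1;
        bool has_prev = (d == 0) ? (t > 0) : (t < Tp - 1);
        if (has_prev) c_prev = cc.lstm_c[l][d].slice(t_prev);
        mat dog = dh % tc % og % (1.0 - og);
        mat dig = dc % gg % ig % (1.0 - ig);
        mat dfg = dc % c_prev % fg % (1.0 - fg);
        mat dgg = dc % ig % (1.0 - gg % gg);
        mat dz(4 * cf.H, N);
        dz.rows(0, cf.H - 1) = dig;
        dz.rows(cf.H, 2 * cf.H - 1) = dfg;
        dz.rows(2 * cf.H, 3 * cf.H - 1) = dgg;
        dz.rows(3 * cf.H, 4 * cf.H - 1) = dog;
        mat xt(Din, N);
        for (int n = 0; n < N; ++n) xt.col(n) = cc.seq_in[l].slice(t).col(n);
        g.lstm_w[l][d] += dz * xt.t();
        g.lstm_b[l][d] += arma::sum(dz, 1);
        mat h_prev(cf.H, N, arma::fill::zeros);
        if (has_prev) h_prev = cc.lstm_h[l][d].slice(t_prev);
        g.lstm_u[l][d] += dz * h_prev.t();
        din.slice(t) += w.lstm_w[l][d].t() * dz;
        dh_next = w.lstm_u[l][d].t() * dz;
        dc_next = dc % fg;
      }
    }
    dlayer_out = din;   // for layer 0 this is d(seq_in[0])
  }

  // sequence -> pooled map gradient
  cube dp2(cf.C2, cf.F4() * cf.T4(), N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < Tp; ++t)
      for (int f = 0; f < cf.F4(); ++f)
        for (int c = 0; c < cf.C2; ++c)
          dp2(c, f + cf.F4() * t, n) = dlayer_out(c + cf.C2 * f, n, t);

  // unpool 2 -> BN2/ReLU -> conv2 -> unpool 1 -> BN1/ReLU -> conv1
  cube dr2(cf.C2, cf.F2() * cf.T2(), N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cf.C2; ++c)
      for (uword s = 0; s < (uword)(cf.F4() * cf.T4()); ++s)
        dr2(c, cc.pool2_idx(c, s, n), n) += dp2(c, s, n);
  // ReLU + BN2 backward
  g.bn2_g.zeros(cf.C2); g.bn2_b.zeros(cf.C2);
  cube da2(cf.C2, cf.F2() * cf.T2(), N);
  {
    real_t M = (real_t)N * cf.F2() * cf.T2();
    vec inv2 = 1.0 / arma::sqrt(cc.bn2_var + cf.bn_eps);
    const uword S = (uword)cf.F2() * cf.T2();
    const int C = cf.C2;
    // fused ReLU-mask + statistics pass, then the normalized gradient
    for (int n = 0; n < N; ++n) {
      const real_t* a = cc.a2.slice(n).memptr();
      const real_t* r = cc.r2.slice(n).memptr();
      real_t* dy = dr2.slice(n).memptr();
      for (uword s = 0; s < S; ++s) {
        for (int c = 0; c < C; ++c) {
          uword i = c + (uword)C * s;
          real_t d = (r[i] > 0) ? dy[i] : 0.0;
          dy[i] = d;
          g.bn2_g(c) += d * (a[i] - cc.bn2_mu(c)) * inv2(c);
          g.bn2_b(c) += d;
        }
      }
    }
    vec m1 = g.bn2_b / M, m2 = g.bn2_g / M;
    vec gi2 = w.bn2_g % inv2;
    for (int n = 0; n < N; ++n) {
      const real_t* a = cc.a2.slice(n).memptr();
      const real_t* dy = dr2.slice(n).memptr();
      real_t* da = da2.slice(n).memptr();
      for (uword s = 0; s < S; ++s) {
        for (int c = 0; c < C; ++c) {
          uword i = c + (uword)C * s;
          real_t xh = (a[i] - cc.bn2_mu(c)) * inv2(c);
          da[i] = (dy[i] - m1(c) - xh * m2(c)) * gi2(c);
        }
      }
    }
  }
  g.conv2_w.zeros(cf.C2, cf.C1 * 9); g.conv2_b.zeros(cf.C2);
  cube dp1(cf.C1, cf.F2() * cf.T2(), N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat col2 = im2col3x3(cc.p1.slice(n), cf.C1, cf.F2(), cf.T2());
    g.conv2_w += da2.slice(n) * col2.t();
    g.conv2_b += arma::sum(da2.slice(n), 1);
    mat gcol = w.conv2_w.t() * da2.slice(n);
    mat gin(cf.C1, cf.F2() * cf.T2(), arma::fill::zeros);
    col2im3x3(gin, gcol, cf.C1, cf.F2(), cf.T2());
    dp1.slice(n) = gin;
  }
  cube dr1(cf.C1, cf.F * cf.T, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cf.C1; ++c)
      for (uword s = 0; s < (uword)(cf.F2() * cf.T2()); ++s)
        dr1(c, cc.pool1_idx(c, s, n), n) += dp1(c, s, n);
  g.bn1_g.zeros(cf.C1); g.bn1_b.zeros(cf.C1);
  cube da1(cf.C1, cf.F * cf.T, N);
  {
    real_t M = (real_t)N * cf.F * cf.T;
    vec inv1 = 1.0 / arma::sqrt(cc.bn1_var + cf.bn_eps);
    const uword S = (uword)cf.F * cf.T;
    const int C = cf.C1;
    for (int n = 0; n < N; ++n) {
      const real_t* a = cc.a1.slice(n).memptr();
      const real_t* r = cc.r1.slice(n).memptr();
      real_t* dy = dr1.slice(n).memptr();
      for (uword s = 0; s < S; ++s) {
        for (int c = 0; c < C; ++c) {
          uword i = c + (uword)C * s;
          real_t d = (r[i] > 0) ? dy[i] : 0.0;
          dy[i] = d;
          g.bn1_g(c) += d * (a[i] - cc.bn1_mu(c)) * inv1(c);
          g.bn1_b(c) += d;
        }
      }
    }
    vec m1 = g.bn1_b / M, m2 = g.bn1_g / M;
    vec gi1 = w.bn1_g % inv1;
    for (int n = 0; n < N; ++n) {
      const real_t* a = cc.a1.slice(n).memptr();
      const real_t* dy = dr1.slice(n).memptr();
      real_t* da = da1.slice(n).memptr();
      for (uword s = 0; s < S; ++s) {
        for (int c = 0; c < C; ++c) {
          uword i = c + (uword)C * s;
          real_t xh = (a[i] - cc.bn1_mu(c)) * inv1(c);
          da[i] = (dy[i] - m1(c) - xh * m2(c)) * gi1(c);
        }
      }
    }
  }
  g.conv1_w.zeros(cf.C1, 9); g.conv1_b.zeros(cf.C1);
  for (int n = 0; n < N; ++n) {
    g.conv1_w += da1.slice(n) * cc.col1[n].t();
    g.conv1_b += arma::sum(da1.slice(n), 1);
  }
}

// ---- R interface ---------------------------------------------------

static List grads_to_list(const Grads& g) {
  char buf[64];
  List out = List::create(
    _["conv1_w"] = g.conv1_w, _["conv1_b"] = g.conv1_b,
    _["bn1_gamma"] = g.bn1_g, _["bn1_beta"] = g.bn1_b,
    _["conv2_w"] = g.conv2_w, _["conv2_b"] = g.conv2_b,
    _["bn2_gamma"] = g.bn2_g, _["bn2_beta"] = g.bn2_b);
  for (int l = 0; l < 2; ++l) for (int d = 0; d < 2; ++d) {
    out[lstm_name("w", l, d, buf)] = g.lstm_w[l][d];
    out[lstm_name("u", l, d, buf)] = g.lstm_u[l][d];
    out[lstm_name("b", l, d, buf)] = g.lstm_b[l][d];
  }
  out["proj_w"] = g.proj_w; out["proj_b"] = g.proj_b;
  out["attn_wq"] = g.wq; out["attn_bq"] = g.bq;
  out["attn_wk"] = g.wk; out["attn_bk"] = g.bk;
  out["attn_wv"] = g.wv; out["attn_bv"] = g.bv;
  out["attn_wo"] = g.wo; out["attn_bo"] = g.bo;
  out["ln1_gamma"] = g.ln1_g; out["ln1_beta"] = g.ln1_b;
  out["ln2_gamma"] = g.ln2_g; out["ln2_beta"] = g.ln2_b;
  out["ff1_w"] = g.ff1_w; out["ff1_b"] = g.ff1_b;
  out["ff2_w"] = g.ff2_w; out["ff2_b"] = g.ff2_b;
  out["fc_w"] = g.fc_w; out["fc_b"] = g.fc_b;
  out["head_em_w"] = g.em_w; out["head_em_b"] = g.em_b;
  out["head_tx_w"] = g.tx_w; out["head_tx_b"] = g.tx_b;
  return out;
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
List nn_forward_cpp(List params, List config, arma::cube X_in, bool training,
                    double seed) {
  Config cf = read_config(config);
  Params w = read_params(params);
  if ((int)X_in.n_rows != cf.F || (int)X_in.n_cols != cf.T)
    stop("input must be (%d, %d, N); got (%d, %d, %d)", cf.F, cf.T,
         (int)X_in.n_rows, (int)X_in.n_cols, (int)X_in.n_slices);
  cube X = arma::conv_to<cube>::from(X_in);
  Cache cc;
  forward(w, cf, X, training, (uint64_t)seed, cc);
  return List::create(_["emotion_probs"] = cc.em_p,
                      _["text_probs"] = cc.tx_p);
}

// [[Rcpp::export(name = ".nn_loss_grad_cpp")]]
List nn_loss_grad_cpp(List params, List config, arma::cube X_in,
                      arma::ivec y_em, arma::ivec y_tx, double seed) {
  Config cf = read_config(config);
  Params w = read_params(params);
  const int N = X_in.n_slices;
  if ((int)y_em.n_elem != N || (int)y_tx.n_elem != N)
    stop("labels must match batch size");
  cube X = arma::conv_to<cube>::from(X_in);
  Cache cc;
  vec rm1, rv1, rm2, rv2;
  forward(w, cf, X, true, (uint64_t)seed, cc, &rm1, &rv1, &rm2, &rv2);
  double loss_em = 0, loss_tx = 0;
  for (int n = 0; n < N; ++n) {
    loss_em -= std::log(std::max((double)cc.em_p(y_em(n), n), 1e-12));
    loss_tx -= std::log(std::max((double)cc.tx_p(y_tx(n), n), 1e-12));
  }
  loss_em /= N; loss_tx /= N;
  Grads g;
  backward(w, cf, cc, y_em, y_tx, g);
  return List::create(
    _["loss"] = loss_em + loss_tx,
    _["loss_emotion"] = loss_em,
    _["loss_text"] = loss_tx,
    _["grads"] = grads_to_list(g),
    _["bn_running"] = List::create(
      _["bn1_run_mean"] = rm1, _["bn1_run_var"] = rv1,
      _["bn2_run_mean"] = rm2, _["bn2_run_var"] = rv2));
}
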