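// DL-ROM neural engine: convolutional autoencoder + deep feedforward network
// trained jointly with ADAM on the two-term per-example loss
//   L = wh/2 ||u - dec(dfnn(t,mu))||^2 + (1-wh)/2 ||enc(u) - dfnn(t,mu)||^2.
//
// Layout conventions (must match the R wrappers):
//  - images are column-major s x s, stored flattened as columns of length s^2;
//  - multi-channel feature maps are stored per sample as a single column with
//    channel-major blocks: entry (c*H*W + spatial) where spatial = i + j*H;
//  - convolutions use kernel k (odd), stride st, zero padding (k-1)/2, so the
//    output side is ceil(H/st); transposed convolutions are the exact adjoint
//    and double the side back.
// All randomness comes from one std::mt19937_64 seeded from R; training is
// single-threaded and bitwise reproducible for a fixed seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double elu(double x) { return x > 0 ? x : std::expm1(x); }
static inline double elu_grad_from_out(double y) { return y > 0 ? 1.0 : y + 1.0; }

static void elu_inplace(mat& A) {
  for (uword i = 0; i < A.n_elem; ++i) A[i] = elu(A[i]);
}
// dX = dY .* f'(x) where Y = elu(X) is the stored activated output
static void elu_backprop(const mat& Y, mat& dY) {
  for (uword i = 0; i < Y.n_elem; ++i) dY[i] *= elu_grad_from_out(Y[i]);
}

struct ConvGeom {
  int Hin, Win, Cin, Cout, k, stride, pad, Hout, Wout, P;
  std::vector<int> map;  // (k*k) x P spatial indices into Hin*Win, -1 = pad
  void build() {
    pad = (k - 1) / 2;
    Hout = (Hin + 2 * pad - k) / stride + 1;
    Wout = (Win + 2 * pad - k) / stride + 1;
    P = Hout * Wout;
    map.assign((size_t)k * k * P, -1);
    for (int oj = 0; oj < Wout; ++oj) {
      for (int oi = 0; oi < Hout; ++oi) {
        int q = oi + oj * Hout;
        int ii0 = oi * stride - pad, jj0 = oj * stride - pad;
        for (int dj = 0; dj < k; ++dj) {
          for (int di = 0; di < k; ++di) {
            int ii = ii0 + di, jj = jj0 + dj;
            if (ii >= 0 && ii < Hin && jj >= 0 && jj < Win)
              map[(size_t)(di + dj * k) + (size_t)q * k * k] = ii + jj * Hin;
          }
        }
      }
    }
  }
};

// gather: A is (Hin*Win*Cin) x B -> Xcol (Cin*k*k) x (P*B)
static mat im2col(const ConvGeom& g, const mat& A) {
  const int kk = g.k * g.k, HW = g.Hin * g.Win;
  const int B = A.n_cols;
  mat X(g.Cin * kk, (size_t)g.P * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* a = A.colptr(b);
    for (int q = 0; q < g.P; ++q) {
      double* xc = X.colptr((size_t)q + (size_t)g.P * b);
      const int* mp = &g.map[(size_t)q * kk];
      for (int c = 0; c < g.Cin; ++c) {
        const double* ac = a + (size_t)c * HW;
        double* xr = xc + (size_t)c * kk;
        for (int r = 0; r < kk; ++r) {
          int sp = mp[r];
          if (sp >= 0) xr[r] = ac[sp];
        }
      }
    }
  }
  return X;
}

// scatter-add adjoint of im2col: X (Cin*k*k) x (P*B) -> A (Hin*Win*Cin) x B
static mat col2im(const ConvGeom& g, const mat& X, int B) {
  const int kk = g.k * g.k, HW = g.Hin * g.Win;
  mat A(HW * g.Cin, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* a = A.colptr(b);
    for (int q = 0; q < g.P; ++q) {
      const double* xc = X.colptr((size_t)q + (size_t)g.P * b);
      const int* mp = &g.map[(size_t)q * kk];
      for (int c = 0; c < g.Cin; ++c) {
        double* ac = a + (size_t)c * HW;
        const double* xr = xc + (size_t)c * kk;
        for (int r = 0; r < kk; ++r) {
          int sp = mp[r];
          if (sp >= 0) ac[sp] += xr[r];
        }
      }
    }
  }
  return A;
}

// reorder conv output (Cout x P*B) -> (P*Cout) x B and add bias
static mat y_to_maps(const mat& Y, int Cout, int P, int B, const vec& bias) {
  mat A(P * Cout, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < Cout; ++c)
      for (int q = 0; q < P; ++q)
        A((size_t)c * P + q, b) = Y(c, (size_t)q + (size_t)P * b) + bias(c);
  return A;
}
static mat maps_to_y(const mat& A, int Cout, int P, int B) {
  mat Y(Cout, (size_t)P * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < Cout; ++c)
      for (int q = 0; q < P; ++q)
        Y(c, (size_t)q + (size_t)P * b) = A((size_t)c * P + q, b);
  return Y;
}

struct Param {
  mat W, mAdam, vAdam;
  void init(int r, int c) { W.zeros(r, c); mAdam.zeros(r, c); vAdam.zeros(r, c); }
};

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void step_begin() { ++t; }
  void update(Param& p, const mat& g) {
    p.mAdam = b1 * p.mAdam + (1 - b1) * g;
    p.vAdam = b2 * p.vAdam + (1 - b2) * square(g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    p.W -= lr * (p.mAdam / c1) / (sqrt(p.vAdam / c2) + eps);
  }
};

struct Model {
  int s, n, n_in;                  // image side, latent dim, dfnn input dim
  std::vector<int> channels;       // encoder conv channels
  int k, stride;
  std::vector<int> dfnn_hidden;
  std::vector<ConvGeom> geoms;     // one per conv level (encoder orientation)
  int top_feat;                    // channels.back() * P_top

  std::vector<Param> encW, encB;   // conv weights (Cout x Cin*k*k), biases
  Param encDW, encDB;              // dense to latent
  Param decDW, decDB;              // latent to top feature map
  std::vector<Param> tcW, tcB;     // transposed conv (ordered top -> image)
  std::vector<Param> dfW, dfB;     // dfnn layers

  void build(int s_, int n_, int n_in_, const std::vector<int>& ch,
             int k_, int st_, const std::vector<int>& hidden) {
    s = s_; n = n_; n_in = n_in_; channels = ch; k = k_; stride = st_;
    dfnn_hidden = hidden;
    geoms.clear();
    int H = s, Cin = 1;
    for (size_t l = 0; l < ch.size(); ++l) {
      ConvGeom g; g.Hin = H; g.Win = H; g.Cin = Cin; g.Cout = ch[l];
      g.k = k; g.stride = st_; g.build();
      geoms.push_back(g);
      H = g.Hout; Cin = ch[l];
    }
    top_feat = channels.back() * geoms.back().P;

    encW.resize(ch.size()); encB.resize(ch.size());
    tcW.resize(ch.size()); tcB.resize(ch.size());
    for (size_t l = 0; l < ch.size(); ++l) {
      encW[l].init(geoms[l].Cout, geoms[l].Cin * k * k);
      encB[l].init(geoms[l].Cout, 1);
      // tconv level l runs geoms[l] backwards: weights (Cout_low x Cin_high*k*k)
      tcW[l].init(geoms[l].Cout, geoms[l].Cin * k * k);
      tcB[l].init(geoms[l].Cin, 1);
    }
    encDW.init(n, top_feat); encDB.init(n, 1);
    decDW.init(top_feat, n); decDB.init(top_feat, 1);

    std::vector<int> widths;
    widths.push_back(n_in);
    for (int h : hidden) widths.push_back(h);
    widths.push_back(n);
    dfW.resize(widths.size() - 1); dfB.resize(widths.size() - 1);
    for (size_t l = 0; l + 1 < widths.size(); ++l) {
      dfW[l].init(widths[l + 1], widths[l]);
      dfB[l].init(widths[l + 1], 1);
    }
  }

  std::vector<Param*> all_params() {
    std::vector<Param*> v;
    for (auto& p : encW) v.push_back(&p);
    for (auto& p : encB) v.push_back(&p);
    v.push_back(&encDW); v.push_back(&encDB);
    v.push_back(&decDW); v.push_back(&decDB);
    for (auto& p : tcW) v.push_back(&p);
    for (auto& p : tcB) v.push_back(&p);
    for (auto& p : dfW) v.push_back(&p);
    for (auto& p : dfB) v.push_back(&p);
    return v;
  }

  void init_weights(std::mt19937_64& rng) {
    auto glorot = [&](Param& p, double fan_in, double fan_out) {
      double lim = std::sqrt(6.0 / (fan_in + fan_out));
      std::uniform_real_distribution<double> U(-lim, lim);
      for (uword i = 0; i < p.W.n_elem; ++i) p.W[i] = U(rng);
    };
    for (size_t l = 0; l < encW.size(); ++l)
      glorot(encW[l], geoms[l].Cin * k * k, geoms[l].Cout * k * k);
    glorot(encDW, top_feat, n);
    glorot(decDW, n, top_feat);
    for (size_t l = 0; l < tcW.size(); ++l)
      glorot(tcW[l], geoms[l].Cout * k * k, geoms[l].Cin * k * k);
    for (auto& p : dfW) glorot(p, p.W.n_cols, p.W.n_rows);
    // biases stay zero
  }
};

// ---------------------------------------------------------------------------
// forward / backward passes (batch columns)

struct EncCache {
  std::vector<mat> act;   // activated output of each conv level
  std::vector<mat> xcol;  // im2col inputs per level
  mat top;                // flattened top features (pre-dense)
};

static mat enc_forward(Model& M, const mat& U, EncCache* cache) {
  int B = U.n_cols;
  mat A = U;
  if (cache) { cache->act.clear(); cache->xcol.clear(); }
  for (size_t l = 0; l < M.geoms.size(); ++l) {
    ConvGeom& g = M.geoms[l];
    mat X = im2col(g, A);
    mat Y = M.encW[l].W * X;
    A = y_to_maps(Y, g.Cout, g.P, B, M.encB[l].W.col(0));
    elu_inplace(A);
    if (cache) { cache->xcol.push_back(std::move(X)); cache->act.push_back(A); }
  }
  if (cache) cache->top = A;
  return M.encDW.W * A + repmat(M.encDB.W, 1, B);  // linear code
}

// returns gradient w.r.t. encoder input (unused) — we only need weight grads
static void enc_backward(Model& M, const mat& U, const EncCache& cache,
                         const mat& dCode,
                         std::vector<mat>& gW, std::vector<mat>& gB,
                         mat& gDW, mat& gDB) {
  int B = U.n_cols;
  gDW = dCode * cache.top.t();
  gDB = sum(dCode, 1);
  mat dA = M.encDW.W.t() * dCode;
  for (int l = (int)M.geoms.size() - 1; l >= 0; --l) {
    ConvGeom& g = M.geoms[l];
    elu_backprop(cache.act[l], dA);
    mat dY = maps_to_y(dA, g.Cout, g.P, B);
    gW[l] = dY * cache.xcol[l].t();
    vec db(g.Cout);
    for (int c = 0; c < g.Cout; ++c) db(c) = accu(dY.row(c));
    gB[l] = db;
    if (l > 0) {
      mat dX = M.encW[l].W.t() * dY;
      dA = col2im(g, dX, B);
    }
  }
}

struct DecCache {
  mat code;                // decoder input
  mat dense_act;           // ELU(decDW code + b)
  std::vector<mat> low;    // tconv level inputs (top -> image order)
  std::vector<mat> out;    // tconv outputs post-activation (except last: linear)
};

static mat dec_forward(Model& M, const mat& code, DecCache* cache) {
  int B = code.n_cols;
  mat A = M.decDW.W * code + repmat(M.decDB.W, 1, B);
  elu_inplace(A);
  if (cache) { cache->code = code; cache->dense_act = A; cache->low.clear(); cache->out.clear(); }
  for (int l = (int)M.geoms.size() - 1; l >= 0; --l) {
    ConvGeom& g = M.geoms[l];
    if (cache) cache->low.push_back(A);
    mat L = maps_to_y(A, g.Cout, g.P, B);         // low-res (Cout x P*B)
    mat T = M.tcW[l].W.t() * L;                   // (Cin*k*k) x (P*B)
    mat H = col2im(g, T, B);                      // (Hin*Win*Cin) x B
    // per-channel bias on the high-res output
    int HW = g.Hin * g.Win;
    for (int b = 0; b < B; ++b) {
      double* a = H.colptr(b);
      for (int c = 0; c < g.Cin; ++c) {
        double bc = M.tcB[l].W(c, 0);
        double* ac = a + (size_t)c * HW;
        for (int spp = 0; spp < HW; ++spp) ac[spp] += bc;
      }
    }
    if (l > 0) elu_inplace(H);                    // last level stays linear
    if (cache) cache->out.push_back(H);
    A = H;
  }
  return A;  // s*s x B
}

static mat dec_backward(Model& M, const DecCache& cache, const mat& dOut,
                        std::vector<mat>& gW, std::vector<mat>& gB,
                        mat& gDW, mat& gDB) {
  int B = dOut.n_cols;
  mat dH = dOut;
  int nl = (int)M.geoms.size();
  for (int pos = nl - 1; pos >= 0; --pos) {   // walk back: image -> top
    int l = nl - 1 - pos;                     // geom level of this tconv
    ConvGeom& g = M.geoms[l];
    if (l > 0) elu_backprop(cache.out[pos], dH);
    // bias grad: sum of dH per high-res channel
    int HW = g.Hin * g.Win;
    vec db(g.Cin, fill::zeros);
    for (int b = 0; b < B; ++b) {
      const double* a = dH.colptr(b);
      for (int c = 0; c < g.Cin; ++c) {
        double sc = 0;
        const double* ac = a + (size_t)c * HW;
        for (int spp = 0; spp < HW; ++spp) sc += ac[spp];
        db(c) += sc;
      }
    }
    gB[l] = db;
    mat dT = im2col(g, dH);                   // (Cin*k*k) x (P*B)
    mat L = maps_to_y(cache.low[pos], g.Cout, g.P, B);
    gW[l] = L * dT.t();                       // (Cout x Cin*k*k)
    mat dL = M.tcW[l].W * dT;                 // (Cout x P*B)
    dH = y_to_maps(dL, g.Cout, g.P, B, vec(g.Cout, fill::zeros));
  }
  // dH is now gradient w.r.t. dense_act
  elu_backprop(cache.dense_act, dH);
  gDW = dH * cache.code.t();
  gDB = sum(dH, 1);
  return M.decDW.W.t() * dH;  // gradient w.r.t. the latent code
}

struct DfnnCache { std::vector<mat> act; mat in; };

static mat dfnn_forward(Model& M, const mat& X, DfnnCache* cache) {
  mat A = X;
  if (cache) { cache->in = X; cache->act.clear(); }
  for (size_t l = 0; l < M.dfW.size(); ++l) {
    A = M.dfW[l].W * A + repmat(M.dfB[l].W, 1, A.n_cols);
    if (l + 1 < M.dfW.size()) elu_inplace(A);
    if (cache) cache->act.push_back(A);
  }
  return A;
}

static void dfnn_backward(Model& M, const DfnnCache& cache, const mat& dOut,
                          std::vector<mat>& gW, std::vector<mat>& gB) {
  mat dA = dOut;
  for (int l = (int)M.dfW.size() - 1; l >= 0; --l) {
    if (l + 1 < (int)M.dfW.size()) elu_backprop(cache.act[l], dA);
    const mat& input = (l == 0) ? cache.in : cache.act[l - 1];
    gW[l] = dA * input.t();
    gB[l] = sum(dA, 1);
    if (l > 0) dA = M.dfW[l].W.t() * dA;
  }
}

// ---------------------------------------------------------------------------
// model <-> R list plumbing

static Model model_from_arch(const Rcpp::List& arch) {
  std::vector<int> ch = Rcpp::as<std::vector<int>>(arch["conv_channels"]);
  std::vector<int> hidden = Rcpp::as<std::vector<int>>(arch["dfnn_hidden"]);
  Model M;
  M.build(Rcpp::as<int>(arch["image_side"]), Rcpp::as<int>(arch["n"]),
          Rcpp::as<int>(arch["n_mu"]) + 1, ch,
          Rcpp::as<int>(arch["kernel"]), Rcpp::as<int>(arch["stride"]), hidden);
  return M;
}

static Rcpp::List weights_to_list(Model& M) {
  Rcpp::List out;
  int L = (int)M.encW.size();
  for (int l = 0; l < L; ++l) {
    out["enc_conv_W" + std::to_string(l + 1)] = M.encW[l].W;
    out["enc_conv_b" + std::to_string(l + 1)] = M.encB[l].W;
  }
  out["enc_dense_W"] = M.encDW.W; out["enc_dense_b"] = M.encDB.W;
  out["dec_dense_W"] = M.decDW.W; out["dec_dense_b"] = M.decDB.W;
  for (int l = 0; l < L; ++l) {
    out["dec_tconv_W" + std::to_string(l + 1)] = M.tcW[l].W;
    out["dec_tconv_b" + std::to_string(l + 1)] = M.tcB[l].W;
  }
  for (size_t l = 0; l < M.dfW.size(); ++l) {
    out["df_W" + std::to_string(l + 1)] = M.dfW[l].W;
    out["df_b" + std::to_string(l + 1)] = M.dfB[l].W;
  }
  return out;
}

static void weights_from_list(Model& M, const Rcpp::List& w) {
  int L = (int)M.encW.size();
  for (int l = 0; l < L; ++l) {
    M.encW[l].W = Rcpp::as<mat>(w["enc_conv_W" + std::to_string(l + 1)]);
    M.encB[l].W = Rcpp::as<mat>(w["enc_conv_b" + std::to_string(l + 1)]);
  }
  M.encDW.W = Rcpp::as<mat>(w["enc_dense_W"]);
  M.encDB.W = Rcpp::as<mat>(w["enc_dense_b"]);
  M.decDW.W = Rcpp::as<mat>(w["dec_dense_W"]);
  M.decDB.W = Rcpp::as<mat>(w["dec_dense_b"]);
  for (int l = 0; l < L; ++l) {
    M.tcW[l].W = Rcpp::as<mat>(w["dec_tconv_W" + std::to_string(l + 1)]);
    M.tcB[l].W = Rcpp::as<mat>(w["dec_tconv_b" + std::to_string(l + 1)]);
  }
  for (size_t l = 0; l < M.dfW.size(); ++l) {
    M.dfW[l].W = Rcpp::as<mat>(w["df_W" + std::to_string(l + 1)]);
    M.dfB[l].W = Rcpp::as<mat>(w["df_b" + std::to_string(l + 1)]);
  }
}

// loss over a set of columns, forward only
static double eval_loss(Model& M, const mat& U, const mat& X, const vec& mask,
                        double wh, const uvec& cols, int chunk = 512) {
  double total = 0;
  for (uword start = 0; start < cols.n_elem; start += chunk) {
    uword end = std::min<uword>(start + chunk, cols.n_elem) - 1;
    uvec idx = cols.subvec(start, end);
    mat Ub = U.cols(idx), Xb = X.cols(idx);
    mat cEnc = enc_forward(M, Ub, nullptr);
    mat cDf = dfnn_forward(M, Xb, nullptr);
    mat Ur = dec_forward(M, cDf, nullptr);
    mat R = Ur - Ub; R.each_col() %= mask;
    double rec = accu(square(R));
    double code = accu(square(cEnc - cDf));
    total += 0.5 * wh * rec + 0.5 * (1 - wh) * code;
  }
  return total / cols.n_elem;
}

// [[Rcpp::export(name = ".dlrom_train_cpp")]]
Rcpp::List dlrom_train_cpp(const arma::mat& U, const arma::mat& X,
                           const arma::vec& mask, const Rcpp::List& arch,
                           const Rcpp::List& config) {
  Model M = model_from_arch(arch);
  const double lr = Rcpp::as<double>(config["learning_rate"]);
  const int batch = Rcpp::as<int>(config["batch_size"]);
  const int max_epochs = Rcpp::as<int>(config["max_epochs"]);
  const int patience = Rcpp::as<int>(config["patience"]);
  const double val_frac = Rcpp::as<double>(config["val_fraction"]);
  const double wh = Rcpp::as<double>(config["omega_h"]);
  const unsigned long seed = (unsigned long)Rcpp::as<double>(config["seed"]);
  const int Ns = U.n_cols;
  if ((int)X.n_cols != Ns) Rcpp::stop("U and X column counts differ");

  std::mt19937_64 rng(seed);
  M.init_weights(rng);

  // random sample-level train/validation split
  std::vector<int> perm(Ns);
  for (int i = 0; i < Ns; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  int n_val = std::max(1, (int)std::lround(val_frac * Ns));
  if (n_val >= Ns) Rcpp::stop("validation split leaves no training samples");
  uvec val_idx(n_val), tr_idx(Ns - n_val);
  for (int i = 0; i < n_val; ++i) val_idx(i) = perm[i];
  for (int i = n_val; i < Ns; ++i) tr_idx(i - n_val) = perm[i];

  Adam opt; opt.lr = lr;
  std::vector<Param*> params = M.all_params();
  int L = (int)M.geoms.size();

  std::vector<double> hist_train, hist_val;
  double best_val = datum::inf;
  int best_epoch = -1, stall = 0;
  Rcpp::List best_weights = weights_to_list(M);

  std::vector<int> order(tr_idx.n_elem);
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)tr_idx(i);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0;
    int n_batches = 0;
    for (size_t start = 0; start < order.size(); start += batch) {
      size_t end = std::min(order.size(), start + batch);
      int B = (int)(end - start);
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx(i) = order[start + i];
      mat Ub = U.cols(idx), Xb = X.cols(idx);

      EncCache ec; DfnnCache fc; DecCache dc;
      mat cEnc = enc_forward(M, Ub, &ec);
      mat cDf = dfnn_forward(M, Xb, &fc);
      mat Ur = dec_forward(M, cDf, &dc);

      mat R = Ur - Ub; R.each_col() %= mask;
      mat dCodeDiff = cEnc - cDf;
      double loss = (0.5 * wh * accu(square(R)) +
                     0.5 * (1 - wh) * accu(square(dCodeDiff))) / B;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite loss at epoch %d", epoch + 1);
      epoch_loss += loss; ++n_batches;

      mat dUr = (wh / B) * R; dUr.each_col() %= mask;
      mat dEnc = ((1 - wh) / B) * dCodeDiff;
      mat dDfDirect = -dEnc;

      std::vector<mat> gtW(L), gtB(L);
      mat gdDW, gdDB;
      mat dCode = dec_backward(M, dc, dUr, gtW, gtB, gdDW, gdDB);
      mat dDf = dCode + dDfDirect;

      std::vector<mat> geW(L), geB(L);
      mat geDW, geDB;
      enc_backward(M, Ub, ec, dEnc, geW, geB, geDW, geDB);

      std::vector<mat> gfW(M.dfW.size()), gfB(M.dfW.size());
      dfnn_backward(M, fc, dDf, gfW, gfB);

      opt.step_begin();
      for (int l = 0; l < L; ++l) { opt.update(M.encW[l], geW[l]); opt.update(M.encB[l], geB[l]); }
      opt.update(M.encDW, geDW); opt.update(M.encDB, geDB);
      opt.update(M.decDW, gdDW); opt.update(M.decDB, gdDB);
      for (int l = 0; l < L; ++l) { opt.update(M.tcW[l], gtW[l]); opt.update(M.tcB[l], gtB[l]); }
      for (size_t l = 0; l < M.dfW.size(); ++l) { opt.update(M.dfW[l], gfW[l]); opt.update(M.dfB[l], gfB[l]); }
    }
    double train_loss = epoch_loss / n_batches;
    double val_loss = eval_loss(M, U, X, mask, wh, val_idx);
    hist_train.push_back(train_loss);
    hist_val.push_back(val_loss);

    if (val_loss < best_val) {
      best_val = val_loss;
      best_epoch = epoch;
      best_weights = weights_to_list(M);
      stall = 0;
    } else if (++stall >= patience) break;

    if ((epoch & 7) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = best_weights,
    Rcpp::Named("train_loss") = hist_train,
    Rcpp::Named("val_loss") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch + 1,
    Rcpp::Named("best_val_loss") = best_val,
    Rcpp::Named("n_val") = n_val,
    Rcpp::Named("val_idx") = val_idx + 1);  // 1-based for R
}

// evaluate decoder(dfnn(t, mu)): the online DL-ROM query path (no encoder)
// [[Rcpp::export(name = ".dlrom_predict_cpp")]]
arma::mat dlrom_predict_cpp(const Rcpp::List& arch, const Rcpp::List& weights,
                            const arma::mat& X) {
  Model M = model_from_arch(arch);
  weights_from_list(M, weights);
  mat code = dfnn_forward(M, X, nullptr);
  return dec_forward(M, code, nullptr);
}

// [[Rcpp::export(name = ".dlrom_encode_cpp")]]
arma::mat dlrom_encode_cpp(const Rcpp::List& arch, const Rcpp::List& weights,
                           const arma::mat& U) {
  Model M = model_from_arch(arch);
  weights_from_list(M, weights);
  return enc_forward(M, U, nullptr);
}

// [[Rcpp::export(name = ".dlrom_dfnn_cpp")]]
arma::mat dlrom_dfnn_cpp(const Rcpp::List& arch, const Rcpp::List& weights,
                         const arma::mat& X) {
  Model M = model_from_arch(arch);
  weights_from_list(M, weights);
  return dfnn_forward(M, X, nullptr);
}
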