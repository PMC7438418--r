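// Slice-wise semantic segmentation engine: U-net / residual U-net with batch
// normalisation after every convolution, trained with SGD + momentum on
// softmax cross-entropy. Single precision throughout; convolutions are
// im2col + sgemm. Feature maps are stored per sample as (C, H*W) matrices
// with the spatial index p = h + H*w (column-major images, h fastest), which
// matches how R matrices arrive.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Ten {
  int C = 0, H = 0, W = 0;
  std::vector<fmat> s; // one (C, H*W) matrix per sample
  int N() const { return (int)s.size(); }
  void zeros_like(const Ten& o) {
    C = o.C; H = o.H; W = o.W;
    s.assign(o.s.size(), fmat(o.C, o.H * o.W, arma::fill::zeros));
  }
};

static double rnorm01() { return norm_rand(); } // R's RNG: seeding via set.seed()

// ---------------------------------------------------------------------------
// layers
// ---------------------------------------------------------------------------

struct Param {
  fmat w, v; // value and momentum buffer
  void init(int r, int c, double sd) {
    w.set_size(r, c);
    if (sd > 0) {
      for (arma::uword i = 0; i < w.n_elem; ++i) w[i] = (float)(rnorm01() * sd);
    } else {
      w.zeros();
    }
    v.zeros(r, c);
  }
};

// 3x3 convolution, stride 1, zero padding 1 (or 1x1 when k == 1).
struct Conv {
  int Cin = 0, Cout = 0, k = 3;
  Param W, b; // W: (Cout, k*k*Cin), row block t*Cin + c for offset t
  Ten in;     // stored input (for dW and col recomputation)

  void build(int cin, int cout, int kk) {
    Cin = cin; Cout = cout; k = kk;
    double sd = std::sqrt(2.0 / (double)(k * k * cin));
    W.init(cout, k * k * cin, sd);
    b.init(cout, 1, 0.0);
  }

  void im2col(const fmat& x, int H, int Wd, fmat& col) const {
    col.set_size(9 * Cin, H * Wd);
    const float* xp = x.memptr();
    float* cp = col.memptr();
    const int HW = H * Wd, rows = 9 * Cin;
    for (int t = 0; t < 9; ++t) {
      int dy = t % 3 - 1, dx = t / 3 - 1;
      for (int w = 0; w < Wd; ++w) {
        int ws = w + dx;
        for (int h = 0; h < H; ++h) {
          int hs = h + dy;
          float* dst = cp + (size_t)(h + H * w) * rows + t * Cin;
          if (hs < 0 || hs >= H || ws < 0 || ws >= Wd) {
            std::memset(dst, 0, sizeof(float) * Cin);
          } else {
            const float* src = xp + (size_t)(hs + H * ws) * Cin;
            std::memcpy(dst, src, sizeof(float) * Cin);
          }
        }
      }
    }
  }

  // NOTE: feature matrices are (C, H*W); for im2col we need channel-major
  // contiguity per pixel, i.e. column (h + H*w) of x — which is exactly a
  // column of the (C, HW) matrix. Offsets shift the pixel index.
  Ten forward(const Ten& x, bool keep) {
    if (keep) in = x;
    Ten y; y.C = Cout; y.H = x.H; y.W = x.W; y.s.resize(x.N());
    if (k == 1) {
      for (int n = 0; n < x.N(); ++n) {
        y.s[n] = W.w * x.s[n];
        y.s[n].each_col() += b.w.col(0);
      }
      return y;
    }
    fmat col;
    for (int n = 0; n < x.N(); ++n) {
      im2col(x.s[n], x.H, x.W, col);
      y.s[n] = W.w * col;
      y.s[n].each_col() += b.w.col(0);
    }
    return y;
  }

  Ten backward(const Ten& dy) {
    Ten dx; dx.C = Cin; dx.H = dy.H; dx.W = dy.W; dx.s.resize(dy.N());
    fmat dW(W.w.n_rows, W.w.n_cols, arma::fill::zeros);
    fvec db(Cout, arma::fill::zeros);
    if (k == 1) {
      for (int n = 0; n < dy.N(); ++n) {
        dW += dy.s[n] * in.s[n].t();
        db += arma::sum(dy.s[n], 1);
        dx.s[n] = W.w.t() * dy.s[n];
      }
    } else {
      fmat col, dcol;
      const int H = dy.H, Wd = dy.W, rows = 9 * Cin;
      for (int n = 0; n < dy.N(); ++n) {
        im2col(in.s[n], H, Wd, col);
        dW += dy.s[n] * col.t();
        db += arma::sum(dy.s[n], 1);
        dcol = W.w.t() * dy.s[n]; // (9*Cin, HW)
        fmat& dxm = dx.s[n];
        dxm.zeros(Cin, H * Wd);
        const float* dp = dcol.memptr();
        float* xp = dxm.memptr();
        for (int t = 0; t < 9; ++t) {
          int dyo = t % 3 - 1, dxo = t / 3 - 1;
          for (int w = 0; w < Wd; ++w) {
            int ws = w + dxo;
            if (ws < 0 || ws >= Wd) continue;
            for (int h = 0; h < H; ++h) {
              int hs = h + dyo;
              if (hs < 0 || hs >= H) continue;
              const float* src = dp + (size_t)(h + H * w) * rows + t * Cin;
              float* dst = xp + (size_t)(hs + H * ws) * Cin;
              for (int c = 0; c < Cin; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
    gW = dW; gb = db;
    in.s.clear();
    return dx;
  }

  fmat gW; fvec gb;
};

struct BatchNorm {
  int C = 0;
  Param gamma, beta;
  fvec run_mean, run_var;
  float eps = 1e-5f, mom = 0.1f;
  Ten xhat; fvec invstd;
  fvec dgamma, dbeta;

  void build(int c) {
    C = c;
    gamma.init(c, 1, 0.0); gamma.w.ones();
    beta.init(c, 1, 0.0);
    run_mean.zeros(c); run_var.ones(c);
  }

  Ten forward(const Ten& x, bool train) {
    Ten y; y.C = x.C; y.H = x.H; y.W = x.W; y.s.resize(x.N());
    if (train) {
      const double cnt = (double)x.N() * x.H * x.W;
      fvec mu(C, arma::fill::zeros), m2(C, arma::fill::zeros);
      for (int n = 0; n < x.N(); ++n) mu += arma::sum(x.s[n], 1);
      mu /= (float)cnt;
      for (int n = 0; n < x.N(); ++n) {
        fmat c = x.s[n]; c.each_col() -= mu;
        m2 += arma::sum(arma::square(c), 1);
      }
      fvec var = m2 / (float)cnt;
      invstd = 1.0f / arma::sqrt(var + eps);
      run_mean = (1 - mom) * run_mean + mom * mu;
      run_var = (1 - mom) * run_var + mom * var;
      xhat.C = x.C; xhat.H = x.H; xhat.W = x.W; xhat.s.resize(x.N());
      for (int n = 0; n < x.N(); ++n) {
        fmat c = x.s[n]; c.each_col() -= mu; c.each_col() %= invstd;
        xhat.s[n] = c;
        c.each_col() %= gamma.w.col(0); c.each_col() += beta.w.col(0);
        y.s[n] = std::move(c);
      }
    } else {
      fvec is = 1.0f / arma::sqrt(run_var + eps);
      for (int n = 0; n < x.N(); ++n) {
        fmat c = x.s[n]; c.each_col() -= run_mean; c.each_col() %= is;
        c.each_col() %= gamma.w.col(0); c.each_col() += beta.w.col(0);
        y.s[n] = std::move(c);
      }
    }
    return y;
  }

  Ten backward(const Ten& dy) {
    const double cnt = (double)dy.N() * dy.H * dy.W;
    dgamma.zeros(C); dbeta.zeros(C);
    for (int n = 0; n < dy.N(); ++n) {
      dgamma += arma::sum(dy.s[n] % xhat.s[n], 1);
      dbeta += arma::sum(dy.s[n], 1);
    }
    Ten dx; dx.C = dy.C; dx.H = dy.H; dx.W = dy.W; dx.s.resize(dy.N());
    fvec coef = gamma.w.col(0) % invstd / (float)cnt;
    for (int n = 0; n < dy.N(); ++n) {
      fmat t = (float)cnt * dy.s[n];
      t.each_col() -= dbeta;
      t -= xhat.s[n] % arma::repmat(dgamma, 1, dy.H * dy.W);
      t.each_col() %= coef;
      dx.s[n] = std::move(t);
    }
    xhat.s.clear();
    return dx;
  }
};

struct ReLU {
  Ten out;
  Ten forward(const Ten& x, bool keep) {
    Ten y; y.C = x.C; y.H = x.H; y.W = x.W; y.s.resize(x.N());
    for (int n = 0; n < x.N(); ++n) y.s[n] = arma::clamp(x.s[n], 0.0f, arma::Datum<float>::inf);
    if (keep) out = y;
    return y;
  }
  Ten backward(const Ten& dy) {
    Ten dx; dx.C = dy.C; dx.H = dy.H; dx.W = dy.W; dx.s.resize(dy.N());
    for (int n = 0; n < dy.N(); ++n)
      dx.s[n] = dy.s[n] % arma::conv_to<fmat>::from(out.s[n] > 0.0f);
    out.s.clear();
    return dx;
  }
};

struct MaxPool2 {
  std::vector<arma::umat> arg; // per sample: (C, HW/4) argmax source index
  int Hin = 0, Win = 0;
  Ten forward(const Ten& x) {
    Hin = x.H; Win = x.W;
    const int Ho = x.H / 2, Wo = x.W / 2;
    Ten y; y.C = x.C; y.H = Ho; y.W = Wo; y.s.resize(x.N());
    arg.assign(x.N(), arma::umat(x.C, Ho * Wo));
    for (int n = 0; n < x.N(); ++n) {
      const fmat& xm = x.s[n];
      fmat& ym = y.s[n]; ym.set_size(x.C, Ho * Wo);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int p00 = 2 * h + x.H * (2 * w), p10 = p00 + 1;
          int p01 = p00 + x.H, p11 = p01 + 1;
          int po = h + Ho * w;
          for (int c = 0; c < x.C; ++c) {
            float v = xm(c, p00); int a = p00;
            if (xm(c, p10) > v) { v = xm(c, p10); a = p10; }
            if (xm(c, p01) > v) { v = xm(c, p01); a = p01; }
            if (xm(c, p11) > v) { v = xm(c, p11); a = p11; }
            ym(c, po) = v; arg[n](c, po) = a;
          }
        }
    }
    return y;
  }
  Ten backward(const Ten& dy) {
    Ten dx; dx.C = dy.C; dx.H = Hin; dx.W = Win;
    dx.s.assign(dy.N(), fmat(dy.C, Hin * Win, arma::fill::zeros));
    for (int n = 0; n < dy.N(); ++n)
      for (int p = 0; p < dy.H * dy.W; ++p)
        for (int c = 0; c < dy.C; ++c)
          dx.s[n](c, arg[n](c, p)) += dy.s[n](c, p);
    arg.clear();
    return dx;
  }
};

// 2x2 transposed convolution with stride 2 (learned up-sampling).
struct Up2 {
  int Cin = 0, Cout = 0;
  Param W[4], b; // one (Cout, Cin) weight per sub-pixel offset
  Ten in;
  void build(int cin, int cout) {
    Cin = cin; Cout = cout;
    double sd = std::sqrt(2.0 / (double)cin);
    for (int t = 0; t < 4; ++t) W[t].init(cout, cin, sd);
    b.init(cout, 1, 0.0);
  }
  Ten forward(const Ten& x, bool keep) {
    if (keep) in = x;
    const int Ho = 2 * x.H, Wo = 2 * x.W;
    Ten y; y.C = Cout; y.H = Ho; y.W = Wo; y.s.resize(x.N());
    for (int n = 0; n < x.N(); ++n) {
      fmat& ym = y.s[n]; ym.set_size(Cout, Ho * Wo);
      for (int t = 0; t < 4; ++t) {
        int dy = t % 2, dx = t / 2;
        fmat part = W[t].w * x.s[n]; // (Cout, H*W)
        part.each_col() += b.w.col(0);
        for (int w = 0; w < x.W; ++w)
          for (int h = 0; h < x.H; ++h)
            ym.col((2 * h + dy) + Ho * (2 * w + dx)) = part.col(h + x.H * w);
      }
    }
    return y;
  }
  Ten backward(const Ten& dy) {
    const int Hi = dy.H / 2, Wi = dy.W / 2;
    Ten dx; dx.C = Cin; dx.H = Hi; dx.W = Wi;
    dx.s.assign(dy.N(), fmat(Cin, Hi * Wi, arma::fill::zeros));
    for (int t = 0; t < 4; ++t) gW[t].zeros(Cout, Cin);
    gb.zeros(Cout);
    fmat sub(dy.C, Hi * Wi);
    for (int n = 0; n < dy.N(); ++n) {
      for (int t = 0; t < 4; ++t) {
        int dyo = t % 2, dxo = t / 2;
        for (int w = 0; w < Wi; ++w)
          for (int h = 0; h < Hi; ++h)
            sub.col(h + Hi * w) = dy.s[n].col((2 * h + dyo) + dy.H * (2 * w + dxo));
        gW[t] += sub * in.s[n].t();
        gb += arma::sum(sub, 1);
        dx.s[n] += W[t].w.t() * sub;
      }
    }
    in.s.clear();
    return dx;
  }
  fmat gW[4]; fvec gb;
};

// conv -> BN -> ReLU -> conv -> BN (+ optional residual) -> ReLU
struct DoubleConv {
  Conv c1, c2, proj;
  BatchNorm b1, b2;
  ReLU r1, r2;
  bool residual = false, use_proj = false;
  Ten in; // kept only when residual without projection

  void build(int cin, int cout, bool res) {
    residual = res;
    c1.build(cin, cout, 3);
    b1.build(cout);
    c2.build(cout, cout, 3);
    b2.build(cout);
    if (res && cin != cout) { use_proj = true; proj.build(cin, cout, 1); }
  }
  Ten forward(const Ten& x, bool train) {
    Ten h = r1.forward(b1.forward(c1.forward(x, train), train), train);
    Ten y = b2.forward(c2.forward(h, train), train);
    if (residual) {
      Ten res = use_proj ? proj.forward(x, train) : x;
      for (int n = 0; n < y.N(); ++n) y.s[n] += res.s[n];
    }
    return r2.forward(y, train);
  }
  Ten backward(const Ten& dy) {
    Ten ds = r2.backward(dy);
    Ten dx = c1.backward(b1.backward(r1.backward(c2.backward(b2.backward(ds)))));
    if (residual) {
      if (use_proj) {
        Ten dres = proj.backward(ds);
        for (int n = 0; n < dx.N(); ++n) dx.s[n] += dres.s[n];
      } else {
        for (int n = 0; n < dx.N(); ++n) dx.s[n] += ds.s[n];
      }
    }
    return dx;
  }
};

// ---------------------------------------------------------------------------
// network
// ---------------------------------------------------------------------------

struct UNet {
  std::string variant;
  int depth, base, classes, in_ch;
  std::vector<DoubleConv> enc;
  std::vector<MaxPool2> pool;
  DoubleConv bott;
  std::vector<Up2> up;       // index i up-samples into level i
  std::vector<DoubleConv> dec;
  Conv head;                 // 1x1 to class scores
  std::vector<Ten> skips;

  UNet(const std::string& var, int base_, int depth_, int classes_, int in_)
      : variant(var), depth(depth_), base(base_), classes(classes_), in_ch(in_) {
    bool res = (variant == "resunet");
    enc.resize(depth); pool.resize(depth); up.resize(depth); dec.resize(depth);
    int cin = in_ch;
    for (int i = 0; i < depth; ++i) {
      enc[i].build(cin, base << i, res);
      cin = base << i;
    }
    bott.build(base << (depth - 1), base << depth, res);
    for (int i = depth - 1; i >= 0; --i) {
      up[i].build(base << (i + 1), base << i);
      dec[i].build(2 * (base << i), base << i, res);
    }
    head.build(base, classes, 1);
  }

  Ten forward(const Ten& x0, bool train) {
    if (x0.H % (1 << depth) || x0.W % (1 << depth))
      stop("input spatial size must be divisible by 2^depth");
    skips.assign(depth, Ten());
    Ten x = x0;
    for (int i = 0; i < depth; ++i) {
      x = enc[i].forward(x, train);
      if (train) skips[i] = x; else skips[i] = x; // skips needed in both modes
      x = pool[i].forward(x);
    }
    x = bott.forward(x, train);
    for (int i = depth - 1; i >= 0; --i) {
      Ten u = up[i].forward(x, train);
      Ten cat; cat.C = u.C + skips[i].C; cat.H = u.H; cat.W = u.W; cat.s.resize(u.N());
      for (int n = 0; n < u.N(); ++n) cat.s[n] = arma::join_cols(u.s[n], skips[i].s[n]);
      if (!train) skips[i].s.clear();
      x = dec[i].forward(cat, train);
    }
    return head.forward(x, train);
  }

  void backward(const Ten& dlogits) {
    Ten d = head.backward(dlogits);
    std::vector<Ten> dskip(depth);
    for (int i = 0; i < depth; ++i) {
      Ten dcat = dec[i].backward(d);
      // split: first up[i].Cout rows belong to the up-sampled path
      int cu = up[i].Cout;
      Ten du; du.C = cu; du.H = dcat.H; du.W = dcat.W; du.s.resize(dcat.N());
      dskip[i].C = dcat.C - cu; dskip[i].H = dcat.H; dskip[i].W = dcat.W;
      dskip[i].s.resize(dcat.N());
      for (int n = 0; n < dcat.N(); ++n) {
        du.s[n] = dcat.s[n].rows(0, cu - 1);
        dskip[i].s[n] = dcat.s[n].rows(cu, dcat.C - 1);
      }
      d = up[i].backward(du);
    }
    d = bott.backward(d);
    for (int i = depth - 1; i >= 0; --i) {
      d = pool[i].backward(d);
      for (int n = 0; n < d.N(); ++n) d.s[n] += dskip[i].s[n];
      d = enc[i].backward(d);
    }
    skips.clear();
  }

  // parameter/gradient bookkeeping -----------------------------------------
  void collect(std::vector<Param*>& ps, std::vector<fmat>& gs) {
    auto addc = [&](Conv& c) {
      ps.push_back(&c.W); gs.push_back(c.gW);
      ps.push_back(&c.b); gs.push_back(fmat(c.gb));
    };
    auto addb = [&](BatchNorm& b) {
      ps.push_back(&b.gamma); gs.push_back(fmat(b.dgamma));
      ps.push_back(&b.beta); gs.push_back(fmat(b.dbeta));
    };
    auto addd = [&](DoubleConv& d) {
      addc(d.c1); addb(d.b1); addc(d.c2); addb(d.b2);
      if (d.use_proj) addc(d.proj);
    };
    for (int i = 0; i < depth; ++i) addd(enc[i]);
    addd(bott);
    for (int i = depth - 1; i >= 0; --i) {
      for (int t = 0; t < 4; ++t) { ps.push_back(&up[i].W[t]); gs.push_back(up[i].gW[t]); }
      ps.push_back(&up[i].b); gs.push_back(fmat(up[i].gb));
      addd(dec[i]);
    }
    addc(head);
  }

  void sgd_step(double lr, double momentum) {
    std::vector<Param*> ps; std::vector<fmat> gs;
    collect(ps, gs);
    for (size_t i = 0; i < ps.size(); ++i) {
      ps[i]->v = (float)momentum * ps[i]->v - (float)lr * gs[i];
      ps[i]->w += ps[i]->v;
    }
  }

  void params_only(std::vector<Param*>& ps) {
    std::vector<fmat> gs_unused;
    // gradients may be empty outside a backward pass; collect() copies them
    // but we only use the parameter pointers here
    auto addc = [&](Conv& c) { ps.push_back(&c.W); ps.push_back(&c.b); };
    auto addb = [&](BatchNorm& b) { ps.push_back(&b.gamma); ps.push_back(&b.beta); };
    auto addd = [&](DoubleConv& d) {
      addc(d.c1); addb(d.b1); addc(d.c2); addb(d.b2);
      if (d.use_proj) addc(d.proj);
    };
    for (int i = 0; i < depth; ++i) addd(enc[i]);
    addd(bott);
    for (int i = depth - 1; i >= 0; --i) {
      for (int t = 0; t < 4; ++t) ps.push_back(&up[i].W[t]);
      ps.push_back(&up[i].b);
      addd(dec[i]);
    }
    addc(head);
  }

  void bn_list(std::vector<BatchNorm*>& bs) {
    auto addd = [&](DoubleConv& d) { bs.push_back(&d.b1); bs.push_back(&d.b2); };
    for (int i = 0; i < depth; ++i) addd(enc[i]);
    addd(bott);
    for (int i = depth - 1; i >= 0; --i) addd(dec[i]);
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static Ten tensor_from_r(const NumericVector& images, int in_ch) {
  IntegerVector d = images.attr("dim");
  if (d.size() != 3) stop("images must be an (H, W, N) array");
  int H = d[0], W = d[1], N = d[2];
  if (in_ch != 1) stop("only single-channel input supported");
  Ten x; x.C = 1; x.H = H; x.W = W; x.s.resize(N);
  const double* p = images.begin();
  for (int n = 0; n < N; ++n) {
    fmat m(1, H * W);
    const double* src = p + (size_t)n * H * W;
    for (int i = 0; i < H * W; ++i) m[i] = (float)src[i];
    x.s[n] = std::move(m);
  }
  return x;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(std::string variant, int base, int depth, int num_classes,
                int in_channels) {
  if (variant != "unet" && variant != "resunet") stop("unknown variant");
  GetRNGstate();
  UNet* net = new UNet(variant, base, depth, num_classes, in_channels);
  PutRNGstate();
  XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export(name = ".net_nparams")]]
double net_nparams(SEXP handle) {
  XPtr<UNet> net(handle);
  std::vector<Param*> ps;
  net->params_only(ps);
  double n = 0;
  for (auto* p : ps) n += (double)p->w.n_elem;
  return n;
}

// [[Rcpp::export(name = ".net_train_batch")]]
double net_train_batch(SEXP handle, NumericVector images, IntegerVector labels,
                       double lr, double momentum) {
  XPtr<UNet> net(handle);
  Ten x = tensor_from_r(images, net->in_ch);
  IntegerVector ld = labels.attr("dim");
  if (ld.size() != 3 || ld[0] != x.H || ld[1] != x.W || ld[2] != x.N())
    stop("labels must match images in shape");
  Ten logits = net->forward(x, true);
  const int K = net->classes, HW = x.H * x.W, N = x.N();
  double loss = 0;
  Ten dl; dl.C = K; dl.H = x.H; dl.W = x.W; dl.s.resize(N);
  const double scale = 1.0 / ((double)N * HW);
  const int* lp = labels.begin();
  for (int n = 0; n < N; ++n) {
    fmat& z = logits.s[n];
    fmat g(K, HW);
    for (int p = 0; p < HW; ++p) {
      int y = lp[(size_t)n * HW + p];
      if (y < 0 || y >= K) stop("label out of range");
      float mx = z.col(p).max();
      double den = 0;
      for (int k = 0; k < K; ++k) den += std::exp((double)z(k, p) - mx);
      double logden = std::log(den) + mx;
      loss += logden - z(y, p);
      for (int k = 0; k < K; ++k)
        g(k, p) = (float)((std::exp((double)z(k, p) - mx) / den - (k == y)) * scale);
    }
    dl.s[n] = std::move(g);
  }
  loss *= scale;
  net->backward(dl);
  net->sgd_step(lr, momentum);
  return loss;
}

// [[Rcpp::export(name = ".net_predict")]]
IntegerVector net_predict(SEXP handle, NumericVector images) {
  XPtr<UNet> net(handle);
  Ten x = tensor_from_r(images, net->in_ch);
  Ten logits = net->forward(x, false);
  const int HW = x.H * x.W, N = x.N(), K = net->classes;
  IntegerVector out((R_xlen_t)HW * N);
  for (int n = 0; n < N; ++n) {
    const fmat& z = logits.s[n];
    for (int p = 0; p < HW; ++p) {
      int best = 0;
      for (int k = 1; k < K; ++k) if (z(k, p) > z(best, p)) best = k;
      out[(size_t)n * HW + p] = best;
    }
  }
  out.attr("dim") = IntegerVector::create(x.H, x.W, N);
  return out;
}

// [[Rcpp::export(name = ".net_logits")]]
NumericVector net_logits(SEXP handle, NumericVector images, bool train) {
  XPtr<UNet> net(handle);
  Ten x = tensor_from_r(images, net->in_ch);
  Ten z = net->forward(x, train);
  const int HW = x.H * x.W, N = x.N(), K = net->classes;
  NumericVector out((R_xlen_t)HW * N * K);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k)
      for (int p = 0; p < HW; ++p)
        out[(size_t)p + (size_t)HW * (k + (size_t)K * n)] = z.s[n](k, p);
  out.attr("dim") = IntegerVector::create(x.H, x.W, K, N);
  return out;
}

// [[Rcpp::export(name = ".net_state")]]
List net_state(SEXP handle) {
  XPtr<UNet> net(handle);
  std::vector<Param*> ps;
  net->params_only(ps);
  List weights(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericVector v(ps[i]->w.n_elem);
    for (arma::uword j = 0; j < ps[i]->w.n_elem; ++j) v[j] = ps[i]->w[j];
    v.attr("dim") = IntegerVector::create(ps[i]->w.n_rows, ps[i]->w.n_cols);
    weights[i] = v;
  }
  std::vector<BatchNorm*> bs;
  net->bn_list(bs);
  List bn(bs.size());
  for (size_t i = 0; i < bs.size(); ++i) {
    NumericVector m(bs[i]->C), vv(bs[i]->C);
    for (int c = 0; c < bs[i]->C; ++c) { m[c] = bs[i]->run_mean[c]; vv[c] = bs[i]->run_var[c]; }
    bn[i] = List::create(_["mean"] = m, _["var"] = vv);
  }
  return List::create(
      _["variant"] = net->variant, _["base"] = net->base, _["depth"] = net->depth,
      _["classes"] = net->classes, _["in_channels"] = net->in_ch,
      _["weights"] = weights, _["bn"] = bn);
}

// [[Rcpp::export(name = ".net_load_state")]]
void net_load_state(SEXP handle, List state) {
  XPtr<UNet> net(handle);
  List weights = state["weights"];
  std::vector<Param*> ps;
  net->params_only(ps);
  if ((size_t)weights.size() != ps.size()) stop("checkpoint does not match architecture");
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericVector v = weights[i];
    if ((arma::uword)v.size() != ps[i]->w.n_elem) stop("checkpoint tensor size mismatch");
    for (arma::uword j = 0; j < ps[i]->w.n_elem; ++j) ps[i]->w[j] = (float)v[j];
    ps[i]->v.zeros();
  }
  List bn = state["bn"];
  std::vector<BatchNorm*> bs;
  net->bn_list(bs);
  if ((size_t)bn.size() != bs.size()) stop("checkpoint BN list mismatch");
  for (size_t i = 0; i < bs.size(); ++i) {
    List e = bn[i];
    NumericVector m = e["mean"], vv = e["var"];
    for (int c = 0; c < bs[i]->C; ++c) {
      bs[i]->run_mean[c] = (float)m[c];
      bs[i]->run_var[c] = (float)vv[c];
    }
  }
}
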