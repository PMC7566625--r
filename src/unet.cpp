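// Convolutional engine for the H&E-to-IF translator: a U-net generator with
// skip connections and a patch-based conditional discriminator, trained by
// Adam with manually derived backpropagation. Convolutions are im2col-based
// with one GEMM per layer per minibatch; single-threaded and
// bit-deterministic for a fixed seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
typedef std::vector<cube> Batch;

static void im2colInto(const cube& x, int k, int stride, int pad, int Ho,
                       int Wo, mat& col, int colOffset) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      double* cp = col.colptr(colOffset + oy + Ho * ox);
      int ry0 = oy * stride - pad, rx0 = ox * stride - pad;
      bool interiorY = (ry0 >= 0 && ry0 + k <= H);
      for (int c = 0; c < C; ++c) {
        const double* sl = x.slice_memptr(c);
        for (int kx = 0; kx < k; ++kx) {
          int rx = rx0 + kx;
          double* dst = cp + c * k * k + kx * k;
          if (rx < 0 || rx >= W) {
            std::memset(dst, 0, k * sizeof(double));
            continue;
          }
          const double* src = sl + (size_t)rx * H + ry0;
          if (interiorY) {
            std::memcpy(dst, src, k * sizeof(double));
          } else {
            for (int ky = 0; ky < k; ++ky) {
              int ry = ry0 + ky;
              dst[ky] = (ry >= 0 && ry < H) ? src[ky] : 0.0;
            }
          }
        }
      }
    }
  }
}

static cube col2im(const mat& dcol, int colOffset, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo) {
  cube dx(H, W, C, arma::fill::zeros);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const double* cp = dcol.colptr(colOffset + oy + Ho * ox);
      int ry0 = oy * stride - pad, rx0 = ox * stride - pad;
      bool interiorY = (ry0 >= 0 && ry0 + k <= H);
      for (int c = 0; c < C; ++c) {
        double* sl = dx.slice_memptr(c);
        for (int kx = 0; kx < k; ++kx) {
          int rx = rx0 + kx;
          if (rx < 0 || rx >= W) continue;
          double* dst = sl + (size_t)rx * H + ry0;
          const double* src = cp + c * k * k + kx * k;
          if (interiorY) {
            for (int ky = 0; ky < k; ++ky) dst[ky] += src[ky];
          } else {
            for (int ky = 0; ky < k; ++ky) {
              int ry = ry0 + ky;
              if (ry >= 0 && ry < H) dst[ky] += src[ky];
            }
          }
        }
      }
    }
  }
  return dx;
}

struct ConvLayer {
  int cin = 0, cout = 0, k = 0, stride = 1, pad = 0;
  mat W; vec b;
  mat mW, vW; vec mb, vb;           // Adam state
  mat colCache;                      // batched im2col matrix (persistent)
  mat outBuf, doutBuf, dcolBuf;      // persistent GEMM buffers
  int inH = 0, inW = 0, outH = 0, outW = 0, nBatch = 0;

  void init(int cin_, int cout_, int k_, int stride_, int pad_,
            std::mt19937_64& rng) {
    cin = cin_; cout = cout_; k = k_; stride = stride_; pad = pad_;
    std::normal_distribution<double> nd(0.0, 0.02);
    W.set_size(cout, k * k * cin);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(cout);
    mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    mb.zeros(cout); vb.zeros(cout);
  }
  Batch forward(const Batch& xs) {
    int n = xs.size();
    inH = xs[0].n_rows; inW = xs[0].n_cols; nBatch = n;
    outH = (inH + 2 * pad - k) / stride + 1;
    outW = (inW + 2 * pad - k) / stride + 1;
    int npos = outH * outW;
    colCache.set_size(k * k * cin, (size_t)npos * n);
    for (int i = 0; i < n; ++i)
      im2colInto(xs[i], k, stride, pad, outH, outW, colCache, i * npos);
    outBuf.set_size(cout, (size_t)npos * n);
    outBuf = W * colCache;
    outBuf.each_col() += b;
    Batch ys(n);
    for (int i = 0; i < n; ++i) {
      cube y(outH, outW, cout);
      for (int c = 0; c < cout; ++c) {
        // row c, columns [i*npos, (i+1)*npos) -> slice c
        for (int p = 0; p < npos; ++p)
          y.slice_memptr(c)[p] = outBuf(c, (size_t)i * npos + p);
      }
      ys[i] = std::move(y);
    }
    return ys;
  }
  // returns input gradients; accumulates nothing (grads applied directly)
  Batch backward(const Batch& dys, double lr, int t, bool update) {
    int n = dys.size();
    int npos = outH * outW;
    doutBuf.set_size(cout, (size_t)npos * n);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < cout; ++c)
        for (int p = 0; p < npos; ++p)
          doutBuf(c, (size_t)i * npos + p) = dys[i].slice_memptr(c)[p];
    mat Wt(W.t());                     // small; keeps the big GEMM plain A*B
    dcolBuf.set_size(k * k * cin, (size_t)npos * n);
    dcolBuf = Wt * doutBuf;
    if (update) {
      mat dW(cout, k * k * cin);
      dW = doutBuf * colCache.t();
      vec db = arma::sum(doutBuf, 1);
      adamStep(dW, db, lr, t);
    }
    Batch dxs(n);
    for (int i = 0; i < n; ++i)
      dxs[i] = col2im(dcolBuf, i * npos, inH, inW, cin, k, stride, pad,
                      outH, outW);
    return dxs;
  }
  void adamStep(const mat& dW, const vec& db, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mW = b1 * mW + (1 - b1) * dW;  vW = b2 * vW + (1 - b2) * (dW % dW);
    mb = b1 * mb + (1 - b1) * db;  vb = b2 * vb + (1 - b2) * (db % db);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    W -= lr * (mW / c1) / (arma::sqrt(vW / c2) + eps);
    b -= lr * (mb / c1) / (arma::sqrt(vb / c2) + eps);
  }
};


// Per-sample, per-channel instance normalization with learned gain/bias
// (conv-norm-activation blocks; the output head is norm-free).
struct InstNorm {
  int C = 0;
  vec gamma, beta;
  vec mg, vg, mb, vb;                // Adam state
  std::vector<cube> xhatC;           // cached normalized activations
  std::vector<mat> invstdC;          // (C x 1) per sample

  void init(int C_) {
    C = C_;
    gamma.ones(C); beta.zeros(C);
    mg.zeros(C); vg.zeros(C); mb.zeros(C); vb.zeros(C);
  }
  Batch forward(const Batch& xs) {
    int n = xs.size();
    xhatC.assign(n, cube());
    invstdC.assign(n, mat());
    Batch ys(n);
    for (int i = 0; i < n; ++i) {
      const cube& x = xs[i];
      int N = x.n_rows * x.n_cols;
      cube xhat(x.n_rows, x.n_cols, C);
      mat istd(C, 1);
      cube y(x.n_rows, x.n_cols, C);
      for (int c = 0; c < C; ++c) {
        double mu = arma::accu(x.slice(c)) / N;
        double var = arma::accu(arma::square(x.slice(c) - mu)) / N;
        double is = 1.0 / std::sqrt(var + 1e-5);
        istd(c, 0) = is;
        xhat.slice(c) = (x.slice(c) - mu) * is;
        y.slice(c) = gamma(c) * xhat.slice(c) + beta(c);
      }
      xhatC[i] = std::move(xhat);
      invstdC[i] = std::move(istd);
      ys[i] = std::move(y);
    }
    return ys;
  }
  Batch backward(const Batch& dys, double lr, int t, bool update) {
    int n = dys.size();
    vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
    Batch dxs(n);
    for (int i = 0; i < n; ++i) {
      const cube& xhat = xhatC[i];
      const cube& dy = dys[i];
      int N = dy.n_rows * dy.n_cols;
      cube dx(dy.n_rows, dy.n_cols, C);
      for (int c = 0; c < C; ++c) {
        double sdy = arma::accu(dy.slice(c));
        double sdyx = arma::accu(dy.slice(c) % xhat.slice(c));
        dgamma(c) += sdyx;
        dbeta(c) += sdy;
        // fused instance-norm input gradient
        dx.slice(c) = (gamma(c) * invstdC[i](c, 0) / N) *
          (N * dy.slice(c) - sdy - xhat.slice(c) * sdyx);
      }
      dxs[i] = std::move(dx);
    }
    if (update) adamStep(dgamma, dbeta, lr, t);
    return dxs;
  }
  void adamStep(const vec& dg, const vec& db, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mg = b1 * mg + (1 - b1) * dg;  vg = b2 * vg + (1 - b2) * (dg % dg);
    mb = b1 * mb + (1 - b1) * db;  vb = b2 * vb + (1 - b2) * (db % db);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    gamma -= lr * (mg / c1) / (arma::sqrt(vg / c2) + eps);
    beta  -= lr * (mb / c1) / (arma::sqrt(vb / c2) + eps);
  }
};

static Batch lreluB(const Batch& xs, double a) {
  Batch ys(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    ys[i] = xs[i];
    ys[i].transform([a](double v) { return v > 0 ? v : a * v; });
  }
  return ys;
}
static Batch lreluGradB(const Batch& post, const Batch& dys, double a) {
  Batch g(dys.size());
  for (size_t i = 0; i < dys.size(); ++i) {
    g[i] = dys[i];
    const cube& p = post[i];
    for (arma::uword e = 0; e < g[i].n_elem; ++e)
      if (p(e) <= 0) g[i](e) *= a;
  }
  return g;
}
static Batch sigmoidB(const Batch& xs) {
  Batch ys(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    ys[i] = xs[i];
    ys[i].transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  }
  return ys;
}
static cube upsample2(const cube& x) {
  cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (arma::uword s = 0; s < x.n_slices; ++s)
    for (arma::uword c = 0; c < x.n_cols; ++c)
      for (arma::uword r = 0; r < x.n_rows; ++r) {
        double v = x(r, c, s);
        y(2 * r, 2 * c, s) = v;     y(2 * r + 1, 2 * c, s) = v;
        y(2 * r, 2 * c + 1, s) = v; y(2 * r + 1, 2 * c + 1, s) = v;
      }
  return y;
}
static cube downsampleSum(const cube& g) {
  cube y(g.n_rows / 2, g.n_cols / 2, g.n_slices, arma::fill::zeros);
  for (arma::uword s = 0; s < g.n_slices; ++s)
    for (arma::uword c = 0; c < y.n_cols; ++c)
      for (arma::uword r = 0; r < y.n_rows; ++r)
        y(r, c, s) = g(2 * r, 2 * c, s) + g(2 * r + 1, 2 * c, s) +
                     g(2 * r, 2 * c + 1, s) + g(2 * r + 1, 2 * c + 1, s);
  return y;
}
static Batch upsample2B(const Batch& xs) {
  Batch ys(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) ys[i] = upsample2(xs[i]);
  return ys;
}
static Batch downsampleSumB(const Batch& xs) {
  Batch ys(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) ys[i] = downsampleSum(xs[i]);
  return ys;
}
static cube concatC(const cube& a, const cube& b) {
  cube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  y.slices(0, a.n_slices - 1) = a;
  y.slices(a.n_slices, y.n_slices - 1) = b;
  return y;
}

// U-net generator: depth stride-2 LeakyReLU down blocks (filters
// fl * min(2^i, 8)), mirrored nearest-upsample + 3x3 conv ReLU up blocks
// with skip concatenation, sigmoid 1-channel output head. depth is chosen
// so the bottleneck is 4x4 at the configured tile size.
struct UNetG {
  int tile = 0, fl = 0, depth = 0;
  std::vector<ConvLayer> down, up;
  std::vector<InstNorm> downN, upN;  // no norm on the first down block
  ConvLayer fin;
  // caches for the last forward batch
  std::vector<Batch> enc, ups;
  Batch out;

  static int chan(int fl, int i) { return fl * std::min(1 << i, 8); }

  void init(int tile_, int fl_, std::mt19937_64& rng) {
    tile = tile_; fl = fl_;
    depth = 0;
    for (int s = tile; s > 4; s /= 2) ++depth;   // bottleneck 4x4
    down.resize(depth); up.resize(depth - 1);
    downN.resize(depth); upN.resize(depth - 1);
    int cin = 3;
    for (int i = 0; i < depth; ++i) {
      down[i].init(cin, chan(fl, i), 4, 2, 1, rng);
      downN[i].init(chan(fl, i));
      cin = chan(fl, i);
    }
    int xc = chan(fl, depth - 1);
    for (int j = 0; j < depth - 1; ++j) {
      int oc = chan(fl, depth - 2 - j);
      up[j].init(xc, oc, 3, 1, 1, rng);
      upN[j].init(oc);
      xc = 2 * oc;                                // concat with skip
    }
    fin.init(xc, 1, 3, 1, 1, rng);
  }
  Batch forward(const Batch& xs) {
    int n = xs.size();
    enc.assign(depth, Batch());
    ups.assign(depth - 1, Batch());
    Batch cur = xs;
    for (int i = 0; i < depth; ++i) {
      cur = down[i].forward(cur);
      if (i > 0) cur = downN[i].forward(cur);
      cur = lreluB(cur, 0.2);
      enc[i] = cur;
    }
    Batch xj = enc[depth - 1];
    for (int j = 0; j < depth - 1; ++j) {
      Batch u = lreluB(upN[j].forward(up[j].forward(upsample2B(xj))), 0.0);
      ups[j] = u;
      Batch nx(n);
      for (int i = 0; i < n; ++i) nx[i] = concatC(u[i], enc[depth - 2 - j][i]);
      xj = std::move(nx);
    }
    out = sigmoidB(fin.forward(upsample2B(xj)));
    return out;
  }
  void backward(const Batch& dy, double lr, int t) {
    int n = dy.size();
    std::vector<Batch> dEnc(depth);
    for (int i = 0; i < depth; ++i) {
      dEnc[i].resize(n);
      for (int s = 0; s < n; ++s)
        dEnc[i][s].zeros(enc[i][s].n_rows, enc[i][s].n_cols,
                         enc[i][s].n_slices);
    }
    // sigmoid slope with a floor: guards the output head against
    // saturation death under sparse L1 targets
    Batch dpre(n);
    for (int i = 0; i < n; ++i) {
      cube slope = out[i] % (1.0 - out[i]);
      slope.transform([](double v) { return std::max(v, 0.05); });
      dpre[i] = dy[i] % slope;
    }
    Batch dxj = downsampleSumB(fin.backward(dpre, lr, t, true));
    for (int j = depth - 2; j >= 0; --j) {
      // dxj is the gradient of concat(ups[j], enc[depth-2-j])
      Batch du(n);
      for (int i = 0; i < n; ++i) {
        int cu = ups[j][i].n_slices;
        du[i] = dxj[i].slices(0, cu - 1);
        dEnc[depth - 2 - j][i] += dxj[i].slices(cu, dxj[i].n_slices - 1);
      }
      Batch dup = lreluGradB(ups[j], du, 0.0);
      dup = upN[j].backward(dup, lr, t, true);
      dxj = downsampleSumB(up[j].backward(dup, lr, t, true));
    }
    for (int i = 0; i < n; ++i) dEnc[depth - 1][i] += dxj[i];
    for (int i = depth - 1; i >= 0; --i) {
      Batch d = lreluGradB(enc[i], dEnc[i], 0.2);
      if (i > 0) d = downN[i].backward(d, lr, t, true);
      Batch dprev = down[i].backward(d, lr, t, true);
      if (i > 0)
        for (int s = 0; s < n; ++s) dEnc[i - 1][s] += dprev[s];
    }
  }
};

// Patch discriminator on concatenated (H&E, IF): three LeakyReLU conv
// blocks then a 1-channel sigmoid patch map (pix2pix convention).
struct Disc {
  std::vector<ConvLayer> conv;   // 4 layers
  std::vector<InstNorm> norm;    // on the two middle layers
  std::vector<Batch> act;

  void init(int fl, std::mt19937_64& rng) {
    conv.resize(4); norm.resize(3);
    conv[0].init(4, fl, 4, 2, 1, rng);
    conv[1].init(fl, 2 * fl, 4, 2, 1, rng);
    conv[2].init(2 * fl, 4 * fl, 4, 1, 1, rng);
    conv[3].init(4 * fl, 1, 4, 1, 1, rng);
    norm[1].init(2 * fl);
    norm[2].init(4 * fl);
  }
  Batch forward(const Batch& xs) {
    act.assign(4, Batch());
    Batch cur = xs;
    for (int i = 0; i < 3; ++i) {
      cur = conv[i].forward(cur);
      if (i > 0) cur = norm[i].forward(cur);
      cur = lreluB(cur, 0.2);
      act[i] = cur;
    }
    cur = sigmoidB(conv[3].forward(cur));
    act[3] = cur;
    return cur;
  }
  Batch backward(const Batch& dprob, double lr, int t, bool update) {
    int n = dprob.size();
    Batch d(n);
    for (int i = 0; i < n; ++i)
      d[i] = dprob[i] % act[3][i] % (1.0 - act[3][i]);
    d = conv[3].backward(d, lr, t, update);
    for (int i = 2; i >= 0; --i) {
      d = lreluGradB(act[i], d, 0.2);
      if (i > 0) d = norm[i].backward(d, lr, t, update);
      d = conv[i].backward(d, lr, t, update);
    }
    return d;   // gradient wrt the 4-channel input
  }
};

// Parameter enumeration over conv and norm layers, in forward order.
struct AnyLayer { ConvLayer* c = nullptr; InstNorm* n = nullptr; };

static std::vector<AnyLayer> gLayers(UNetG& G) {
  std::vector<AnyLayer> v;
  for (int i = 0; i < G.depth; ++i) {
    v.push_back({&G.down[i], nullptr});
    if (i > 0) v.push_back({nullptr, &G.downN[i]});
  }
  for (int j = 0; j < G.depth - 1; ++j) {
    v.push_back({&G.up[j], nullptr});
    v.push_back({nullptr, &G.upN[j]});
  }
  v.push_back({&G.fin, nullptr});
  return v;
}
static std::vector<AnyLayer> dLayers(Disc& D) {
  std::vector<AnyLayer> v;
  for (int i = 0; i < 4; ++i) {
    v.push_back({&D.conv[i], nullptr});
    if (i == 1 || i == 2) v.push_back({nullptr, &D.norm[i]});
  }
  return v;
}

struct GanState {
  int tile = 0, fl = 0;
  bool adversarial = true;
  std::mt19937_64 rng;
  UNetG G;
  Disc D;
  int tG = 0, tD = 0;
};

static cube sliceHE(const NumericVector& arr, int h, int w, int idx) {
  cube x(h, w, 3);
  const double* p = arr.begin();
  long long plane = (long long)h * w;
  for (int c = 0; c < 3; ++c)
    std::copy(p + ((long long)idx * 3 + c) * plane,
              p + ((long long)idx * 3 + c + 1) * plane,
              x.slice_memptr(c));
  return x;
}
static cube sliceIF(const NumericVector& arr, int h, int w, int idx) {
  cube y(h, w, 1);
  const double* p = arr.begin();
  long long plane = (long long)h * w;
  std::copy(p + (long long)idx * plane, p + (long long)(idx + 1) * plane,
            y.slice_memptr(0));
  return y;
}

// [[Rcpp::export]]
SEXP gan_create(int tile, int firstLayerFilters, bool adversarial, int seed) {
  GanState* st = new GanState();
  st->tile = tile; st->fl = firstLayerFilters; st->adversarial = adversarial;
  st->rng.seed((unsigned long long)seed);
  st->G.init(tile, firstLayerFilters, st->rng);
  if (adversarial) st->D.init(firstLayerFilters, st->rng);
  XPtr<GanState> ptr(st, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector gan_forward(SEXP ptr, NumericVector he, IntegerVector dims) {
  XPtr<GanState> st(ptr);
  int h = dims[0], w = dims[1], n = dims[3];
  Batch xs(n);
  for (int i = 0; i < n; ++i) xs[i] = sliceHE(he, h, w, i);
  Batch ys = st->G.forward(xs);
  NumericVector out((long long)h * w * n);
  out.attr("dim") = IntegerVector::create(h, w, n);
  for (int i = 0; i < n; ++i)
    std::copy(ys[i].slice_memptr(0), ys[i].slice_memptr(0) + (long long)h * w,
              out.begin() + (long long)i * h * w);
  return out;
}

static inline double clampP(double p) {
  return std::min(1.0 - 1e-7, std::max(1e-7, p));
}


// One optimizer step on a batch. Adversarial mode: D step (BCE real vs
// fake) then G step (non-saturating adversarial term + lambda * L1).
// l1_only mode: G step on lambda * L1 alone.
// [[Rcpp::export]]
List gan_train_step(SEXP ptr, NumericVector he, NumericVector ifimg,
                    IntegerVector dims, double lambda, double lr) {
  XPtr<GanState> st(ptr);
  int h = dims[0], w = dims[1], n = dims[3];
  long long npix = (long long)h * w * n;
  double dLoss = NA_REAL, gAdv = NA_REAL, accReal = NA_REAL, accFake = NA_REAL;
  double l1 = 0.0;

  Batch xs(n), ys(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = sliceHE(he, h, w, i);
    ys[i] = sliceIF(ifimg, h, w, i);
  }

  if (st->adversarial) {
    // ---- discriminator step (real half, then fake half)
    Batch fakes = st->G.forward(xs);
    Batch realIn(n), fakeIn(n);
    for (int i = 0; i < n; ++i) {
      realIn[i] = concatC(xs[i], ys[i]);
      fakeIn[i] = concatC(xs[i], fakes[i]);
    }
    double dl = 0.0, ar = 0.0, af = 0.0;
    long long npatch = 0;
    {
      Batch p = st->D.forward(realIn);
      Batch dp(n);
      for (int i = 0; i < n; ++i) {
        dp[i].set_size(arma::size(p[i]));
        npatch += p[i].n_elem;
        for (arma::uword e = 0; e < p[i].n_elem; ++e) {
          double pe = clampP(p[i](e));
          dl += -std::log(pe);
          ar += (pe > 0.5);
          dp[i](e) = -1.0 / pe;
        }
      }
      for (int i = 0; i < n; ++i) dp[i] /= (double)npatch;
      st->tD++;
      st->D.backward(dp, lr, st->tD, true);
    }
    {
      Batch p = st->D.forward(fakeIn);
      Batch dp(n);
      for (int i = 0; i < n; ++i) {
        dp[i].set_size(arma::size(p[i]));
        for (arma::uword e = 0; e < p[i].n_elem; ++e) {
          double pe = clampP(p[i](e));
          dl += -std::log(1.0 - pe);
          af += (pe < 0.5);
          dp[i](e) = 1.0 / (1.0 - pe);
        }
      }
      for (int i = 0; i < n; ++i) dp[i] /= (double)npatch;
      st->tD++;
      st->D.backward(dp, lr, st->tD, true);
    }
    dLoss = dl / npatch;  // mean(-log D_real) + mean(-log(1 - D_fake))
    accReal = ar / npatch; accFake = af / npatch;

    // ---- generator step
    Batch fake2 = st->G.forward(xs);
    Batch gIn(n);
    for (int i = 0; i < n; ++i) gIn[i] = concatC(xs[i], fake2[i]);
    Batch p = st->D.forward(gIn);
    double ga = 0.0;
    Batch dp(n);
    for (int i = 0; i < n; ++i) {
      dp[i].set_size(arma::size(p[i]));
      for (arma::uword e = 0; e < p[i].n_elem; ++e) {
        double pe = clampP(p[i](e));
        ga += -std::log(pe);                    // non-saturating form
        dp[i](e) = -1.0 / pe / (double)p[i].n_elem / n;
      }
    }
    Batch dIn = st->D.backward(dp, lr, 0, false);  // no D update here
    Batch dFake(n);
    for (int i = 0; i < n; ++i) {
      dFake[i] = cube(dIn[i].slices(3, 3));
      l1 += arma::accu(arma::abs(ys[i] - fake2[i]));
      cube dl1 = fake2[i] - ys[i];
      dl1.transform([](double v) { return v > 0 ? 1.0 : (v < 0 ? -1.0 : 0.0); });
      dFake[i] += lambda / (double)npix * dl1;
    }
    st->tG++;
    st->G.backward(dFake, lr, st->tG);
    gAdv = ga / n;
    l1 /= npix;
  } else {
    Batch fake = st->G.forward(xs);
    Batch dFake(n);
    for (int i = 0; i < n; ++i) {
      l1 += arma::accu(arma::abs(ys[i] - fake[i]));
      cube dl1 = fake[i] - ys[i];
      dl1.transform([](double v) { return v > 0 ? 1.0 : (v < 0 ? -1.0 : 0.0); });
      dFake[i] = lambda / (double)npix * dl1;
    }
    st->tG++;
    st->G.backward(dFake, lr, st->tG);
    l1 /= npix;
  }
  return List::create(_["d_loss"] = dLoss, _["g_adv"] = gAdv,
                      _["l1"] = l1, _["lambda_l1"] = lambda * l1,
                      _["d_acc_real"] = accReal, _["d_acc_fake"] = accFake);
}

static List layersToList(std::vector<AnyLayer> ls) {
  List out(ls.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    if (ls[i].c) {
      ConvLayer* l = ls[i].c;
      out[i] = List::create(
        _["W"] = wrap(l->W), _["b"] = wrap(l->b),
        _["meta"] = IntegerVector::create(l->cin, l->cout, l->k, l->stride,
                                          l->pad));
    } else {
      InstNorm* l = ls[i].n;
      out[i] = List::create(
        _["W"] = wrap(mat(l->gamma)), _["b"] = wrap(l->beta),
        _["meta"] = IntegerVector::create(l->C, l->C, 0, 0, 0));  // k=0: norm
    }
  }
  return out;
}
static void listToLayers(List src, std::vector<AnyLayer> ls) {
  if ((size_t)src.size() != ls.size()) stop("weight list length mismatch");
  for (size_t i = 0; i < ls.size(); ++i) {
    List li = src[i];
    mat W = as<mat>(li["W"]);
    vec b = as<vec>(li["b"]);
    if (ls[i].c) {
      if (W.n_rows != ls[i].c->W.n_rows || W.n_cols != ls[i].c->W.n_cols)
        stop("weight matrix shape mismatch at layer %d", (int)i + 1);
      ls[i].c->W = W; ls[i].c->b = b;
    } else {
      if ((int)W.n_elem != ls[i].n->C)
        stop("norm parameter shape mismatch at layer %d", (int)i + 1);
      ls[i].n->gamma = arma::vectorise(W); ls[i].n->beta = b;
    }
  }
}

// [[Rcpp::export]]
List gan_get_weights(SEXP ptr) {
  XPtr<GanState> st(ptr);
  List g = layersToList(gLayers(st->G));
  if (st->adversarial)
    return List::create(_["generator"] = g,
                        _["discriminator"] = layersToList(dLayers(st->D)));
  return List::create(_["generator"] = g);
}

// [[Rcpp::export]]
void gan_set_weights(SEXP ptr, List weights) {
  XPtr<GanState> st(ptr);
  listToLayers(weights["generator"], gLayers(st->G));
  if (st->adversarial && weights.containsElementNamed("discriminator"))
    listToLayers(weights["discriminator"], dLayers(st->D));
}

// Mean patch probability of the discriminator per (he, if) pair;
// diagnostic, used by tests of the adversarial objective.
// [[Rcpp::export]]
NumericVector gan_discriminate(SEXP ptr, NumericVector he, NumericVector ifimg,
                               IntegerVector dims) {
  XPtr<GanState> st(ptr);
  if (!st->adversarial) stop("l1_only translator has no discriminator");
  int h = dims[0], w = dims[1], n = dims[3];
  Batch xs(n);
  for (int i = 0; i < n; ++i)
    xs[i] = concatC(sliceHE(he, h, w, i), sliceIF(ifimg, h, w, i));
  Batch p = st->D.forward(xs);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = arma::accu(p[i]) / p[i].n_elem;
  return out;
}
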