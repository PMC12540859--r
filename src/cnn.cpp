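// Compact CNN engine for 75x75x5 single-cell crops.
//
// Architecture: four 3x3 convolution blocks (conv -> batch norm -> ReLU),
// each optionally followed by a 2x2/stride-2 max-pool (always after the
// last block), then 1x1 adaptive average pooling to give a width[4]-dim
// representation h, and a fully connected head (projection head for the
// contrastive encoder, classification head for the WBC depletion model).
// Training uses Adam with L2 weight decay on the weight matrices.
//
// Activations are stored as tall ((H*W*batch) x channels) float matrices
// with sample-major row blocks and in-block row index p = x*H + y, so each
// channel is a contiguous column and convolutions reduce to one tall
// GEMM per layer via im2col. Weights cross the R boundary as doubles (the
// public checkpoint format); arithmetic runs in single precision.
#include <RcppArmadillo.h>
#include <malloc.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// keep big activation buffers on the heap across calls instead of
// mmap/munmap churn (hundreds of MB per training step otherwise)
namespace {
struct MallocTuning {
  MallocTuning() {
#ifdef M_MMAP_THRESHOLD
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  }
} malloc_tuning;
}
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uword;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

struct Net {
  std::vector<fmat> W;          // conv kernels (9*Cin) x K (transposed view)
  std::vector<fvec> b, g, be, rm, rv;
  std::vector<fmat> Wh;         // head weights din x dout (transposed view)
  std::vector<fvec> bh;
  std::vector<int> widths;
  int in_ch;
  bool pool_each;
};

static fmat to_f(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static fvec to_fv(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}
static NumericMatrix from_f(const fmat &m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static NumericVector from_fv(const fvec &v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

static Net parse_net(const List &weights, const List &cfg) {
  Net n;
  IntegerVector w = cfg["widths"];
  n.widths = std::vector<int>(w.begin(), w.end());
  n.in_ch = as<int>(cfg["in_ch"]);
  n.pool_each = as<bool>(cfg["pool_each"]);
  List Wc = weights["Wconv"], bc = weights["bconv"], gc = weights["gamma"],
       bec = weights["beta"], rmc = weights["rmean"], rvc = weights["rvar"],
       Wh = weights["Whead"], bh = weights["bhead"];
  for (int l = 0; l < 4; ++l) {
    n.W.push_back(to_f(Wc[l]).t());          // stored K x 9Cin -> 9Cin x K
    n.b.push_back(to_fv(bc[l]));
    n.g.push_back(to_fv(gc[l]));
    n.be.push_back(to_fv(bec[l]));
    n.rm.push_back(to_fv(rmc[l]));
    n.rv.push_back(to_fv(rvc[l]));
  }
  for (int l = 0; l < Wh.size(); ++l) {
    n.Wh.push_back(to_f(Wh[l]).t());         // stored dout x din -> din x dout
    n.bh.push_back(to_fv(bh[l]));
  }
  return n;
}

static List net_to_list(const Net &n) {
  List Wc(4), bc(4), gc(4), bec(4), rmc(4), rvc(4);
  for (int l = 0; l < 4; ++l) {
    Wc[l] = from_f(n.W[l].t()); bc[l] = from_fv(n.b[l]);
    gc[l] = from_fv(n.g[l]); bec[l] = from_fv(n.be[l]);
    rmc[l] = from_fv(n.rm[l]); rvc[l] = from_fv(n.rv[l]);
  }
  int nh = n.Wh.size();
  List Whl(nh), bhl(nh);
  for (int l = 0; l < nh; ++l) {
    Whl[l] = from_f(n.Wh[l].t()); bhl[l] = from_fv(n.bh[l]);
  }
  return List::create(_["Wconv"] = Wc, _["bconv"] = bc, _["gamma"] = gc,
                      _["beta"] = bec, _["rmean"] = rmc, _["rvar"] = rvc,
                      _["Whead"] = Whl, _["bhead"] = bhl);
}

// im2col for 3x3 pad 1 on tall layout. A: (H*W*B) x Cin -> (H*W*B) x (9*Cin),
// output column j = kidx*Cin + c with kidx = (dx+1)*3 + (dy+1).
static fmat im2col3(const fmat &A, int H, int W, int B) {
  int Cin = A.n_cols, HW = H * W;
  fmat col((uword)HW * B, (uword)Cin * 9, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const float *src0 = A.colptr(c);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int kidx = (dx + 1) * 3 + (dy + 1);
        float *dst0 = col.colptr((uword)kidx * Cin + c);
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        int len = y1 - y0;
        if (len <= 0) continue;
        for (int bimg = 0; bimg < B; ++bimg) {
          uword off = (uword)bimg * HW;
          for (int x = 0; x < W; ++x) {
            int sx = x + dx;
            if (sx < 0 || sx >= W) continue;
            std::memcpy(dst0 + off + (uword)x * H + y0,
                        src0 + off + (uword)sx * H + y0 + dy,
                        sizeof(float) * len);
          }
        }
      }
  }
  return col;
}

// adjoint: scatter-add dcol ((H*W*B) x 9Cin) back to dA ((H*W*B) x Cin)
static fmat col2im3(const fmat &dcol, int Cin, int H, int W, int B) {
  fmat dA((uword)H * W * B, Cin, arma::fill::zeros);
  int HW = H * W;
  for (int c = 0; c < Cin; ++c) {
    float *dst0 = dA.colptr(c);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int kidx = (dx + 1) * 3 + (dy + 1);
        const float *src0 = dcol.colptr((uword)kidx * Cin + c);
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        int len = y1 - y0;
        if (len <= 0) continue;
        for (int bimg = 0; bimg < B; ++bimg) {
          uword off = (uword)bimg * HW;
          for (int x = 0; x < W; ++x) {
            int sx = x + dx;
            if (sx < 0 || sx >= W) continue;
            const float *s = src0 + off + (uword)x * H + y0;
            float *d = dst0 + off + (uword)sx * H + y0 + dy;
            for (int i = 0; i < len; ++i) d[i] += s[i];
          }
        }
      }
  }
  return dA;
}

struct LayerCache {
  fmat col, xhat;         // im2col input, BN-normalized pre-activation
  fvec sigma;
  arma::umat argmax;      // pool argmax (row index within column), empty if
  int Hin, Win, Hout, Wout;
  bool pooled;
};

struct FwdCache {
  std::vector<LayerCache> layer;
  int Hf, Wf, B;
  std::vector<fmat> head_in, head_pre;
};

// contiguous per-column scalar broadcasts (each_row() is row-strided and
// pathologically slow on tall activation matrices)
static inline void col_add(fmat &Z, const fvec &b) {
  for (uword k = 0; k < Z.n_cols; ++k) {
    float v = b(k), *p = Z.colptr(k);
    for (uword i = 0; i < Z.n_rows; ++i) p[i] += v;
  }
}
static inline void col_axpb(fmat &Z, const fvec &a, const fvec &b) {
  // Z[,k] = Z[,k] * a[k] + b[k]
  for (uword k = 0; k < Z.n_cols; ++k) {
    float av = a(k), bv = b(k), *p = Z.colptr(k);
    for (uword i = 0; i < Z.n_rows; ++i) p[i] = p[i] * av + bv;
  }
}

static fmat maxpool(const fmat &A, int H, int W, int B, arma::umat &argmax) {
  int Ho = H / 2, Wo = W / 2, K = A.n_cols;
  fmat out((uword)Ho * Wo * B, K);
  argmax.set_size((uword)Ho * Wo * B, K);
  for (int k = 0; k < K; ++k) {
    const float *src = A.colptr(k);
    float *dst = out.colptr(k);
    uword *am = argmax.colptr(k);
    for (int bimg = 0; bimg < B; ++bimg) {
      uword offi = (uword)bimg * (uword)(H * W);
      uword offo = (uword)bimg * (uword)(Ho * Wo);
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          uword c00 = offi + (uword)(2 * xo) * H + 2 * yo;
          uword cands[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
          float best = src[cands[0]];
          uword bi = cands[0];
          for (int q = 1; q < 4; ++q)
            if (src[cands[q]] > best) { best = src[cands[q]]; bi = cands[q]; }
          dst[offo + (uword)xo * Ho + yo] = best;
          am[offo + (uword)xo * Ho + yo] = bi;
        }
    }
  }
  return out;
}

// forward through conv trunk; returns h (B x last width)
static fmat trunk_forward(const Net &n, fmat A, int B, bool training,
                          FwdCache *cache, Net *upd) {
  int H = 75, W = 75;
  for (int l = 0; l < 4; ++l) {
    LayerCache lc;
    lc.Hin = H; lc.Win = W;
    fmat col = im2col3(A, H, W, B);
    fmat Z = col * n.W[l];
    col_add(Z, n.b[l]);
    fvec mu, sg;
    if (training) {
      mu = arma::mean(Z, 0).t();
      fvec var = arma::var(Z, 1 /*biased*/, 0).t();
      sg = arma::sqrt(var + BN_EPS);
      if (upd) {
        upd->rm[l] = (1 - BN_MOM) * n.rm[l] + BN_MOM * mu;
        upd->rv[l] = (1 - BN_MOM) * n.rv[l] + BN_MOM * var;
      }
    } else {
      mu = n.rm[l];
      sg = arma::sqrt(n.rv[l] + BN_EPS);
    }
    fmat xhat = std::move(Z);
    col_axpb(xhat, 1.0f / sg, -mu / sg);       // (x - mu) / sigma
    // fused scale-shift + ReLU: act = max(0, g*xhat + be)
    fmat act(xhat.n_rows, xhat.n_cols);
    for (uword k = 0; k < act.n_cols; ++k) {
      float gk = n.g[l](k), bk = n.be[l](k);
      const float *xh = xhat.colptr(k);
      float *p = act.colptr(k);
      for (uword i = 0; i < act.n_rows; ++i) {
        float v = gk * xh[i] + bk;
        p[i] = v > 0 ? v : 0;
      }
    }
    bool pooled = n.pool_each || l == 3;
    lc.pooled = pooled;
    if (cache) { lc.col = std::move(col); lc.xhat = std::move(xhat);
                 lc.sigma = sg; }
    if (pooled) {
      arma::umat am;
      A = maxpool(act, H, W, B, am);
      if (cache) lc.argmax = std::move(am);
      H /= 2; W /= 2;
    } else {
      A = std::move(act);
    }
    lc.Hout = H; lc.Wout = W;
    if (cache) cache->layer.push_back(std::move(lc));
  }
  if (cache) { cache->Hf = H; cache->Wf = W; cache->B = B; }
  // global average pool: h (B x K)
  int K = A.n_cols, HW = H * W;
  fmat h(B, K);
  for (int k = 0; k < K; ++k) {
    const float *src = A.colptr(k);
    for (int bimg = 0; bimg < B; ++bimg) {
      float s = 0;
      const float *p = src + (uword)bimg * HW;
      for (int i = 0; i < HW; ++i) s += p[i];
      h(bimg, k) = s / HW;
    }
  }
  if (cache) cache->head_in.push_back(h);   // GAP output feeds the head
  return h;
}

// head over rows (B x dims); ReLU between layers, last layer linear
static fmat head_forward(const Net &n, const fmat &h, FwdCache *cache) {
  fmat a = h;
  int nh = n.Wh.size();
  for (int l = 0; l < nh; ++l) {
    if (cache && l > 0) cache->head_in.push_back(a);
    fmat z = a * n.Wh[l];
    z.each_row() += n.bh[l].t();
    if (cache) cache->head_pre.push_back(z);
    if (l < nh - 1) z.for_each([](float &v) { if (v < 0) v = 0; });
    a = std::move(z);
  }
  return a;
}

struct Grads {
  std::vector<fmat> W;
  std::vector<fvec> b, g, be;
  std::vector<fmat> Wh;
  std::vector<fvec> bh;
};

// backward from dOut (B x dout gradient at head output)
static void net_backward(const Net &n, const FwdCache &cache, fmat dOut,
                         Grads &gr) {
  int nh = n.Wh.size();
  gr.Wh.resize(nh); gr.bh.resize(nh);
  for (int l = nh - 1; l >= 0; --l) {
    if (l < nh - 1) {
      const fmat &pre = cache.head_pre[l];
      for (uword i = 0; i < dOut.n_elem; ++i)
        if (pre[i] <= 0) dOut[i] = 0;
    }
    gr.Wh[l] = (cache.head_in[l].t() * dOut).t();   // dout x din (public shape)
    gr.bh[l] = arma::sum(dOut, 0).t();
    dOut = dOut * n.Wh[l].t();
  }
  // dOut is now dh (B x K); GAP backward
  int B = cache.B, HW = cache.Hf * cache.Wf;
  fmat dA((uword)HW * B, dOut.n_cols);
  for (uword k = 0; k < dOut.n_cols; ++k) {
    float *dst = dA.colptr(k);
    for (int bimg = 0; bimg < B; ++bimg) {
      float v = dOut(bimg, k) / HW;
      float *p = dst + (uword)bimg * HW;
      for (int i = 0; i < HW; ++i) p[i] = v;
    }
  }
  gr.W.resize(4); gr.b.resize(4); gr.g.resize(4); gr.be.resize(4);
  for (int l = 3; l >= 0; --l) {
    const LayerCache &lc = cache.layer[l];
    fmat dpost;
    if (lc.pooled) {
      dpost.zeros((uword)lc.Hin * lc.Win * B, dA.n_cols);
      for (uword k = 0; k < dA.n_cols; ++k) {
        float *dst = dpost.colptr(k);
        const float *src = dA.colptr(k);
        const uword *am = lc.argmax.colptr(k);
        for (uword j = 0; j < dA.n_rows; ++j) dst[am[j]] += src[j];
      }
    } else {
      dpost = std::move(dA);
    }
    // ReLU mask from the BN parameters: active iff g*xhat + be > 0
    for (uword k = 0; k < dpost.n_cols; ++k) {
      float gk = n.g[l](k), bk = n.be[l](k);
      float *p = dpost.colptr(k);
      const float *xh = lc.xhat.colptr(k);
      for (uword i = 0; i < dpost.n_rows; ++i)
        if (gk * xh[i] + bk <= 0) p[i] = 0;
    }
    // BN backward (per channel column, M elements)
    float M = dpost.n_rows;
    gr.g[l] = arma::sum(dpost % lc.xhat, 0).t();
    gr.be[l] = arma::sum(dpost, 0).t();
    fmat dxhat = std::move(dpost);
    col_axpb(dxhat, n.g[l], fvec(dxhat.n_cols, arma::fill::zeros));
    fvec sum_dx = arma::sum(dxhat, 0).t();
    fvec sum_dxx = arma::sum(dxhat % lc.xhat, 0).t();
    // dZ[,k] = (M*dxhat - sum_dx - xhat*sum_dxx) / (M*sigma), per column
    fmat dZ = std::move(dxhat);
    for (uword k = 0; k < dZ.n_cols; ++k) {
      float sdx = sum_dx(k), sdxx = sum_dxx(k);
      float inv = 1.0f / (M * lc.sigma(k));
      float *p = dZ.colptr(k);
      const float *xh = lc.xhat.colptr(k);
      for (uword i = 0; i < dZ.n_rows; ++i)
        p[i] = (M * p[i] - sdx - xh[i] * sdxx) * inv;
    }
    // conv backward
    gr.W[l] = (lc.col.t() * dZ).t();               // K x 9Cin (public shape)
    gr.b[l] = arma::sum(dZ, 0).t();
    if (l > 0) {
      fmat dcol = dZ * n.W[l].t();
      dA = col2im3(dcol, n.W[l].n_rows / 9, lc.Hin, lc.Win, B);
    }
  }
}

// Adam over the flat parameter ordering Wconv(4), bconv(4), gamma(4),
// beta(4), Whead..., bhead...; state lists m, v hold double matrices.
static void adam_update(Net &n, const Grads &gr, List &m, List &v, int step,
                        double lr, double wd) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double c1 = 1.0 - std::pow(b1, step), c2 = 1.0 - std::pow(b2, step);
  int idx = 0;
  auto upd_mat = [&](fmat &w_T, const fmat &g_pub, bool transposed,
                     bool decay) {
    // w_T is the transposed working copy; g_pub is in public shape
    fmat wpub = transposed ? fmat(w_T.t()) : w_T;
    fmat g = g_pub;
    if (decay && wd > 0) g += (float)wd * wpub;
    NumericMatrix mm = m[idx], vv = v[idx];
    for (uword i = 0; i < g.n_elem; ++i) {
      double gi = g[i];
      mm[i] = b1 * mm[i] + (1 - b1) * gi;
      vv[i] = b2 * vv[i] + (1 - b2) * gi * gi;
      wpub[i] -= (float)(lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps));
    }
    w_T = transposed ? fmat(wpub.t()) : wpub;
    ++idx;
  };
  auto upd_vec = [&](fvec &w) {
    // gradient passed via closure caller; see calls below
    ++idx;
  };
  (void)upd_vec;
  auto upd_v = [&](fvec &w, const fvec &g0) {
    NumericMatrix mm = m[idx], vv = v[idx];
    for (uword i = 0; i < g0.n_elem; ++i) {
      double gi = g0[i];
      mm[i] = b1 * mm[i] + (1 - b1) * gi;
      vv[i] = b2 * vv[i] + (1 - b2) * gi * gi;
      w[i] -= (float)(lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps));
    }
    ++idx;
  };
  for (int l = 0; l < 4; ++l) upd_mat(n.W[l], gr.W[l], true, true);
  for (int l = 0; l < 4; ++l) upd_v(n.b[l], gr.b[l]);
  for (int l = 0; l < 4; ++l) upd_v(n.g[l], gr.g[l]);
  for (int l = 0; l < 4; ++l) upd_v(n.be[l], gr.be[l]);
  for (size_t l = 0; l < n.Wh.size(); ++l) upd_mat(n.Wh[l], gr.Wh[l], true, true);
  for (size_t l = 0; l < n.Wh.size(); ++l) upd_v(n.bh[l], gr.bh[l]);
}

// NT-Xent loss and gradient on projections Z (2N x P rows), pairs (i, i+N).
static double nt_xent(const fmat &Z, double tau, fmat *dZ) {
  uword n2 = Z.n_rows;
  if (n2 % 2 != 0) stop("NT-Xent needs an even number of rows");
  uword N = n2 / 2;
  fvec norms(n2);
  fmat Zn(n2, Z.n_cols);
  for (uword i = 0; i < n2; ++i) {
    double nv = arma::norm(Z.row(i));
    if (nv < 1e-12) stop("zero-norm projection vector: cosine undefined");
    norms(i) = nv;
    Zn.row(i) = Z.row(i) / (float)nv;
  }
  fmat S = (Zn * Zn.t()) / (float)tau;
  double loss = 0;
  fmat P(n2, n2, arma::fill::zeros);
  for (uword i = 0; i < n2; ++i) {
    uword pos = i < N ? i + N : i - N;
    double mx = -arma::datum::inf;
    for (uword k = 0; k < n2; ++k)
      if (k != i && S(i, k) > mx) mx = S(i, k);
    double se = 0;
    for (uword k = 0; k < n2; ++k)
      if (k != i) se += std::exp((double)S(i, k) - mx);
    double lse = mx + std::log(se);
    loss += -((double)S(i, pos) - lse);
    if (dZ) {
      for (uword k = 0; k < n2; ++k)
        if (k != i) P(i, k) = std::exp((double)S(i, k) - lse);
      P(i, pos) -= 1.0f;
    }
  }
  loss /= n2;
  if (dZ) {
    P /= (float)n2;
    fmat dZn = (P + P.t()) * Zn / (float)tau;
    dZ->set_size(n2, Z.n_cols);
    for (uword i = 0; i < n2; ++i) {
      float dp = arma::dot(Zn.row(i), dZn.row(i));
      dZ->row(i) = (dZn.row(i) - Zn.row(i) * dp) / norms(i);
    }
  }
  return loss;
}

// [[Rcpp::export]]
double cpp_nt_xent_loss(const arma::mat &Z, double tau) {
  fmat Zf(Z.n_rows, Z.n_cols);
  std::copy(Z.begin(), Z.end(), Zf.begin());
  return nt_xent(Zf, tau, nullptr);
}

// X arrives as (75*75*in_ch) x B doubles, one column per sample; convert to
// the tall layout (75*75*B) x in_ch
static fmat reshape_input(const arma::mat &X, int in_ch) {
  int HW = 75 * 75, B = X.n_cols;
  fmat A((uword)HW * B, in_ch);
  for (int c = 0; c < in_ch; ++c) {
    float *dst = A.colptr(c);
    for (int bimg = 0; bimg < B; ++bimg) {
      const double *src = X.colptr(bimg) + (uword)c * HW;
      float *d = dst + (uword)bimg * HW;
      for (int i = 0; i < HW; ++i) d[i] = (float)src[i];
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::mat cpp_forward_h(const arma::mat &X, List weights, List cfg) {
  Net n = parse_net(weights, cfg);
  int B = X.n_cols;
  fmat h = trunk_forward(n, reshape_input(X, n.in_ch), B, false, nullptr,
                         nullptr);
  arma::mat out(h.n_cols, h.n_rows);      // K x B (legacy orientation)
  for (uword i = 0; i < h.n_rows; ++i)
    for (uword k = 0; k < h.n_cols; ++k) out(k, i) = h(i, k);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_forward_head(const arma::mat &X, List weights, List cfg) {
  Net n = parse_net(weights, cfg);
  int B = X.n_cols;
  fmat h = trunk_forward(n, reshape_input(X, n.in_ch), B, false, nullptr,
                         nullptr);
  fmat z = head_forward(n, h, nullptr);
  arma::mat out(z.n_cols, z.n_rows);
  for (uword i = 0; i < z.n_rows; ++i)
    for (uword k = 0; k < z.n_cols; ++k) out(k, i) = z(i, k);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_head_only(const arma::mat &h, List weights, List cfg) {
  Net n = parse_net(weights, cfg);
  fmat hf(h.n_cols, h.n_rows);            // incoming K x B -> B x K
  for (uword i = 0; i < h.n_cols; ++i)
    for (uword k = 0; k < h.n_rows; ++k) hf(i, k) = (float)h(k, i);
  fmat z = head_forward(n, hf, nullptr);
  arma::mat out(z.n_cols, z.n_rows);
  for (uword i = 0; i < z.n_rows; ++i)
    for (uword k = 0; k < z.n_cols; ++k) out(k, i) = z(i, k);
  return out;
}

// [[Rcpp::export]]
List cpp_step_contrastive(const arma::mat &X, List weights, List m, List v,
                          List cfg, int step, double lr, double wd,
                          double tau) {
  Net n = parse_net(weights, cfg);
  Net upd = n;
  int B = X.n_cols;
  FwdCache cache;
  arma::wall_clock ck;
  bool prof = std::getenv("CYTODEEP_PROFILE") != nullptr;
  ck.tic();
  fmat h = trunk_forward(n, reshape_input(X, n.in_ch), B, true, &cache, &upd);
  fmat z = head_forward(n, h, &cache);
  double t_f = ck.toc(); ck.tic();
  fmat dz;
  double loss = nt_xent(z, tau, &dz);
  Grads gr;
  net_backward(n, cache, dz, gr);
  double t_b = ck.toc(); ck.tic();
  adam_update(upd, gr, m, v, step, lr, wd);
  List out = List::create(_["weights"] = net_to_list(upd), _["m"] = m,
                          _["v"] = v, _["loss"] = loss);
  if (prof)
    Rcout << "fwd " << t_f << " bwd " << t_b << " adam " << ck.toc() << "\n";
  return out;
}

// [[Rcpp::export]]
List cpp_step_supervised(const arma::mat &X, IntegerVector y, List weights,
                         List m, List v, List cfg, int step, double lr,
                         double wd) {
  Net n = parse_net(weights, cfg);
  Net upd = n;
  int B = X.n_cols;
  FwdCache cache;
  fmat h = trunk_forward(n, reshape_input(X, n.in_ch), B, true, &cache, &upd);
  fmat logits = head_forward(n, h, &cache);
  fmat dlog(B, logits.n_cols);
  double loss = 0;
  for (int i = 0; i < B; ++i) {
    frowvec lg = logits.row(i);
    float mx = lg.max();
    frowvec e = arma::exp(lg - mx);
    float s = arma::accu(e);
    frowvec p = e / s;
    loss += -((double)lg(y[i]) - mx - std::log((double)s));
    p(y[i]) -= 1.0f;
    dlog.row(i) = p / (float)B;
  }
  loss /= B;
  Grads gr;
  net_backward(n, cache, dlog, gr);
  adam_update(upd, gr, m, v, step, lr, wd);
  return List::create(_["weights"] = net_to_list(upd), _["m"] = m, _["v"] = v,
                      _["loss"] = loss);
}

// mean cross-entropy of a labelled batch under current weights (eval mode)
// [[Rcpp::export]]
double cpp_eval_ce(const arma::mat &X, IntegerVector y, List weights,
                   List cfg) {
  Net n = parse_net(weights, cfg);
  int B = X.n_cols;
  fmat h = trunk_forward(n, reshape_input(X, n.in_ch), B, false, nullptr,
                         nullptr);
  fmat logits = head_forward(n, h, nullptr);
  double loss = 0;
  for (int i = 0; i < B; ++i) {
    frowvec lg = logits.row(i);
    float mx = lg.max();
    loss += -((double)lg(y[i]) - mx -
              std::log((double)arma::accu(arma::exp(lg - mx))));
  }
  return loss / B;
}
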