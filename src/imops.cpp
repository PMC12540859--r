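// Image primitives used by the simulator, augmentation chain and
// perturbation suite: separable Gaussian blur and affine warping of
// 75x75x5 crop stacks (bilinear for intensity channels, nearest for the
// mask channel).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Separable Gaussian blur with reflected borders. radius <= 0 picks
// ceil(3*sigma); radius = 1 gives the 3-pixel kernel used in augmentation.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix x, double sigma, int radius) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int r = radius > 0 ? radius : (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int j = i + d;
        if (j < 0) j = -j - 1;
        if (j >= nr) j = 2 * nr - j - 1;
        acc += k[d + r] * x(j, c);
      }
      tmp(i, c) = acc;
    }
  // cols
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int j = c + d;
        if (j < 0) j = -j - 1;
        if (j >= nc) j = 2 * nc - j - 1;
        acc += k[d + r] * tmp(i, j);
      }
      out(i, c) = acc;
    }
  return out;
}

// Render one synthetic cell into a 75x75x5 crop: anisotropic Gaussian
// blobs (nucleus geometry for DAPI, cytoplasm geometry for the other
// channels) clipped to the elliptical footprint, plus additive background
// noise from a Box-Muller mt19937 stream (seeded, deterministic).
// [[Rcpp::export]]
NumericVector cpp_render_crop(double cy, double cx, double a_n, double b_n,
                              double a_c, double b_c, double theta,
                              NumericVector amps, double noise_level,
                              double noise_sd, int noise_seed,
                              bool add_noise) {
  const int H = 75, W = 75;
  NumericVector out(H * W * 5);
  out.attr("dim") = IntegerVector::create(H, W, 5);
  double a_f = std::max(a_n, a_c), b_f = std::max(b_n, b_c);
  double ct = std::cos(theta), st = std::sin(theta);
  double sn_a = a_n / 1.6, sn_b = b_n / 1.6;
  double sc_a = a_c / 1.6, sc_b = b_c / 1.6;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double dy = y + 1 - cy, dx = x + 1 - cx;   // 1-based centre, as in R
      double u = dy * ct + dx * st;
      double v = -dy * st + dx * ct;
      double fu = u / a_f, fv = v / b_f;
      if (fu * fu + fv * fv > 1) continue;
      out[y + H * (x + W * 4)] = 1.0;
      double gn = std::exp(-0.5 * (u * u / (sn_a * sn_a) + v * v / (sn_b * sn_b)));
      double gc = std::exp(-0.5 * (u * u / (sc_a * sc_a) + v * v / (sc_b * sc_b)));
      for (int k = 0; k < 4; ++k)
        out[y + H * (x + W * k)] = amps[k] * (k == 0 ? gn : gc);
    }
  if (add_noise) {
    std::mt19937 gen(noise_seed);
    auto unif = [&]() { return (gen() + 0.5) * (1.0 / 4294967296.0); };
    int n = H * W * 4;
    for (int i = 0; i < n; i += 2) {
      double u1 = unif(), u2 = unif();
      double r = std::sqrt(-2.0 * std::log(u1));
      double z1 = r * std::cos(2 * M_PI * u2), z2 = r * std::sin(2 * M_PI * u2);
      out[i] += noise_level + noise_sd * z1;
      if (i + 1 < n) out[i + 1] += noise_level + noise_sd * z2;
    }
  } else {
    for (int i = 0; i < H * W * 4; ++i) out[i] += noise_level;
  }
  for (int i = 0; i < H * W * 4; ++i) {
    double v = std::round(out[i]);
    out[i] = v < 0 ? 0 : (v > 65535 ? 65535 : v);
  }
  return out;
}

// Affine warp of an H x W x C stack. The forward map is
//   dst = A (src - ctr) + ctr + t,
// so sampling uses src = Ainv (dst - ctr - t) + ctr. Channels flagged in
// `nearest` use nearest-neighbour sampling (instance/binary masks), others
// bilinear; out-of-frame samples are zero.
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector img, NumericMatrix Ainv,
                              NumericVector t, LogicalVector nearest) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out(H * W * C);
  out.attr("dim") = d;
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  double a11 = Ainv(0, 0), a12 = Ainv(0, 1), a21 = Ainv(1, 0), a22 = Ainv(1, 1);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double dy = y - cy - t[0], dx = x - cx - t[1];
      double sy = a11 * dy + a12 * dx + cy;
      double sx = a21 * dy + a22 * dx + cx;
      for (int c = 0; c < C; ++c) {
        double val = 0.0;
        if (nearest[c]) {
          int iy = (int)std::floor(sy + 0.5), ix = (int)std::floor(sx + 0.5);
          if (iy >= 0 && iy < H && ix >= 0 && ix < W)
            val = img[iy + H * (ix + W * c)];
        } else {
          int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
          double fy = sy - y0, fx = sx - x0;
          for (int oy = 0; oy <= 1; ++oy)
            for (int ox = 0; ox <= 1; ++ox) {
              int yy = y0 + oy, xx = x0 + ox;
              if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
              double w = (oy ? fy : 1 - fy) * (ox ? fx : 1 - fx);
              val += w * img[yy + H * (xx + W * c)];
            }
        }
        out[y + H * (x + W * c)] = val;
      }
    }
  }
  return out;
}
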