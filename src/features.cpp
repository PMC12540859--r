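// Engineered 368-dimension feature vector for a 75x75x5 single-cell crop.
//
// Layout (fixed; mirrored by the R-side manifest):
//   [8]   shape: area, perimeter, eccentricity, major_axis, minor_axis,
//         solidity, extent, equiv_diameter
//   [2]   mask global: boundary_roughness, center_offset
//   [8]   |weighted-centroid offset| (dr, dc) per channel (4 channels)
//   [120] 12 intensity stats x 10 images (4 channels then 6 channel-pair
//         products): mean, median, sd, mad, min, max, q05, q25, q75, q95,
//         skewness, excess kurtosis; intensities pre-scaled to [0,1]
//   [182] 13 Haralick stats (symmetrized GLCM, 64 fixed grey levels on
//         [0,1], 4 directions averaged) x (4 channels x offsets {1,2} +
//         6 products x offset 1)
//   [48]  12 gradient-magnitude stats x 4 channels
//
// All statistics are computed over the masked pixels only, so every feature
// is invariant under horizontal/vertical flips (the Haralick direction set
// is closed under flips because the GLCM is symmetrized).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int H = 75, W = 75;

static double quant7(std::vector<double> &x, double p) {
  // R's default (type 7) quantile on a sorted copy
  int n = x.size();
  if (n == 1) return x[0];
  double h = (n - 1) * p;
  int f = (int)std::floor(h);
  if (f >= n - 1) return x[n - 1];
  return x[f] + (h - f) * (x[f + 1] - x[f]);
}

static void intensity_stats(const std::vector<double> &vals, double *out) {
  int n = vals.size();
  std::vector<double> s(vals);
  std::sort(s.begin(), s.end());
  double mean = 0;
  for (double v : s) mean += v;
  mean /= n;
  double med = quant7(s, 0.5);
  double m2 = 0, m3 = 0, m4 = 0;
  for (double v : s) {
    double d = v - mean;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
  }
  double var = n > 1 ? m2 / (n - 1) : 0.0;
  m2 /= n; m3 /= n; m4 /= n;
  std::vector<double> ad(n);
  for (int i = 0; i < n; ++i) ad[i] = std::fabs(vals[i] - med);
  std::sort(ad.begin(), ad.end());
  double madv = 1.4826 * quant7(ad, 0.5);
  double skew = m2 > 1e-12 ? m3 / std::pow(m2, 1.5) : 0.0;
  double kurt = m2 > 1e-12 ? m4 / (m2 * m2) - 3.0 : 0.0;
  out[0] = mean; out[1] = med; out[2] = std::sqrt(var); out[3] = madv;
  out[4] = s.front(); out[5] = s.back();
  out[6] = quant7(s, 0.05); out[7] = quant7(s, 0.25);
  out[8] = quant7(s, 0.75); out[9] = quant7(s, 0.95);
  out[10] = skew; out[11] = kurt;
}

// 13 classic Haralick statistics from a symmetrized, normalized GLCM built
// over 4 directions at offset d, restricted to masked pixel pairs.
static void haralick13(const arma::mat &img, const arma::umat &mask, int d,
                       double *out) {
  const int NG = 64;
  arma::mat P(NG, NG, arma::fill::zeros);
  int offs[4][2] = {{0, d}, {d, 0}, {d, d}, {d, -d}};
  auto level = [](double v) {
    int g = (int)std::floor(v * NG);
    if (g < 0) g = 0;
    if (g >= NG) g = NG - 1;
    return g;
  };
  double npairs = 0;
  for (int o = 0; o < 4; ++o) {
    int dy = offs[o][0], dx = offs[o][1];
    for (int x = 0; x < W; ++x) {
      int x2 = x + dx;
      if (x2 < 0 || x2 >= W) continue;
      for (int y = 0; y < H; ++y) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= H) continue;
        if (!mask(y, x) || !mask(y2, x2)) continue;
        int a = level(img(y, x)), b = level(img(y2, x2));
        P(a, b) += 1; P(b, a) += 1;  // symmetrize
        npairs += 2;
      }
    }
  }
  for (int i = 0; i < 13; ++i) out[i] = 0.0;
  if (npairs < 1) return;
  P /= npairs;
  arma::vec px = arma::sum(P, 1);             // row marginals
  arma::vec pxy_sum(2 * NG - 1, arma::fill::zeros);   // p_{x+y}, k = i+j
  arma::vec pxy_diff(NG, arma::fill::zeros);          // p_{|x-y|}
  double asm_ = 0, con = 0, idm = 0, ent = 0, corr_num = 0, var_ = 0;
  double mu = 0;
  for (int i = 0; i < NG; ++i) mu += (i + 1) * px(i);
  double sig2 = 0;
  for (int i = 0; i < NG; ++i) sig2 += (i + 1 - mu) * (i + 1 - mu) * px(i);
  for (int i = 0; i < NG; ++i)
    for (int j = 0; j < NG; ++j) {
      double p = P(i, j);
      if (p <= 0) { pxy_sum(i + j) += 0; continue; }
      asm_ += p * p;
      con += (i - j) * (i - j) * p;
      idm += p / (1.0 + (i - j) * (i - j));
      ent -= p * std::log(p);
      corr_num += (i + 1) * (j + 1) * p;
      var_ += (i + 1 - mu) * (i + 1 - mu) * p;
      pxy_sum(i + j) += p;
      pxy_diff(std::abs(i - j)) += p;
    }
  double corr = sig2 > 1e-12 ? (corr_num - mu * mu) / sig2 : 0.0;
  double savg = 0, svar = 0, sent = 0;
  for (int k = 0; k < 2 * NG - 1; ++k) {
    double p = pxy_sum(k);
    if (p > 0) { savg += (k + 2) * p; sent -= p * std::log(p); }
  }
  for (int k = 0; k < 2 * NG - 1; ++k) {
    double p = pxy_sum(k);
    if (p > 0) svar += (k + 2 - savg) * (k + 2 - savg) * p;
  }
  double davg = 0, dvar = 0, dent = 0;
  for (int k = 0; k < NG; ++k) {
    double p = pxy_diff(k);
    if (p > 0) { davg += k * p; dent -= p * std::log(p); }
  }
  for (int k = 0; k < NG; ++k) {
    double p = pxy_diff(k);
    if (p > 0) dvar += (k - davg) * (k - davg) * p;
  }
  // information measures of correlation (marginals equal: HX = HY)
  double hx = 0;
  for (int i = 0; i < NG; ++i)
    if (px(i) > 0) hx -= px(i) * std::log(px(i));
  double hxy1 = 0, hxy2 = 0;
  for (int i = 0; i < NG; ++i)
    for (int j = 0; j < NG; ++j) {
      double q = px(i) * px(j);
      if (q > 0) {
        if (P(i, j) > 0) hxy1 -= P(i, j) * std::log(q);
        hxy2 -= q * std::log(q);
      }
    }
  double f12 = hx > 1e-12 ? (ent - hxy1) / hx : 0.0;
  double e2 = 1.0 - std::exp(-2.0 * (hxy2 - ent));
  double f13 = e2 > 0 ? std::sqrt(e2) : 0.0;
  out[0] = asm_; out[1] = con; out[2] = corr; out[3] = var_; out[4] = idm;
  out[5] = savg; out[6] = svar; out[7] = sent; out[8] = ent; out[9] = dvar;
  out[10] = dent; out[11] = f12; out[12] = f13;
}

// [[Rcpp::export]]
NumericVector cpp_engineered_features(NumericVector crop) {
  IntegerVector d = crop.attr("dim");
  if (d[0] != H || d[1] != W || d[2] != 5)
    stop("crop must be 75 x 75 x 5");
  arma::cube C(crop.begin(), H, W, 5, false);
  arma::umat mask(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) mask(y, x) = C(y, x, 4) > 0.5 ? 1 : 0;
  int area = arma::accu(mask);
  if (area == 0) stop("degenerate cell: empty mask");

  NumericVector out(368);
  int pos = 0;

  // ---- shape -------------------------------------------------------------
  std::vector<int> ys, xs;
  ys.reserve(area); xs.reserve(area);
  int perim = 0;
  int ymin = H, ymax = -1, xmin = W, xmax = -1;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (mask(y, x)) {
        ys.push_back(y); xs.push_back(x);
        if (y < ymin) ymin = y;
        if (y > ymax) ymax = y;
        if (x < xmin) xmin = x;
        if (x > xmax) xmax = x;
        bool edge = y == 0 || y == H - 1 || x == 0 || x == W - 1;
        if (edge || !mask(y - 1, x) || !mask(y + 1, x) ||
            !mask(y, x - 1) || !mask(y, x + 1))
          ++perim;
      }
  double cy = 0, cx = 0;
  for (int i = 0; i < area; ++i) { cy += ys[i]; cx += xs[i]; }
  cy /= area; cx /= area;
  double mu20 = 0, mu02 = 0, mu11 = 0;
  for (int i = 0; i < area; ++i) {
    double dy = ys[i] - cy, dx = xs[i] - cx;
    mu20 += dy * dy; mu02 += dx * dx; mu11 += dy * dx;
  }
  mu20 /= area; mu02 /= area; mu11 /= area;
  double common = std::sqrt(std::pow(mu20 - mu02, 2) + 4 * mu11 * mu11);
  double l1 = (mu20 + mu02 + common) / 2.0, l2 = (mu20 + mu02 - common) / 2.0;
  if (l2 < 0) l2 = 0;
  double ecc = l1 > 1e-12 ? std::sqrt(std::max(0.0, 1.0 - l2 / l1)) : 0.0;
  double major = 4.0 * std::sqrt(l1), minor = 4.0 * std::sqrt(l2);
  // convex hull (monotone chain) of pixel centres for solidity
  std::vector<std::pair<int, int>> pts(area);
  for (int i = 0; i < area; ++i) pts[i] = {xs[i], ys[i]};
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  auto cross = [](const std::pair<int, int> &o, const std::pair<int, int> &a,
                  const std::pair<int, int> &b) {
    return (double)(a.first - o.first) * (b.second - o.second) -
           (double)(a.second - o.second) * (b.first - o.first);
  };
  int np = pts.size();
  std::vector<std::pair<int, int>> hull(2 * np);
  int k = 0;
  for (int i = 0; i < np; ++i) {
    while (k >= 2 && cross(hull[k - 2], hull[k - 1], pts[i]) <= 0) k--;
    hull[k++] = pts[i];
  }
  int lower = k + 1;
  for (int i = np - 2; i >= 0; --i) {
    while (k >= lower && cross(hull[k - 2], hull[k - 1], pts[i]) <= 0) k--;
    hull[k++] = pts[i];
  }
  hull.resize(k > 1 ? k - 1 : k);
  double harea = 0, hper = 0;
  int nh = hull.size();
  for (int i = 0; i < nh; ++i) {
    int j = (i + 1) % nh;
    harea += (double)hull[i].first * hull[j].second -
             (double)hull[j].first * hull[i].second;
    double ddx = hull[j].first - hull[i].first,
           ddy = hull[j].second - hull[i].second;
    hper += std::sqrt(ddx * ddx + ddy * ddy);
  }
  harea = std::fabs(harea) / 2.0 + hper / 2.0 + 1.0;  // Pick-style pixel-area
  double solidity = std::min(1.0, area / std::max(harea, 1.0));
  double extent = (double)area / ((ymax - ymin + 1.0) * (xmax - xmin + 1.0));
  double eqd = 2.0 * std::sqrt(area / M_PI);
  out[pos++] = area; out[pos++] = perim; out[pos++] = ecc;
  out[pos++] = major; out[pos++] = minor; out[pos++] = solidity;
  out[pos++] = extent; out[pos++] = eqd;

  // ---- mask globals ------------------------------------------------------
  out[pos++] = perim / (2.0 * std::sqrt(M_PI * area));
  double ctr = (H - 1) / 2.0;
  out[pos++] = std::sqrt((cy - ctr) * (cy - ctr) + (cx - ctr) * (cx - ctr));

  // normalized channel planes and masked value lists
  std::vector<arma::mat> chan(4);
  std::vector<std::vector<double>> vals(10);
  for (int c = 0; c < 4; ++c) {
    chan[c] = C.slice(c) / 65535.0;
    vals[c].reserve(area);
    for (int i = 0; i < area; ++i) vals[c].push_back(chan[c](ys[i], xs[i]));
  }
  int pair_a[6] = {0, 0, 0, 1, 1, 2}, pair_b[6] = {1, 2, 3, 2, 3, 3};
  for (int p = 0; p < 6; ++p) {
    vals[4 + p].reserve(area);
    for (int i = 0; i < area; ++i)
      vals[4 + p].push_back(vals[pair_a[p]][i] * vals[pair_b[p]][i]);
  }

  // ---- |weighted-centroid offsets| ---------------------------------------
  for (int c = 0; c < 4; ++c) {
    double sw = 0, swy = 0, swx = 0;
    for (int i = 0; i < area; ++i) {
      double w = vals[c][i];
      sw += w; swy += w * ys[i]; swx += w * xs[i];
    }
    if (sw > 1e-12) {
      out[pos++] = std::fabs(swy / sw - cy);
      out[pos++] = std::fabs(swx / sw - cx);
    } else {
      out[pos++] = 0; out[pos++] = 0;
    }
  }

  // ---- intensity statistics ----------------------------------------------
  for (int im = 0; im < 10; ++im) {
    intensity_stats(vals[im], &out[pos]);
    pos += 12;
  }

  // ---- Haralick ----------------------------------------------------------
  for (int c = 0; c < 4; ++c)
    for (int s = 1; s <= 2; ++s) {
      haralick13(chan[c], mask, s, &out[pos]);
      pos += 13;
    }
  for (int p = 0; p < 6; ++p) {
    arma::mat prod = chan[pair_a[p]] % chan[pair_b[p]];
    haralick13(prod, mask, 1, &out[pos]);
    pos += 13;
  }

  // ---- gradient magnitude ------------------------------------------------
  for (int c = 0; c < 4; ++c) {
    std::vector<double> gm(area);
    const arma::mat &im = chan[c];
    for (int i = 0; i < area; ++i) {
      int y = ys[i], x = xs[i];
      int ym = y > 0 ? y - 1 : y, yp = y < H - 1 ? y + 1 : y;
      int xm = x > 0 ? x - 1 : x, xp = x < W - 1 ? x + 1 : x;
      double gy = (im(yp, x) - im(ym, x)) / 2.0;
      double gx = (im(y, xp) - im(y, xm)) / 2.0;
      gm[i] = std::sqrt(gy * gy + gx * gx);
    }
    intensity_stats(gm, &out[pos]);
    pos += 12;
  }

  if (pos != 368) stop("internal error: feature layout mismatch");
  for (int i = 0; i < 368; ++i)
    if (!std::isfinite(out[i])) out[i] = 0.0;
  return out;
}
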