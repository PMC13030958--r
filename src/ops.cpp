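// Low-level image primitives: separable / dense convolution with symmetric
// boundary reflection, bilinear & nearest resizing, majority label filtering,
// morphological thinning, and 4-connected distance-to-background transforms.
// All routines operate on R matrices (rows = y, cols = x), column-major.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// symmetric reflection (edge pixel included: a b c d | d c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_sepconv2(const NumericMatrix& img,
                           const NumericVector& ky,
                           const NumericVector& kx) {
  const int H = img.nrow(), W = img.ncol();
  const int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // convolve columns (y direction)
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int t = -ry; t <= ry; ++t)
        acc += ky[t + ry] * img(reflect_idx(y + t, H), x);
      tmp(y, x) = acc;
    }
  }
  // convolve rows (x direction)
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int t = -rx; t <= rx; ++t)
        acc += kx[t + rx] * tmp(y, reflect_idx(x + t, W));
      out(y, x) = acc;
    }
  }
  return out;
}

// Dense 2D convolution (correlation with centered kernel), symmetric reflect.
// Used by the toy CNN backbone; kernel is (kh x kw).
// [[Rcpp::export]]
NumericMatrix cpp_conv2(const NumericMatrix& img, const NumericMatrix& ker) {
  const int H = img.nrow(), W = img.ncol();
  const int rh = (ker.nrow() - 1) / 2, rw = (ker.ncol() - 1) / 2;
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int a = -rh; a <= rh; ++a)
        for (int b = -rw; b <= rw; ++b)
          acc += ker(a + rh, b + rw) * img(reflect_idx(y + a, H), reflect_idx(x + b, W));
      out(y, x) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericMatrix out(Ho, Wo);
  for (int x = 0; x < Wo; ++x)
    for (int y = 0; y < Ho; ++y) {
      double m = img(2 * y, 2 * x);
      if (2 * y + 1 < H) m = std::max(m, img(2 * y + 1, 2 * x));
      if (2 * x + 1 < W) m = std::max(m, img(2 * y, 2 * x + 1));
      if (2 * y + 1 < H && 2 * x + 1 < W) m = std::max(m, img(2 * y + 1, 2 * x + 1));
      out(y, x) = m;
    }
  return out;
}

// Bilinear resize with half-pixel centers (matches the usual image convention).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int x = 0; x < out_w; ++x) {
    double fx = (x + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(std::max(x0 + 1, 0), W - 1);
    for (int y = 0; y < out_h; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(std::max(y0 + 1, 0), H - 1);
      out(y, x) =
        (1 - wy) * ((1 - wx) * img(y0c, x0c) + wx * img(y0c, x1c)) +
        wy       * ((1 - wx) * img(y1c, x0c) + wx * img(y1c, x1c));
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_resize_nearest(const IntegerMatrix& img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int x = 0; x < out_w; ++x) {
    int xs = std::min((int)std::floor((x + 0.5) * sx), W - 1);
    for (int y = 0; y < out_h; ++y) {
      int ys = std::min((int)std::floor((y + 0.5) * sy), H - 1);
      out(y, x) = img(ys, xs);
    }
  }
  return out;
}

// Modal label in a (2r+1)^2 window; ties keep the center pixel's label.
// [[Rcpp::export]]
IntegerMatrix cpp_majority_filter(const IntegerMatrix& lab, int radius) {
  const int H = lab.nrow(), W = lab.ncol();
  int maxlab = 0;
  for (int i = 0; i < H * W; ++i) maxlab = std::max(maxlab, lab[i]);
  IntegerMatrix out(H, W);
  std::vector<int> cnt(maxlab + 1);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int a = std::max(0, y - radius); a <= std::min(H - 1, y + radius); ++a)
        for (int b = std::max(0, x - radius); b <= std::min(W - 1, x + radius); ++b)
          ++cnt[lab(a, b)];
      int center = lab(y, x);
      int best = center, bestn = cnt[center];
      for (int c = 0; c <= maxlab; ++c)
        if (cnt[c] > bestn) { best = c; bestn = cnt[c]; }
      out(y, x) = best;
    }
  return out;
}

// Zhang-Suen thinning to a 1-px skeleton. Input/output: 0/1 integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix im = clone(mask);
  auto at = [&](int y, int x) -> int {
    if (y < 0 || y >= H || x < 0 || x >= W) return 0;
    return im(y, x) != 0;
  };
  bool changed = true;
  std::vector<std::pair<int,int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y) {
          if (!at(y, x)) continue;
          int p2 = at(y-1,x), p3 = at(y-1,x+1), p4 = at(y,x+1), p5 = at(y+1,x+1);
          int p6 = at(y+1,x), p7 = at(y+1,x-1), p8 = at(y,x-1), p9 = at(y-1,x-1);
          int B = p2+p3+p4+p5+p6+p7+p8+p9;
          if (B < 2 || B > 6) continue;
          int A = (p2==0&&p3==1)+(p3==0&&p4==1)+(p4==0&&p5==1)+(p5==0&&p6==1)
                + (p6==0&&p7==1)+(p7==0&&p8==1)+(p8==0&&p9==1)+(p9==0&&p2==1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
          } else {
            if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
          }
          del.push_back({y, x});
        }
      for (auto& p : del) im(p.first, p.second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return im;
}

// 4-connected distance (in steps) from each foreground pixel to the nearest
// background pixel; pixels outside the image count as background. Background
// pixels get 0; unreachable foreground (none with 4-connectivity) gets -1.
// [[Rcpp::export]]
IntegerMatrix cpp_dist_to_background(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix d(H, W);
  std::queue<int> q;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0) { d(y, x) = 0; q.push(y * W + x); }
      else if (y == 0 || y == H - 1 || x == 0 || x == W - 1) {
        d(y, x) = 1; q.push(y * W + x);   // border foreground touches outside
      } else d(y, x) = -1;
    }
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int y = v / W, x = v % W;
    for (int k = 0; k < 4; ++k) {
      int ny = y + dy[k], nx = x + dx[k];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      if (d(ny, nx) == -1) { d(ny, nx) = d(y, x) + 1; q.push(ny * W + nx); }
    }
  }
  return d;
}

// Steepest-descent 4-connected path from (y0, x0) (1-based) down the distance
// field until distance 1 (adjacent to background). Returns n x 2 matrix of
// 1-based (y, x) path pixels, strictly inside the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_descend_path(const IntegerMatrix& dist, int y0, int x0) {
  const int H = dist.nrow(), W = dist.ncol();
  int y = y0 - 1, x = x0 - 1;
  std::vector<int> ys, xs;
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  while (true) {
    ys.push_back(y + 1); xs.push_back(x + 1);
    int cur = dist(y, x);
    if (cur <= 1) break;
    int by = -1, bx = -1, bd = cur;
    for (int k = 0; k < 4; ++k) {
      int ny = y + dy[k], nx = x + dx[k];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      if (dist(ny, nx) >= 1 && dist(ny, nx) < bd) { bd = dist(ny, nx); by = ny; bx = nx; }
    }
    if (by < 0) break;   // plateau; should not happen for BFS distances
    y = by; x = bx;
  }
  IntegerMatrix out(ys.size(), 2);
  for (size_t i = 0; i < ys.size(); ++i) { out(i, 0) = ys[i]; out(i, 1) = xs[i]; }
  return out;
}
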