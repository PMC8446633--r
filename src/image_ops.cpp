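// Low-level raster operations: interpolating resize/warp, bilateral filter,
// connected-component labeling, and the anisotropic nearest-seed tessellation
// used by the synthetic micrograph generator.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Keys cubic convolution kernel, a = -0.5 (the classic "cubic" interpolant).
static inline double cubic_w(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t < 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0) return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// method: 0 = nearest, 1 = bilinear, 2 = cubic. Pixel-center alignment:
// src = (dst + 0.5) * scale - 0.5.
// [[Rcpp::export(name = ".cpp_resize_mat")]]
NumericMatrix cpp_resize_mat(NumericMatrix img, int oh, int ow, int method) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int x = 0; x < ow; ++x) {
    double fx = (x + 0.5) * sx - 0.5;
    for (int y = 0; y < oh; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      double v = 0.0;
      if (method == 0) {
        int iy = clampi((int)std::floor(fy + 0.5), 0, H - 1);
        int ix = clampi((int)std::floor(fx + 0.5), 0, W - 1);
        v = img(iy, ix);
      } else if (method == 1) {
        int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
        double dy = fy - y0, dx = fx - x0;
        int y1 = clampi(y0 + 1, 0, H - 1), x1 = clampi(x0 + 1, 0, W - 1);
        y0 = clampi(y0, 0, H - 1); x0 = clampi(x0, 0, W - 1);
        v = (1 - dy) * ((1 - dx) * img(y0, x0) + dx * img(y0, x1)) +
            dy * ((1 - dx) * img(y1, x0) + dx * img(y1, x1));
      } else {
        int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
        double acc = 0.0, wsum = 0.0;
        for (int j = -1; j <= 2; ++j) {
          double wy = cubic_w(fy - (y0 + j));
          if (wy == 0.0) continue;
          int yy = clampi(y0 + j, 0, H - 1);
          for (int i = -1; i <= 2; ++i) {
            double wx = cubic_w(fx - (x0 + i));
            if (wx == 0.0) continue;
            int xx = clampi(x0 + i, 0, W - 1);
            acc += wy * wx * img(yy, xx);
            wsum += wy * wx;
          }
        }
        v = acc / wsum;
      }
      out(y, x) = v;
    }
  }
  return out;
}

// Inverse-mapped affine warp: for output pixel (x, y) [0-based, pixel centers],
// source position = Minv %*% c(x, y, 1). method 0 = nearest, 1 = bilinear.
// [[Rcpp::export(name = ".cpp_warp_affine_mat")]]
NumericMatrix cpp_warp_affine_mat(NumericMatrix img, NumericMatrix minv,
                                  int oh, int ow, int method, double fill) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  for (int x = 0; x < ow; ++x) {
    for (int y = 0; y < oh; ++y) {
      double fx = minv(0, 0) * x + minv(0, 1) * y + minv(0, 2);
      double fy = minv(1, 0) * x + minv(1, 1) * y + minv(1, 2);
      double v;
      if (method == 0) {
        int iy = (int)std::floor(fy + 0.5), ix = (int)std::floor(fx + 0.5);
        v = (iy < 0 || iy >= H || ix < 0 || ix >= W) ? fill : img(iy, ix);
      } else {
        int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
        if (y0 < -1 || y0 > H - 1 || x0 < -1 || x0 > W - 1) {
          v = fill;
        } else {
          double dy = fy - y0, dx = fx - x0;
          double v00 = (y0 < 0 || x0 < 0) ? fill : img(y0, x0);
          double v01 = (y0 < 0 || x0 + 1 >= W) ? fill : img(y0, x0 + 1);
          double v10 = (y0 + 1 >= H || x0 < 0) ? fill : img(y0 + 1, x0);
          double v11 = (y0 + 1 >= H || x0 + 1 >= W) ? fill : img(y0 + 1, x0 + 1);
          v = (1 - dy) * ((1 - dx) * v00 + dx * v01) +
              dy * ((1 - dx) * v10 + dx * v11);
        }
      }
      out(y, x) = v;
    }
  }
  return out;
}

// Edge-preserving bilateral filter: spatial Gaussian x range Gaussian over a
// (2r+1)^2 window, normalized.
// [[Rcpp::export(name = ".cpp_bilateral_mat")]]
NumericMatrix cpp_bilateral_mat(NumericMatrix img, int radius,
                                double sigma_range, double sigma_space) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  int side = 2 * radius + 1;
  std::vector<double> sw(side * side);
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      sw[(dy + radius) * side + (dx + radius)] =
          std::exp(-(dx * dx + dy * dy) / (2.0 * sigma_space * sigma_space));
  double inv2sr2 = 1.0 / (2.0 * sigma_range * sigma_range);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double c = img(y, x), acc = 0.0, wsum = 0.0;
      for (int dx = -radius; dx <= radius; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= W) continue;
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= H) continue;
          double d = img(yy, xx) - c;
          double w = sw[(dy + radius) * side + (dx + radius)] *
                     std::exp(-d * d * inv2sr2);
          acc += w * img(yy, xx);
          wsum += w;
        }
      }
      out(y, x) = acc / wsum;
    }
  }
  return out;
}

// Label connected foreground (value 1) components; connectivity 4 or 8.
// Labels are contiguous 1..K in raster-scan discovery order.
// [[Rcpp::export(name = ".cpp_label_mat")]]
IntegerMatrix cpp_label_mat(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nn = (connectivity == 8) ? 8 : 4;
  const int* ddx = (connectivity == 8) ? dx8 : dx4;
  const int* ddy = (connectivity == 8) ? dy8 : dy4;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) != 1 || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(x * H + y);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int px = p / H, py = p % H;
        for (int k = 0; k < nn; ++k) {
          int qx = px + ddx[k], qy = py + ddy[k];
          if (qx < 0 || qx >= W || qy < 0 || qy >= H) continue;
          if (mask(qy, qx) == 1 && lab(qy, qx) == 0) {
            lab(qy, qx) = next;
            stack.push_back(qx * H + qy);
          }
        }
      }
    }
  }
  return lab;
}

// Anisotropic nearest-seed tessellation. Distance between pixel p and seed s is
// sqrt(((px-sx)/elong)^2 + (py-sy)^2), so cells stretch along x by `elong`.
// Returns the per-pixel region id (1-based) and a wall mask marking pixels
// within Chebyshev radius `rad` of a region boundary.
// [[Rcpp::export(name = ".cpp_voronoi_scene")]]
List cpp_voronoi_scene(int H, int W, NumericVector sx, NumericVector sy,
                       double elong, int rad) {
  int n = sx.size();
  IntegerMatrix region(H, W);
  double inv_e2 = 1.0 / (elong * elong);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double best = R_PosInf; int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dx = x - sx[i], dy = y - sy[i];
        double d = dx * dx * inv_e2 + dy * dy;
        if (d < best) { best = d; bi = i; }
      }
      region(y, x) = bi + 1;
    }
  }
  LogicalMatrix wall(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int id = region(y, x);
      bool w = false;
      for (int dx = -rad; dx <= rad && !w; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= W) continue;
        for (int dy = -rad; dy <= rad; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= H) continue;
          if (region(yy, xx) != id) { w = true; break; }
        }
      }
      wall(y, x) = w;
    }
  }
  return List::create(_["region"] = region, _["wall"] = wall);
}
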