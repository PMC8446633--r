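// Compact CPU conv-net engine backing the stomata detector and the
// U-Net-style cell-wall segmenter: 3x3 convolutions via im2col + GEMM
// (single precision, Armadillo), 2x2 max-pooling, nearest-neighbour
// upsampling with skip concatenation, residual backbone blocks, softmax /
// smooth-L1 detector loss and pixelwise binary cross-entropy, with
// hand-derived backward passes. Parameters travel as flat R lists of
// (weight matrix, bias vector) pairs in a fixed architecture order.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
using namespace Rcpp;
using namespace arma;

static fcube cube_from_r(NumericVector a) {
  IntegerVector d = a.attr("dim");
  int H = d[0], W = d[1], C = (d.size() > 2) ? d[2] : 1;
  fcube x(H, W, C);
  const double* p = a.begin();
  for (uword i = 0; i < x.n_elem; ++i) x(i) = (float)p[i];
  return x;
}

struct ConvP { fmat W; fvec b; };

static std::vector<ConvP> load_params(List params) {
  std::vector<ConvP> v;
  for (int i = 0; i + 1 < params.size(); i += 2) {
    NumericMatrix wm = params[i];
    NumericVector bv = params[i + 1];
    fmat W(wm.nrow(), wm.ncol());
    for (uword k = 0; k < W.n_elem; ++k) W(k) = (float)wm[k];
    fvec b(bv.size());
    for (int k = 0; k < bv.size(); ++k) b(k) = (float)bv[k];
    v.push_back({std::move(W), std::move(b)});
  }
  return v;
}

struct GradStore {
  std::vector<fmat> dW;
  std::vector<fvec> db;
  void init(const std::vector<ConvP>& p) {
    for (auto& c : p) {
      dW.push_back(fmat(c.W.n_rows, c.W.n_cols, fill::zeros));
      db.push_back(fvec(c.b.n_elem, fill::zeros));
    }
  }
  List to_r() const {
    List out(2 * dW.size());
    for (size_t i = 0; i < dW.size(); ++i) {
      NumericMatrix wm(dW[i].n_rows, dW[i].n_cols);
      for (uword k = 0; k < dW[i].n_elem; ++k) wm[k] = dW[i](k);
      NumericVector bv(db[i].n_elem);
      for (uword k = 0; k < db[i].n_elem; ++k) bv[k] = db[i](k);
      out[2 * i] = wm;
      out[2 * i + 1] = bv;
    }
    return out;
  }
};

// im2col for 3x3 kernels, zero padding 1, in transposed layout:
// (H*W) x (C*9) with pixel index x*H + y (column-major pixel order,
// matching R array layout), so inner copies are contiguous column runs.
static fmat im2col3(const fcube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat At((uword)H * W, C * 9, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* xs = x.slice_memptr(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int k = c * 9 + (dy + 1) * 3 + (dx + 1);
        float* col = At.colptr(k);
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        int len = y1 - y0;
        if (len <= 0) continue;
        for (int xx = 0; xx < W; ++xx) {
          int sx = xx + dx;
          if (sx < 0 || sx >= W) continue;
          std::memcpy(col + (uword)xx * H + y0,
                      xs + (uword)sx * H + y0 + dy, len * sizeof(float));
        }
      }
    }
  }
  return At;
}

// scatter-add of a (H*W) x (C*9) gradient back onto the input grid
static fcube col2im3(const fmat& dAt, int H, int W, int C) {
  fcube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* xs = dx.slice_memptr(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dxk = -1; dxk <= 1; ++dxk) {
        int k = c * 9 + (dy + 1) * 3 + (dxk + 1);
        const float* col = dAt.colptr(k);
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int xx = 0; xx < W; ++xx) {
          int sx = xx + dxk;
          if (sx < 0 || sx >= W) continue;
          float* dst = xs + (uword)sx * H + y0 + dy;
          const float* src = col + (uword)xx * H + y0;
          for (int yy = 0; yy < y1 - y0; ++yy) dst[yy] += src[yy];
        }
      }
    }
  }
  return dx;
}

static fcube conv3_fwd(const fcube& x, const ConvP& p) {
  int H = x.n_rows, W = x.n_cols;
  int Cout = p.W.n_rows;
  fcube out(H, W, Cout);
  fmat At = im2col3(x);
  fmat Ym(out.memptr(), (uword)H * W, Cout, false, true);
  Ym = At * p.W.t();
  Ym.each_row() += p.b.t();
  return out;
}

static fcube conv3_bwd(const fcube& x, const ConvP& p, const fcube& dout,
                       fmat& dW, fvec& db) {
  int H = x.n_rows, W = x.n_cols;
  fmat At = im2col3(x);
  const fmat dYm(const_cast<float*>(dout.memptr()), (uword)H * W,
                 dout.n_slices, false, true);
  dW += dYm.t() * At;
  db += sum(dYm, 0).t();
  fmat dAt = dYm * p.W;
  return col2im3(dAt, H, W, x.n_slices);
}

static fcube conv1_fwd(const fcube& x, const ConvP& p) {
  int H = x.n_rows, W = x.n_cols;
  int Cout = p.W.n_rows;
  const fmat Xm(const_cast<float*>(x.memptr()), (uword)H * W, x.n_slices,
                false, true);
  fcube out(H, W, Cout);
  fmat Ym(out.memptr(), (uword)H * W, Cout, false, true);
  Ym = Xm * p.W.t();
  Ym.each_row() += p.b.t();
  return out;
}

static fcube conv1_bwd(const fcube& x, const ConvP& p, const fcube& dout,
                       fmat& dW, fvec& db) {
  int H = x.n_rows, W = x.n_cols;
  const fmat Xm(const_cast<float*>(x.memptr()), (uword)H * W, x.n_slices,
                false, true);
  const fmat dYm(const_cast<float*>(dout.memptr()), (uword)H * W,
                 dout.n_slices, false, true);
  dW += dYm.t() * Xm;
  db += sum(dYm, 0).t();
  fcube dx(H, W, x.n_slices);
  fmat dXm(dx.memptr(), (uword)H * W, x.n_slices, false, true);
  dXm = dYm * p.W;
  return dx;
}

static void relu_(fcube& x) {
  x.transform([](float v) { return v > 0 ? v : 0.f; });
}

static fcube relu_bwd(const fcube& out, const fcube& dout) {
  fcube d = dout;
  for (uword i = 0; i < d.n_elem; ++i) if (out(i) <= 0) d(i) = 0;
  return d;
}

static fcube maxpool2(const fcube& x, ucube& amax) {
  int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  fcube out(H, W, C);
  amax.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const fmat& xs = x.slice(c);
    for (int xx = 0; xx < W; ++xx) {
      for (int yy = 0; yy < H; ++yy) {
        float best = -1e30f; uword bi = 0;
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j) {
            uword idx = (uword)xs.n_rows * (2 * xx + i) + (2 * yy + j);
            float v = xs(idx);
            if (v > best) { best = v; bi = idx; }
          }
        out(yy, xx, c) = best;
        amax(yy, xx, c) = bi;
      }
    }
  }
  return out;
}

static fcube maxpool2_bwd(const fcube& dout, const ucube& amax, int H, int W) {
  int C = dout.n_slices;
  fcube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword k = 0; k < dout.slice(c).n_elem; ++k)
      dx.slice(c)(amax.slice(c)(k)) += dout.slice(c)(k);
  return dx;
}

static fcube upsample2(const fcube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fcube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int xx = 0; xx < 2 * W; ++xx)
      for (int yy = 0; yy < 2 * H; ++yy)
        out(yy, xx, c) = x(yy / 2, xx / 2, c);
  return out;
}

static fcube upsample2_bwd(const fcube& dout) {
  int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  fcube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int xx = 0; xx < (int)dout.n_cols; ++xx)
      for (int yy = 0; yy < (int)dout.n_rows; ++yy)
        dx(yy / 2, xx / 2, c) += dout(yy, xx, c);
  return dx;
}

static fcube concat_c(const fcube& a, const fcube& b) {
  fcube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, out.n_slices - 1) = b;
  return out;
}

// ---------------- U-Net-style segmenter ----------------
// Parameter order: enc levels 0..D-1 (conv1, conv2), bottleneck (conv1,
// conv2), dec levels D-1..0 (conv1, conv2), output 1x1 conv. Level l has
// width*2^l channels; bottleneck width*2^D.

struct UnetCache {
  std::vector<fcube> enc_in, enc_mid, enc_out;
  std::vector<ucube> amax;
  fcube bot_in, bot_mid, bot_out;
  std::vector<fcube> dec_cat, dec_mid, dec_out;
  fcube prob;
};

static void unet_forward(const std::vector<ConvP>& P, const fcube& x,
                         int depth, UnetCache& C) {
  int pi = 0;
  fcube cur = x;
  C.enc_in.resize(depth); C.enc_mid.resize(depth); C.enc_out.resize(depth);
  C.amax.resize(depth);
  C.dec_cat.resize(depth); C.dec_mid.resize(depth); C.dec_out.resize(depth);
  for (int l = 0; l < depth; ++l) {
    C.enc_in[l] = cur;
    fcube a = conv3_fwd(cur, P[pi++]); relu_(a); C.enc_mid[l] = a;
    fcube b = conv3_fwd(a, P[pi++]); relu_(b); C.enc_out[l] = b;
    cur = maxpool2(b, C.amax[l]);
  }
  C.bot_in = cur;
  fcube b1 = conv3_fwd(cur, P[pi++]); relu_(b1); C.bot_mid = b1;
  fcube b2 = conv3_fwd(b1, P[pi++]); relu_(b2); C.bot_out = b2;
  cur = b2;
  for (int l = depth - 1; l >= 0; --l) {
    fcube up = upsample2(cur);
    fcube cat = concat_c(up, C.enc_out[l]);
    C.dec_cat[l] = cat;
    fcube d1 = conv3_fwd(cat, P[pi++]); relu_(d1); C.dec_mid[l] = d1;
    fcube d2 = conv3_fwd(d1, P[pi++]); relu_(d2); C.dec_out[l] = d2;
    cur = d2;
  }
  C.prob = conv1_fwd(cur, P[pi++]);
  C.prob.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
}

// [[Rcpp::export(name = ".cpp_unet_infer")]]
NumericMatrix cpp_unet_infer(List params, NumericVector x_, int depth) {
  std::vector<ConvP> P = load_params(params);
  fcube x = cube_from_r(x_);
  UnetCache C;
  unet_forward(P, x, depth, C);
  NumericMatrix out(C.prob.n_rows, C.prob.n_cols);
  for (uword k = 0; k < C.prob.slice(0).n_elem; ++k) out[k] = C.prob.slice(0)(k);
  return out;
}

// One training example: forward, pixelwise BCE, full backward.
// Parameter index map (D = depth): enc l -> 2l, 2l+1; bottleneck -> 2D,
// 2D+1; dec level l -> 2D+2+2*(D-1-l) (+1); output conv -> 4D+2.
// [[Rcpp::export(name = ".cpp_unet_step")]]
List cpp_unet_step(List params, NumericVector x_, NumericMatrix y_, int depth) {
  std::vector<ConvP> P = load_params(params);
  fcube x = cube_from_r(x_);
  UnetCache C;
  unet_forward(P, x, depth, C);
  int H = C.prob.n_rows, W = C.prob.n_cols;
  double N = (double)H * W;
  const float eps = 1e-7f;
  double loss = 0.0;
  fcube dlogit(H, W, 1);
  for (int xx = 0; xx < W; ++xx) {
    for (int yy = 0; yy < H; ++yy) {
      float p = C.prob(yy, xx, 0);
      float pc = std::min(std::max(p, eps), 1.0f - eps);
      float y = (float)y_(yy, xx);
      loss += -(y * std::log(pc) + (1.0f - y) * std::log(1.0f - pc));
      dlogit(yy, xx, 0) = (p - y) / N;  // sigmoid+BCE fused gradient
    }
  }
  loss /= N;

  GradStore G; G.init(P);
  int D = depth;
  int i_out = 4 * D + 2;
  fcube d = conv1_bwd(C.dec_out[0], P[i_out], dlogit, G.dW[i_out], G.db[i_out]);

  std::vector<fcube> skip_grad(D);
  for (int l = 0; l < D; ++l) {  // decoder levels, shallow to deep
    int i1 = 2 * D + 2 + 2 * (D - 1 - l), i2 = i1 + 1;
    d = relu_bwd(C.dec_out[l], d);
    d = conv3_bwd(C.dec_mid[l], P[i2], d, G.dW[i2], G.db[i2]);
    d = relu_bwd(C.dec_mid[l], d);
    d = conv3_bwd(C.dec_cat[l], P[i1], d, G.dW[i1], G.db[i1]);
    uword cu = C.dec_cat[l].n_slices - C.enc_out[l].n_slices;
    skip_grad[l] = d.slices(cu, d.n_slices - 1);
    d = upsample2_bwd(d.slices(0, cu - 1));
    C.dec_cat[l].reset(); C.dec_mid[l].reset(); C.dec_out[l].reset();
  }
  // d is now the gradient wrt bottleneck output
  d = relu_bwd(C.bot_out, d);
  d = conv3_bwd(C.bot_mid, P[2 * D + 1], d, G.dW[2 * D + 1], G.db[2 * D + 1]);
  d = relu_bwd(C.bot_mid, d);
  d = conv3_bwd(C.bot_in, P[2 * D], d, G.dW[2 * D], G.db[2 * D]);
  for (int l = D - 1; l >= 0; --l) {  // encoder levels, deep to shallow
    d = maxpool2_bwd(d, C.amax[l], C.enc_out[l].n_rows, C.enc_out[l].n_cols);
    d += skip_grad[l];
    d = relu_bwd(C.enc_out[l], d);
    d = conv3_bwd(C.enc_mid[l], P[2 * l + 1], d, G.dW[2 * l + 1], G.db[2 * l + 1]);
    d = relu_bwd(C.enc_mid[l], d);
    d = conv3_bwd(C.enc_in[l], P[2 * l], d, G.dW[2 * l], G.db[2 * l]);
  }
  return List::create(_["loss"] = loss, _["grads"] = G.to_r());
}

// ---------------- anchor-based stomata detector ----------------
// Backbone: residual blocks (conv3-ReLU, conv3 + identity, ReLU, maxpool2)
// with widths[l] channels; head: conv3-ReLU then 1x1 conv emitting, per
// anchor a of A, 2 class logits (slices 2a, 2a+1) followed by 4 box deltas
// (slices 2A + 4a..+3). Parameter order: block l (conv_a, conv_b), head_mid,
// head_out. Anchor id at feature cell (y, x): (x*Hp + y)*A + a, 0-based.

struct DetCache {
  std::vector<fcube> blk_in, blk_t, blk_u;
  std::vector<ucube> amax;
  fcube mid_in, mid, out;
};

static void det_forward(const std::vector<ConvP>& P, const fcube& x,
                        int nblocks, DetCache& C) {
  int pi = 0;
  fcube cur = x;
  C.blk_in.resize(nblocks); C.blk_t.resize(nblocks); C.blk_u.resize(nblocks);
  C.amax.resize(nblocks);
  for (int l = 0; l < nblocks; ++l) {
    C.blk_in[l] = cur;
    fcube t = conv3_fwd(cur, P[pi++]); relu_(t); C.blk_t[l] = t;
    fcube u = conv3_fwd(t, P[pi++]);
    u += t;                      // residual connection
    relu_(u); C.blk_u[l] = u;
    cur = maxpool2(u, C.amax[l]);
  }
  C.mid_in = cur;
  fcube m = conv3_fwd(cur, P[pi++]); relu_(m); C.mid = m;
  C.out = conv1_fwd(m, P[pi++]);
}

// [[Rcpp::export(name = ".cpp_det_forward")]]
NumericVector cpp_det_forward(List params, NumericVector x_, int nblocks) {
  std::vector<ConvP> P = load_params(params);
  fcube x = cube_from_r(x_);
  DetCache C;
  det_forward(P, x, nblocks, C);
  NumericVector out(C.out.n_elem);
  for (uword i = 0; i < C.out.n_elem; ++i) out[i] = C.out(i);
  out.attr("dim") = IntegerVector::create(C.out.n_rows, C.out.n_cols,
                                          C.out.n_slices);
  return out;
}

static inline double smoothl1(double v) {
  double a = std::fabs(v);
  return a < 1.0 ? 0.5 * v * v : a - 0.5;
}

// labels: per-anchor -1 (ignore) / 0 (background) / 1 (stoma); reg_t: 4 x
// n_anchors target deltas (used where label == 1). Loss follows the
// two-term detector objective: mean softmax CE over labeled anchors plus
// lambda * mean smooth-L1 over positive anchors (zero when no positives).
// [[Rcpp::export(name = ".cpp_det_step")]]
List cpp_det_step(List params, NumericVector x_, int nblocks, int A,
                  IntegerVector labels, NumericMatrix reg_t, double lambda) {
  std::vector<ConvP> P = load_params(params);
  fcube x = cube_from_r(x_);
  DetCache C;
  det_forward(P, x, nblocks, C);
  int Hp = C.out.n_rows, Wp = C.out.n_cols;

  int n_cls = 0, n_pos = 0;
  for (int i = 0; i < labels.size(); ++i) {
    if (labels[i] >= 0) ++n_cls;
    if (labels[i] == 1) ++n_pos;
  }
  double loss_cls = 0.0, loss_reg = 0.0;
  fcube dout(Hp, Wp, C.out.n_slices, fill::zeros);
  for (int xx = 0; xx < Wp; ++xx) {
    for (int yy = 0; yy < Hp; ++yy) {
      for (int a = 0; a < A; ++a) {
        int aid = (xx * Hp + yy) * A + a;
        int lab = labels[aid];
        if (lab >= 0 && n_cls > 0) {
          float l0 = C.out(yy, xx, 2 * a), l1 = C.out(yy, xx, 2 * a + 1);
          float m = std::max(l0, l1);
          double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m);
          double z = e0 + e1;
          double p1 = e1 / z;
          double pt = lab == 1 ? p1 : (1.0 - p1);
          loss_cls += -std::log(std::max(pt, 1e-12));
          dout(yy, xx, 2 * a) = ((1.0 - p1) - (lab == 0 ? 1.0 : 0.0)) / n_cls;
          dout(yy, xx, 2 * a + 1) = (p1 - (lab == 1 ? 1.0 : 0.0)) / n_cls;
        }
        if (lab == 1 && n_pos > 0) {
          for (int k = 0; k < 4; ++k) {
            double dlt = C.out(yy, xx, 2 * A + 4 * a + k) - reg_t(k, aid);
            loss_reg += smoothl1(dlt);
            double g = (std::fabs(dlt) < 1.0) ? dlt
                       : (dlt > 0 ? 1.0 : -1.0);
            dout(yy, xx, 2 * A + 4 * a + k) = lambda * g / n_pos;
          }
        }
      }
    }
  }
  if (n_cls > 0) loss_cls /= n_cls;
  loss_reg = (n_pos > 0) ? lambda * loss_reg / n_pos : 0.0;
  double loss = loss_cls + loss_reg;

  GradStore G; G.init(P);
  int np = (int)P.size();
  int ih = np - 1, im = np - 2;
  fcube d = conv1_bwd(C.mid, P[ih], dout, G.dW[ih], G.db[ih]);
  d = relu_bwd(C.mid, d);
  d = conv3_bwd(C.mid_in, P[im], d, G.dW[im], G.db[im]);
  for (int l = nblocks - 1; l >= 0; --l) {
    d = maxpool2_bwd(d, C.amax[l], C.blk_u[l].n_rows, C.blk_u[l].n_cols);
    d = relu_bwd(C.blk_u[l], d);
    fcube dt = conv3_bwd(C.blk_t[l], P[2 * l + 1], d, G.dW[2 * l + 1],
                         G.db[2 * l + 1]);
    dt += d;  // identity branch of the residual
    dt = relu_bwd(C.blk_t[l], dt);
    d = conv3_bwd(C.blk_in[l], P[2 * l], dt, G.dW[2 * l], G.db[2 * l]);
  }
  return List::create(_["loss"] = loss, _["loss_cls"] = loss_cls,
                      _["loss_reg"] = loss_reg, _["grads"] = G.to_r());
}
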