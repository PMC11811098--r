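// U-Net segmentation engine: forward, Dice loss, and hand-derived
// backpropagation. Channels-first cubes (H, W, C); convolutions are 3x3,
// stride 1, zero-padded, via im2col + BLAS gemm. Topology is the classic
// 4-level encoder/decoder with channel doubling, nearest-neighbour 2x2
// upsampling, skip concatenation and a final 1x1 pixel classifier. Each
// 3x3 convolution is followed by per-channel instance normalization (with
// learnable scale/shift) and a leaky-ReLU activation, which keeps Dice-loss
// training stable without batch statistics.
//
// Weights arrive from R as a flat list. Each 3x3 conv layer contributes
// [W (Cout x Cin*9), gamma (Cout), beta (Cout)]; the final 1x1 classifier
// contributes [W (1 x Cin), b (1)]. Layer order:
//   enc1a, enc1b, enc2a, enc2b, enc3a, enc3b, enc4a, enc4b,
//   bott_a, bott_b, dec4a, dec4b, dec3a, dec3b, dec2a, dec2b,
//   dec1a, dec1b, final
// All randomness (init, shuffling, augmentation) lives on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

const int DEPTH = 4;
const int NCONV = 2 * DEPTH + 2 + 2 * DEPTH + 1; // 19 (last one is 1x1)
const int NPAR = (NCONV - 1) * 3 + 2;            // flat weight-list length
const double LEAK = 0.01;
const double IN_EPS = 1e-5;

struct Conv {
  mat W;      // Cout x Cin*9 (final layer: 1 x Cin)
  vec g, b;   // instance-norm scale/shift (final layer: b = bias, g unused)
};

std::vector<Conv> parse_weights(const Rcpp::List& weights) {
  if (weights.size() != NPAR)
    Rcpp::stop("expected %d weight entries, got %d", NPAR,
               (int)weights.size());
  std::vector<Conv> layers(NCONV);
  int k = 0;
  for (int l = 0; l < NCONV - 1; ++l) {
    layers[l].W = Rcpp::as<mat>(weights[k++]);
    layers[l].g = Rcpp::as<vec>(weights[k++]);
    layers[l].b = Rcpp::as<vec>(weights[k++]);
  }
  layers[NCONV - 1].W = Rcpp::as<mat>(weights[k++]);
  layers[NCONV - 1].b = Rcpp::as<vec>(weights[k++]);
  return layers;
}

// im2col for a 3x3 zero-padded window. K is (C*9) x (H*W), pixel (i,j)
// lives in column j*H + i (column-major, matching arma cube layout).
void im2col3(const cube& x, mat& K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  K.zeros(C * 9, H * W);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int v = -1; v <= 1; ++v) {
      for (int u = -1; u <= 1; ++u) {
        const int krow = c * 9 + (u + 1) * 3 + (v + 1);
        for (int j = 0; j < W; ++j) {
          const int jj = j + v;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -u), i1 = std::min(H - 1, H - 1 - u);
          const double* src = xs.colptr(jj);
          for (int i = i0; i <= i1; ++i)
            K(krow, j * H + i) = src[i + u];
        }
      }
    }
  }
}

// Adjoint of im2col3: scatter-add dK back onto the input grid.
void col2im3(const mat& dK, int H, int W, int C, cube& dx) {
  dx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    mat& ds = dx.slice(c);
    for (int v = -1; v <= 1; ++v) {
      for (int u = -1; u <= 1; ++u) {
        const int krow = c * 9 + (u + 1) * 3 + (v + 1);
        for (int j = 0; j < W; ++j) {
          const int jj = j + v;
          if (jj < 0 || jj >= W) continue;
          double* dst = ds.colptr(jj);
          for (int i = std::max(0, -u); i <= std::min(H - 1, H - 1 - u); ++i)
            dst[i + u] += dK(krow, j * H + i);
        }
      }
    }
  }
}

inline cube mat_to_cube(const mat& m, int H, int W) {
  cube out(H, W, m.n_rows);
  for (uword c = 0; c < m.n_rows; ++c)
    out.slice(c) = reshape(m.row(c), H, W);
  return out;
}

inline mat cube_to_mat(const cube& x) {
  const int HW = x.n_rows * x.n_cols;
  mat m(x.n_slices, HW);
  for (uword c = 0; c < x.n_slices; ++c)
    m.row(c) = vectorise(x.slice(c)).t();
  return m;
}

struct ConvCache {
  mat K;       // im2col of the input
  mat zh;      // normalized pre-activation (Cout x HW)
  mat pre;     // post-affine pre-activation (for the leaky-ReLU mask)
  vec inv;     // 1 / sqrt(var + eps) per channel
  int H, W, Cin;
};

// conv -> instance norm -> leaky ReLU
cube conv_in_lrelu_fwd(const Conv& cv, const cube& x, ConvCache& cc) {
  cc.H = x.n_rows; cc.W = x.n_cols; cc.Cin = x.n_slices;
  im2col3(x, cc.K);
  mat z = cv.W * cc.K;
  const int HW = z.n_cols;
  cc.inv.set_size(z.n_rows);
  cc.zh.set_size(z.n_rows, HW);
  for (uword c = 0; c < z.n_rows; ++c) {
    const double mu = mean(z.row(c));
    const double va = accu(square(z.row(c) - mu)) / HW;
    cc.inv(c) = 1.0 / std::sqrt(va + IN_EPS);
    cc.zh.row(c) = (z.row(c) - mu) * cc.inv(c);
  }
  cc.pre = cc.zh.each_col() % cv.g;
  cc.pre.each_col() += cv.b;
  mat act = cc.pre;
  act.transform([](double v) { return v > 0 ? v : LEAK * v; });
  return mat_to_cube(act, cc.H, cc.W);
}

// Backward through leaky ReLU + instance norm + conv. Returns gradient
// w.r.t. the layer input; accumulates dW/dg/db.
cube conv_in_lrelu_bwd(const Conv& cv, const ConvCache& cc, const cube& dy,
                       mat& dW, vec& dg, vec& db) {
  mat dA = cube_to_mat(dy);
  for (uword i = 0; i < dA.n_elem; ++i)
    if (cc.pre(i) <= 0) dA(i) *= LEAK;
  dg += sum(dA % cc.zh, 1);
  db += sum(dA, 1);
  mat dzh = dA.each_col() % cv.g;
  mat dz(dzh.n_rows, dzh.n_cols);
  const int HW = dzh.n_cols;
  for (uword c = 0; c < dzh.n_rows; ++c) {
    const double m1 = mean(dzh.row(c));
    const double m2 = mean(dzh.row(c) % cc.zh.row(c));
    dz.row(c) = cc.inv(c) * (dzh.row(c) - m1 - cc.zh.row(c) * m2);
  }
  dW += dz * cc.K.t();
  mat dK = cv.W.t() * dz;
  cube dx;
  col2im3(dK, cc.H, cc.W, cc.Cin, dx);
  return dx;
}

cube maxpool2_fwd(const cube& x, ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = x(2 * i, 2 * j, c);
        uword bk = 0;
        const double c1 = x(2 * i + 1, 2 * j, c);
        const double c2 = x(2 * i, 2 * j + 1, c);
        const double c3 = x(2 * i + 1, 2 * j + 1, c);
        if (c1 > best) { best = c1; bk = 1; }
        if (c2 > best) { best = c2; bk = 2; }
        if (c3 > best) { best = c3; bk = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = bk;
      }
  return y;
}

cube maxpool2_bwd(const cube& dy, const ucube& idx) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube dx(2 * H, 2 * W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const uword k = idx(i, j, c);
        dx(2 * i + (k & 1u), 2 * j + (k >> 1), c) = dy(i, j, c);
      }
  return dx;
}

cube upsample2_fwd(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

cube upsample2_bwd(const cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

cube concat_ch(const cube& a, const cube& b) {
  cube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  y.slices(0, a.n_slices - 1) = a;
  y.slices(a.n_slices, y.n_slices - 1) = b;
  return y;
}

struct ForwardCache {
  std::vector<ConvCache> cc;
  std::vector<ucube> pool_idx;
  std::vector<uword> skip_ch;
  mat final_in;                        // input to the 1x1 layer (C x HW)
  mat probs;                           // sigmoid output, 1 x HW
  int H, W;
};

mat unet_forward_one(const std::vector<Conv>& L, const mat& img,
                     ForwardCache& fc) {
  fc.cc.resize(NCONV - 1);
  fc.pool_idx.resize(DEPTH);
  fc.skip_ch.resize(DEPTH);
  fc.H = img.n_rows; fc.W = img.n_cols;
  cube a(img.n_rows, img.n_cols, 1);
  a.slice(0) = img;
  std::vector<cube> skips(DEPTH);
  int l = 0;
  for (int d = 0; d < DEPTH; ++d) {
    a = conv_in_lrelu_fwd(L[l], a, fc.cc[l]); ++l;
    a = conv_in_lrelu_fwd(L[l], a, fc.cc[l]); ++l;
    skips[d] = a;
    fc.skip_ch[d] = a.n_slices;
    a = maxpool2_fwd(a, fc.pool_idx[d]);
  }
  a = conv_in_lrelu_fwd(L[l], a, fc.cc[l]); ++l;
  a = conv_in_lrelu_fwd(L[l], a, fc.cc[l]); ++l;
  for (int d = DEPTH - 1; d >= 0; --d) {
    a = upsample2_fwd(a);
    a = concat_ch(a, skips[d]);
    a = conv_in_lrelu_fwd(L[l], a, fc.cc[l]); ++l;
    a = conv_in_lrelu_fwd(L[l], a, fc.cc[l]); ++l;
  }
  fc.final_in = cube_to_mat(a);
  mat logits = L[NCONV - 1].W * fc.final_in;
  logits.each_col() += L[NCONV - 1].b;
  fc.probs = 1.0 / (1.0 + exp(-logits));
  return fc.probs;
}

void unet_backward_one(const std::vector<Conv>& L, const ForwardCache& fc,
                       const mat& dlogits, std::vector<Conv>& g) {
  int l = NCONV - 1;
  g[l].W += dlogits * fc.final_in.t();
  g[l].b += sum(dlogits, 1);
  mat dfin = L[l].W.t() * dlogits;
  cube da = mat_to_cube(dfin, fc.H, fc.W);
  --l;
  std::vector<cube> dskips(DEPTH);
  for (int d = 0; d < DEPTH; ++d) {
    da = conv_in_lrelu_bwd(L[l], fc.cc[l], da, g[l].W, g[l].g, g[l].b); --l;
    da = conv_in_lrelu_bwd(L[l], fc.cc[l], da, g[l].W, g[l].g, g[l].b); --l;
    const uword upC = da.n_slices - fc.skip_ch[d];
    dskips[d] = da.slices(upC, da.n_slices - 1);
    cube dup = da.slices(0, upC - 1);
    da = upsample2_bwd(dup);
  }
  da = conv_in_lrelu_bwd(L[l], fc.cc[l], da, g[l].W, g[l].g, g[l].b); --l;
  da = conv_in_lrelu_bwd(L[l], fc.cc[l], da, g[l].W, g[l].g, g[l].b); --l;
  for (int d = DEPTH - 1; d >= 0; --d) {
    da = maxpool2_bwd(da, fc.pool_idx[d]);
    da += dskips[d];
    da = conv_in_lrelu_bwd(L[l], fc.cc[l], da, g[l].W, g[l].g, g[l].b); --l;
    da = conv_in_lrelu_bwd(L[l], fc.cc[l], da, g[l].W, g[l].g, g[l].b); --l;
  }
}

Rcpp::List pack_grads(const std::vector<Conv>& g, int N) {
  Rcpp::List grads(NPAR);
  int k = 0;
  for (int l = 0; l < NCONV - 1; ++l) {
    grads[k++] = Rcpp::wrap(mat(g[l].W / N));
    grads[k++] = Rcpp::wrap(vec(g[l].g / N));
    grads[k++] = Rcpp::wrap(vec(g[l].b / N));
  }
  grads[k++] = Rcpp::wrap(mat(g[NCONV - 1].W / N));
  grads[k++] = Rcpp::wrap(vec(g[NCONV - 1].b / N));
  return grads;
}

} // namespace

// Mean soft-Dice loss and averaged gradients over a mini-batch.
// x, y: H x W x N cubes (grayscale images in [0,1], binary masks).
// [[Rcpp::export]]
Rcpp::List unet_grad(Rcpp::List weights, const arma::cube& x,
                     const arma::cube& y, double eps = 1.0) {
  std::vector<Conv> L = parse_weights(weights);
  std::vector<Conv> g(NCONV);
  for (int l = 0; l < NCONV; ++l) {
    g[l].W.zeros(L[l].W.n_rows, L[l].W.n_cols);
    g[l].g.zeros(L[l].g.n_elem);
    g[l].b.zeros(L[l].b.n_elem);
  }
  const int N = x.n_slices;
  double loss = 0.0, soft_dsc = 0.0;
  for (int n = 0; n < N; ++n) {
    ForwardCache fc;
    mat p = unet_forward_one(L, x.slice(n), fc);
    rowvec gt = vectorise(y.slice(n)).t();
    const double num = 2.0 * dot(p.row(0), gt) + eps;
    const double den = accu(p) + accu(gt) + eps;
    loss += 1.0 - num / den;
    soft_dsc += num / den;
    // dL/dp_i = -(2*g_i*den - num) / den^2 ; chain through the sigmoid
    mat dp = -(2.0 * gt * den - num) / (den * den);
    mat dz = dp % p % (1.0 - p);
    unet_backward_one(L, fc, dz, g);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / N,
                            Rcpp::Named("soft_dsc") = soft_dsc / N,
                            Rcpp::Named("grads") = pack_grads(g, N));
}

// Forward-only inference: returns the sigmoid probability map for one image.
// [[Rcpp::export]]
arma::mat unet_infer(Rcpp::List weights, const arma::mat& x) {
  std::vector<Conv> L = parse_weights(weights);
  ForwardCache fc;
  mat p = unet_forward_one(L, x, fc);
  return reshape(p.row(0), x.n_rows, x.n_cols);
}

// Maximum column-wise vertical extent (last - first + 1) of a binary mask.
// [[Rcpp::export]]
int iph_px_cpp(const arma::mat& mask) {
  const int H = mask.n_rows, W = mask.n_cols;
  int best = 0;
  for (int j = 0; j < W; ++j) {
    const double* col = mask.colptr(j);
    int first = -1, last = -1;
    for (int i = 0; i < H; ++i)
      if (col[i] > 0) { if (first < 0) first = i; last = i; }
    if (first >= 0 && last - first + 1 > best) best = last - first + 1;
  }
  return best;
}
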