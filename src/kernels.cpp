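#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3D convolution kernels shared by the classifier forward/backward pass and
// the relevance-propagation engine. All arrays are column-major R arrays:
//   volumes  x : (D, H, W, C, N)
//   kernels  w : (K, K, K, Cin, Cout), K odd, stride 1, "same" zero padding.
// Convolutions are lowered to im2col + BLAS matrix products per batch item;
// the D-axis inner copies are contiguous, so lowering stays cheap relative
// to the GEMM.

static inline void get_dims5(const NumericVector& x, int* d) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 5) stop("expected a 5-d array");
  for (int i = 0; i < 5; i++) d[i] = xd[i];
}

// Lower one volume (D,H,W,Ci slab at `xp`) into cols: (D*H*W) x (K^3*Ci).
static void im2col(const double* xp, int D, int H, int W, int Ci, int K,
                   arma::mat& cols) {
  const int P = (K - 1) / 2;
  const R_xlen_t DHW = (R_xlen_t)D * H * W;
  cols.zeros();
  int col = 0;
  for (int ci = 0; ci < Ci; ci++) {
    const double* xb = xp + DHW * ci;
    for (int dz = 0; dz < K; dz++)
      for (int dy = 0; dy < K; dy++)
        for (int dx = 0; dx < K; dx++, col++) {
          const int ox = dx - P, oy = dy - P, oz = dz - P;
          double* cb = cols.colptr(col);
          const int i0 = std::max(0, -ox), i1 = std::min(D, D - ox);
          const int j0 = std::max(0, -oy), j1 = std::min(H, H - oy);
          const int k0 = std::max(0, -oz), k1 = std::min(W, W - oz);
          for (int k = k0; k < k1; k++)
            for (int j = j0; j < j1; j++) {
              const double* src = xb + ox +
                (R_xlen_t)D * ((j + oy) + (R_xlen_t)H * (k + oz));
              double* dst = cb + (R_xlen_t)D * (j + (R_xlen_t)H * k);
              std::copy(src + i0, src + i1, dst + i0);
            }
        }
  }
}

// Scatter-add the cols layout back into a volume slab (adjoint of im2col).
static void col2im(const arma::mat& cols, int D, int H, int W, int Ci, int K,
                   double* xp) {
  const int P = (K - 1) / 2;
  const R_xlen_t DHW = (R_xlen_t)D * H * W;
  int col = 0;
  for (int ci = 0; ci < Ci; ci++) {
    double* xb = xp + DHW * ci;
    for (int dz = 0; dz < K; dz++)
      for (int dy = 0; dy < K; dy++)
        for (int dx = 0; dx < K; dx++, col++) {
          const int ox = dx - P, oy = dy - P, oz = dz - P;
          const double* cb = cols.colptr(col);
          const int i0 = std::max(0, -ox), i1 = std::min(D, D - ox);
          const int j0 = std::max(0, -oy), j1 = std::min(H, H - oy);
          const int k0 = std::max(0, -oz), k1 = std::min(W, W - oz);
          for (int k = k0; k < k1; k++)
            for (int j = j0; j < j1; j++) {
              double* dst = xb + ox +
                (R_xlen_t)D * ((j + oy) + (R_xlen_t)H * (k + oz));
              const double* src = cb + (R_xlen_t)D * (j + (R_xlen_t)H * k);
              for (int i = i0; i < i1; i++) dst[i] += src[i];
            }
        }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int xd[5];
  get_dims5(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("kernel must be a 5-d array");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  if (wd[1] != K || wd[2] != K) stop("kernel must be cubic");
  if (wd[3] != Ci) stop("kernel input channels do not match input");
  if (b.size() != Co) stop("bias length must equal output channels");
  if (K % 2 == 0) stop("kernel width must be odd");

  const R_xlen_t DHW = (R_xlen_t)D * H * W;
  const int KC = K * K * K * Ci;
  NumericVector out(DHW * Co * N);
  out.attr("dim") = IntegerVector::create(D, H, W, Co, N);
  arma::mat wm(w.begin(), KC, Co, false, true);
  arma::mat cols(DHW, KC);
  for (int n = 0; n < N; n++) {
    im2col(x.begin() + DHW * Ci * n, D, H, W, Ci, K, cols);
    arma::mat om(out.begin() + DHW * Co * n, DHW, Co, false, true);
    om = cols * wm;
    for (int co = 0; co < Co; co++) om.col(co) += b[co];
  }
  return out;
}

// Gradient (or relevance message) with respect to the convolution input:
// gx(m) = sum_n w_mn * gy(n).
// [[Rcpp::export(name = ".conv3d_bwd_input")]]
NumericVector conv3d_bwd_input(NumericVector gy, NumericVector w) {
  int yd[5];
  get_dims5(gy, yd);
  IntegerVector wd = w.attr("dim");
  const int D = yd[0], H = yd[1], W = yd[2], Co = yd[3], N = yd[4];
  const int K = wd[0], Ci = wd[3];
  if (wd[4] != Co) stop("kernel output channels do not match gradient");

  const R_xlen_t DHW = (R_xlen_t)D * H * W;
  const int KC = K * K * K * Ci;
  NumericVector gx(DHW * Ci * N);
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci, N);
  arma::mat wm(w.begin(), KC, Co, false, true);
  for (int n = 0; n < N; n++) {
    arma::mat ym(gy.begin() + DHW * Co * n, DHW, Co, false, true);
    arma::mat cols = ym * wm.t();          // DHW x KC
    col2im(cols, D, H, W, Ci, K, gx.begin() + DHW * Ci * n);
  }
  return gx;
}

// [[Rcpp::export(name = ".conv3d_bwd_weights")]]
List conv3d_bwd_weights(NumericVector x, NumericVector gy, int K) {
  int xd[5], yd[5];
  get_dims5(x, xd);
  get_dims5(gy, yd);
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3], N = xd[4];
  const int Co = yd[3];
  const R_xlen_t DHW = (R_xlen_t)D * H * W;
  const int KC = K * K * K * Ci;

  NumericVector gw((R_xlen_t)KC * Co);
  gw.attr("dim") = IntegerVector::create(K, K, K, Ci, Co);
  NumericVector gb(Co);
  arma::mat gwm(gw.begin(), KC, Co, false, true);
  arma::vec gbv(gb.begin(), Co, false, true);
  arma::mat cols(DHW, KC);
  for (int n = 0; n < N; n++) {
    im2col(x.begin() + DHW * Ci * n, D, H, W, Ci, K, cols);
    arma::mat ym(gy.begin() + DHW * Co * n, DHW, Co, false, true);
    gwm += cols.t() * ym;
    gbv += arma::sum(ym, 0).t();
  }
  return List::create(Named("gw") = gw, Named("gb") = gb);
}

// Average pooling with cubic window `s` and stride `s` (non-overlapping).
// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd(NumericVector x, int s) {
  int xd[5];
  get_dims5(x, xd);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  if (D % s || H % s || W % s) stop("spatial dims must be divisible by pool size");
  const int Do = D / s, Ho = H / s, Wo = W / s;
  const double inv = 1.0 / (s * s * s);
  NumericVector out((R_xlen_t)Do * Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t DHW = (R_xlen_t)D * H * W, oDHW = (R_xlen_t)Do * Ho * Wo;

  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; cn++) {
    const double* xb = xp + DHW * cn;
    double* ob = op + oDHW * cn;
    for (int k = 0; k < Wo; k++)
      for (int j = 0; j < Ho; j++)
        for (int i = 0; i < Do; i++) {
          double acc = 0.0;
          for (int dz = 0; dz < s; dz++)
            for (int dy = 0; dy < s; dy++)
              for (int dx = 0; dx < s; dx++)
                acc += xb[(i * s + dx) +
                          (R_xlen_t)D * ((j * s + dy) + (R_xlen_t)H * (k * s + dz))];
          ob[i + (R_xlen_t)Do * (j + (R_xlen_t)Ho * k)] = acc * inv;
        }
  }
  return out;
}

// Replicate each pooled cell over its s^3 source block, scaled by `scale`
// (scale = 1/s^3 gives the average-pooling gradient; scale = 1 gives plain
// block upsampling used by the relevance engine).
// [[Rcpp::export(name = ".pool_upsample")]]
NumericVector pool_upsample(NumericVector gy, int s, double scale) {
  int yd[5];
  get_dims5(gy, yd);
  const int Do = yd[0], Ho = yd[1], Wo = yd[2], C = yd[3], N = yd[4];
  const int D = Do * s, H = Ho * s, W = Wo * s;
  NumericVector gx((R_xlen_t)D * H * W * C * N);
  gx.attr("dim") = IntegerVector::create(D, H, W, C, N);
  const double* yp = gy.begin();
  double* xp = gx.begin();
  const R_xlen_t DHW = (R_xlen_t)D * H * W, oDHW = (R_xlen_t)Do * Ho * Wo;

  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; cn++) {
    const double* yb = yp + oDHW * cn;
    double* xb = xp + DHW * cn;
    for (int k = 0; k < W; k++)
      for (int j = 0; j < H; j++)
        for (int i = 0; i < D; i++)
          xb[i + (R_xlen_t)D * (j + (R_xlen_t)H * k)] =
            scale * yb[(i / s) + (R_xlen_t)Do * ((j / s) + (R_xlen_t)Ho * (k / s))];
  }
  return gx;
}
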