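// Windowed multi-head attention inner loops.
//
// The R side computes the joint QKV projection as one BLAS call over all
// windows of a batch; these kernels run the per-window, per-head
// scaled-dot-product attention (forward) and its exact reverse-mode
// gradients (backward). Rows of `qkv` are window-major: window k occupies
// rows [k*w2, (k+1)*w2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// bias: (w2, w2, heads) relative-position bias per head (may be empty).
// masks: (w2, w2, nmask) additive masks for wrapped windows; maskid maps
// each window to a mask slice (1-based, 0 = unmasked).
// Returns the concatenated head outputs (pre output-projection) and, when
// keep, the attention probabilities for the backward pass.
// [[Rcpp::export]]
List attn_core_fwd(const arma::mat& qkv, int w2, int heads,
                   const arma::cube& bias, bool use_bias,
                   const arma::cube& masks, const arma::ivec& maskid,
                   double scale, bool keep) {
  const int N = qkv.n_rows, C = qkv.n_cols / 3, hd = C / heads;
  const int nwB = N / w2;
  arma::mat out(N, C);
  arma::cube A(w2, w2, keep ? (size_t)nwB * heads : 0);
  arma::mat S(w2, w2);
  for (int k = 0; k < nwB; k++) {
    const int r0 = k * w2, r1 = r0 + w2 - 1;
    for (int h = 0; h < heads; h++) {
      const int c0 = h * hd, c1 = c0 + hd - 1;
      S = (scale * qkv.submat(r0, c0, r1, c1)) *
          qkv.submat(r0, C + c0, r1, C + c1).t();
      if (use_bias) S += bias.slice(h);
      if (maskid[k] > 0) S += masks.slice(maskid[k] - 1);
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      out.submat(r0, c0, r1, c1) = S * qkv.submat(r0, 2 * C + c0, r1, 2 * C + c1);
      if (keep) A.slice((size_t)k * heads + h) = S;
    }
  }
  return List::create(_["out"] = out, _["A"] = A);
}

// doc: gradient w.r.t. the concatenated head outputs. Returns the gradient
// w.r.t. qkv and, when wanted, the per-head sum of score gradients over
// all windows (the relative-position-bias gradient before table indexing).
// [[Rcpp::export]]
List attn_core_bwd(const arma::mat& doc, const arma::mat& qkv,
                   const arma::cube& A, int w2, int heads, double scale,
                   bool want_dbias) {
  const int N = qkv.n_rows, C = qkv.n_cols / 3, hd = C / heads;
  const int nwB = N / w2;
  arma::mat dqkv(N, 3 * C, arma::fill::zeros);
  arma::cube dbias(w2, w2, want_dbias ? heads : 0, arma::fill::zeros);
  arma::mat dA(w2, w2), dS(w2, w2);
  for (int k = 0; k < nwB; k++) {
    const int r0 = k * w2, r1 = r0 + w2 - 1;
    for (int h = 0; h < heads; h++) {
      const int c0 = h * hd, c1 = c0 + hd - 1;
      const arma::mat& Aw = A.slice((size_t)k * heads + h);
      arma::mat dO = doc.submat(r0, c0, r1, c1);
      arma::mat V = qkv.submat(r0, 2 * C + c0, r1, 2 * C + c1);
      dA = dO * V.t();
      dqkv.submat(r0, 2 * C + c0, r1, 2 * C + c1) = Aw.t() * dO;
      arma::vec rs = arma::sum(Aw % dA, 1);
      dA.each_col() -= rs;
      dS = Aw % dA;
      if (want_dbias) dbias.slice(h) += dS;
      arma::mat Qs = scale * qkv.submat(r0, c0, r1, c1);
      arma::mat K = qkv.submat(r0, C + c0, r1, C + c1);
      dqkv.submat(r0, c0, r1, c1) = scale * (dS * K);
      dqkv.submat(r0, C + c0, r1, C + c1) = dS.t() * Qs;
    }
  }
  return List::create(_["dqkv"] = dqkv, _["dbias"] = dbias);
}

// Add a per-column bias to a freshly allocated matrix in place (the caller
// guarantees the matrix is not aliased).
// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix y, NumericVector b) {
  const R_xlen_t n = y.nrow(), C = y.ncol();
  double* p = REAL(y);
  for (R_xlen_t j = 0; j < C; j++) {
    const double bj = b[j];
    double* col = p + j * n;
    for (R_xlen_t i = 0; i < n; i++) col[i] += bj;
  }
}

// Batched im2col: x is (H, W, C, B) column-major; output rows are
// image-major, token index column-major (row fastest); column order:
// kernel row fastest, then kernel column, then input channel.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int B,
                         int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1, Wo = (W + 2 * p - k) / s + 1;
  const int Ntok = Ho * Wo;
  NumericMatrix out(B * Ntok, k * k * C);
  const double* px = REAL(x);
  double* po = REAL(out);
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t planeHWC = planeHW * C;
  int col = 0;
  for (int ci = 0; ci < C; ci++)
    for (int dx = 0; dx < k; dx++)
      for (int dy = 0; dy < k; dy++, col++) {
        double* ocol = po + (R_xlen_t)col * B * Ntok;
        for (int b = 0; b < B; b++) {
          const double* base = px + (R_xlen_t)b * planeHWC + (R_xlen_t)ci * planeHW;
          double* orow = ocol + (R_xlen_t)b * Ntok;
          for (int c2 = 0; c2 < Wo; c2++) {
            const int xc = c2 * s + dx - p;
            if (xc < 0 || xc >= W) {
              for (int r2 = 0; r2 < Ho; r2++) orow[c2 * Ho + r2] = 0.0;
              continue;
            }
            const double* bc = base + (R_xlen_t)xc * H;
            for (int r2 = 0; r2 < Ho; r2++) {
              const int xr = r2 * s + dy - p;
              orow[c2 * Ho + r2] = (xr < 0 || xr >= H) ? 0.0 : bc[xr];
            }
          }
        }
      }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch gradients into (H, W, C, B).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcols, int H, int W, int C, int B,
                         int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1, Wo = (W + 2 * p - k) / s + 1;
  const int Ntok = Ho * Wo;
  NumericVector dx_img((R_xlen_t)H * W * C * B);
  double* pd = REAL(dx_img);
  const double* pc = REAL(dcols);
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t planeHWC = planeHW * C;
  int col = 0;
  for (int ci = 0; ci < C; ci++)
    for (int dx = 0; dx < k; dx++)
      for (int dy = 0; dy < k; dy++, col++) {
        const double* icol = pc + (R_xlen_t)col * B * Ntok;
        for (int b = 0; b < B; b++) {
          double* base = pd + (R_xlen_t)b * planeHWC + (R_xlen_t)ci * planeHW;
          const double* irow = icol + (R_xlen_t)b * Ntok;
          for (int c2 = 0; c2 < Wo; c2++) {
            const int xc = c2 * s + dx - p;
            if (xc < 0 || xc >= W) continue;
            double* bc = base + (R_xlen_t)xc * H;
            for (int r2 = 0; r2 < Ho; r2++) {
              const int xr = r2 * s + dy - p;
              if (xr >= 0 && xr < H) bc[xr] += irow[c2 * Ho + r2];
            }
          }
        }
      }
  dx_img.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx_img;
}

// Exact GELU x * Phi(x) in one pass; returns y and Phi(x) for backward.
// [[Rcpp::export]]
List gelu_fwd_cpp(NumericVector x) {
  const R_xlen_t n = x.size();
  NumericVector y(n), phi(n);
  const double* px = REAL(x);
  double* py = REAL(y); double* pp = REAL(phi);
  const double isqrt2 = 0.7071067811865475;
  for (R_xlen_t i = 0; i < n; i++) {
    const double ph = 0.5 * (1.0 + std::erf(px[i] * isqrt2));
    pp[i] = ph;
    py[i] = px[i] * ph;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["phi"] = phi);
}

// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector dy, NumericVector x,
                           NumericVector phi) {
  const R_xlen_t n = x.size();
  NumericVector dx(n);
  const double* pd = REAL(dy); const double* px = REAL(x);
  const double* pp = REAL(phi); double* po = REAL(dx);
  const double c = 0.3989422804014327; // 1/sqrt(2*pi)
  for (R_xlen_t i = 0; i < n; i++)
    po[i] = pd[i] * (pp[i] + px[i] * c * std::exp(-0.5 * px[i] * px[i]));
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// y = xhat * g[col] + b[col] in one pass (LayerNorm affine part).
// [[Rcpp::export]]
NumericMatrix ln_affine_cpp(NumericMatrix xhat, NumericVector g,
                            NumericVector b) {
  const R_xlen_t n = xhat.nrow(), C = xhat.ncol();
  NumericMatrix y(n, C);
  const double* px = REAL(xhat); double* py = REAL(y);
  for (R_xlen_t j = 0; j < C; j++) {
    const double gj = g[j], bj = b[j];
    const double* xc = px + j * n; double* yc = py + j * n;
    for (R_xlen_t i = 0; i < n; i++) yc[i] = xc[i] * gj + bj;
  }
  return y;
}

// dy * g[col] in one pass.
// [[Rcpp::export]]
NumericMatrix scale_cols_cpp(NumericMatrix dy, NumericVector g) {
  const R_xlen_t n = dy.nrow(), C = dy.ncol();
  NumericMatrix out(n, C);
  const double* pd = REAL(dy); double* po = REAL(out);
  for (R_xlen_t j = 0; j < C; j++) {
    const double gj = g[j];
    const double* dc = pd + j * n; double* oc = po + j * n;
    for (R_xlen_t i = 0; i < n; i++) oc[i] = dc[i] * gj;
  }
  return out;
}
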