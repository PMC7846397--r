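// Low-level layers for the hourglass network: 2-D convolution with reflection
// padding (im2col + BLAS gemm), single-sample batch normalisation, LeakyReLU
// and factor-2 bilinear upsampling, each with its exact backward pass.
// Tensors are arma::cube with dimensions (height, width, channels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// reflect index into [0, n-1] without repeating the edge sample
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  return i;
}

static cube pad_reflect(const cube& x, int p) {
  if (p == 0) return x;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H + 2 * p, W + 2 * p, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W + 2 * p; ++j) {
      int sj = reflect(j - p, W);
      for (int i = 0; i < H + 2 * p; ++i)
        out(i, j, c) = x(reflect(i - p, H), sj, c);
    }
  return out;
}

// patch matrix in transposed layout: (Ho*Wo) x (Cin*k*k), so each patch
// column is filled by contiguous copies when stride == 1
static mat im2colT(const cube& xp, int k, int stride, int Ho, int Wo) {
  const int C = xp.n_slices, Hp = xp.n_rows;
  const size_t P = (size_t)Ho * Wo;
  mat cols(P, C * k * k);
  const double* xb = xp.memptr();
  double* cb = cols.memptr();
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = (size_t)c * k * k + (size_t)kj * k + ki;
        double* dst = cb + col * P;
        for (int j = 0; j < Wo; ++j) {
          const double* src = xb + ((size_t)c * xp.n_cols + j * stride + kj)
                                   * Hp + ki;
          if (stride == 1)
            std::memcpy(dst + (size_t)j * Ho, src, Ho * sizeof(double));
          else
            for (int i = 0; i < Ho; ++i)
              dst[(size_t)j * Ho + i] = src[(size_t)i * stride];
        }
      }
  return cols;
}

// scatter-add of the transposed patch matrix back into the padded shape
static cube col2imT(const mat& cols, int C, int Hp, int Wp, int k, int stride,
                    int Ho, int Wo) {
  cube out(Hp, Wp, C, fill::zeros);
  const size_t P = (size_t)Ho * Wo;
  const double* cb = cols.memptr();
  double* ob = out.memptr();
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = (size_t)c * k * k + (size_t)kj * k + ki;
        const double* src = cb + col * P;
        for (int j = 0; j < Wo; ++j) {
          double* dst = ob + ((size_t)c * Wp + j * stride + kj) * Hp + ki;
          if (stride == 1)
            for (int i = 0; i < Ho; ++i) dst[i] += src[(size_t)j * Ho + i];
          else
            for (int i = 0; i < Ho; ++i)
              dst[(size_t)i * stride] += src[(size_t)j * Ho + i];
        }
      }
  return out;
}

// fold padded-gradient borders back onto interior cells (adjoint of reflect)
static cube unpad_reflect(const cube& g, int p, int H, int W) {
  if (p == 0) return g;
  const int C = g.n_slices;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)g.n_cols; ++j) {
      int sj = reflect(j - p, W);
      for (int i = 0; i < (int)g.n_rows; ++i)
        out(reflect(i - p, H), sj, c) += g(i, j, c);
    }
  return out;
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& w,
                    const arma::vec& b, int k, int stride) {
  const int p = (k - 1) / 2;
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * p - k) / stride + 1;
  const int Wo = (W + 2 * p - k) / stride + 1;
  const int Cout = w.n_rows;
  cube xp = pad_reflect(x, p);
  mat cols = im2colT(xp, k, stride, Ho, Wo);
  cube y(Ho, Wo, Cout);
  // the cube's memory is exactly the (Ho*Wo) x Cout product layout
  mat ymat(y.memptr(), (size_t)Ho * Wo, Cout, false, true);
  ymat = cols * w.t();
  ymat.each_row() += b.t();
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
Rcpp::List conv_bwd(const arma::cube& x, const arma::mat& w, int k, int stride,
                    const arma::cube& dy) {
  const int p = (k - 1) / 2;
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  cube xp = pad_reflect(x, p);
  mat cols = im2colT(xp, k, stride, Ho, Wo);
  const mat dymat(const_cast<double*>(dy.memptr()), (size_t)Ho * Wo, Cout,
                  false, true);
  mat dw = dymat.t() * cols;
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w;
  cube dxp = col2imT(dcols, Cin, H + 2 * p, W + 2 * p, k, stride, Ho, Wo);
  cube dx = unpad_reflect(dxp, p, H, W);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// single-sample batch normalisation over the spatial dimensions of each
// channel (population variance)
// [[Rcpp::export(name = ".bn_fwd")]]
Rcpp::List bn_fwd(const arma::cube& x, const arma::vec& gamma,
                  const arma::vec& beta, double eps) {
  const int C = x.n_slices;
  cube y(x.n_rows, x.n_cols, C);
  vec mu(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    double m = accu(s) / s.n_elem;
    double v = accu(square(s - m)) / s.n_elem;
    mu(c) = m;
    istd(c) = 1.0 / std::sqrt(v + eps);
    y.slice(c) = gamma(c) * ((s - m) * istd(c)) + beta(c);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("mu") = mu,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export(name = ".bn_bwd")]]
Rcpp::List bn_bwd(const arma::cube& x, const arma::vec& gamma,
                  const arma::vec& mu, const arma::vec& istd,
                  const arma::cube& dy) {
  const int C = x.n_slices;
  const double M = x.n_rows * x.n_cols;
  cube dx(x.n_rows, x.n_cols, C);
  vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    mat xhat = (x.slice(c) - mu(c)) * istd(c);
    const mat& g = dy.slice(c);
    dbeta(c) = accu(g);
    dgamma(c) = accu(g % xhat);
    // dx = gamma*istd/M * (M*g - sum(g) - xhat*sum(g*xhat))
    dx.slice(c) = (gamma(c) * istd(c) / M) *
      (M * g - dbeta(c) - xhat * dgamma(c));
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
arma::cube lrelu_fwd(const arma::cube& x, double slope) {
  cube y = x;
  y.transform([slope](double v) { return v > 0 ? v : slope * v; });
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
arma::cube lrelu_bwd(const arma::cube& x, const arma::cube& dy, double slope) {
  cube dx = dy;
  const double* px = x.memptr();
  double* pd = dx.memptr();
  for (uword i = 0; i < x.n_elem; ++i)
    if (px[i] <= 0) pd[i] *= slope;
  return dx;
}

// factor-2 bilinear upsampling, half-pixel centre alignment
// [[Rcpp::export(name = ".up_fwd")]]
arma::cube up_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j) {
      double sj = (j + 0.5) / 2.0 - 0.5;
      int j0 = std::max(0, (int)std::floor(sj));
      int j1 = std::min(W - 1, j0 + 1);
      double wj = std::min(1.0, std::max(0.0, sj - j0));
      for (int i = 0; i < 2 * H; ++i) {
        double si = (i + 0.5) / 2.0 - 0.5;
        int i0 = std::max(0, (int)std::floor(si));
        int i1 = std::min(H - 1, i0 + 1);
        double wi = std::min(1.0, std::max(0.0, si - i0));
        y(i, j, c) = (1 - wi) * (1 - wj) * x(i0, j0, c)
                   + wi * (1 - wj) * x(i1, j0, c)
                   + (1 - wi) * wj * x(i0, j1, c)
                   + wi * wj * x(i1, j1, c);
      }
    }
  return y;
}

// [[Rcpp::export(name = ".up_bwd")]]
arma::cube up_bwd(const arma::cube& dy) {
  const int H2 = dy.n_rows, W2 = dy.n_cols, C = dy.n_slices;
  const int H = H2 / 2, W = W2 / 2;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j) {
      double sj = (j + 0.5) / 2.0 - 0.5;
      int j0 = std::max(0, (int)std::floor(sj));
      int j1 = std::min(W - 1, j0 + 1);
      double wj = std::min(1.0, std::max(0.0, sj - j0));
      for (int i = 0; i < H2; ++i) {
        double si = (i + 0.5) / 2.0 - 0.5;
        int i0 = std::max(0, (int)std::floor(si));
        int i1 = std::min(H - 1, i0 + 1);
        double wi = std::min(1.0, std::max(0.0, si - i0));
        dx(i0, j0, c) += (1 - wi) * (1 - wj) * dy(i, j, c);
        dx(i1, j0, c) += wi * (1 - wj) * dy(i, j, c);
        dx(i0, j1, c) += (1 - wi) * wj * dy(i, j, c);
        dx(i1, j1, c) += wi * wj * dy(i, j, c);
      }
    }
  return dx;
}
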