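// 2-D convolution primitives (stride 1, zero "same" padding, odd kernels)
// used by the autoencoder feature extractor. Layout follows R column-major
// arrays: images are (H, W, C, N), weights (KH, KW, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col_same(const double* x, int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat out(kh * kw * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = c * kh * kw + dj * kh + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, ph - di);
          const int i1 = std::min(H, H + ph - di);
          for (int i = i0; i < i1; ++i) {
            out(row, (size_t)j * H + i) = xc[(size_t)sj * H + (i + di - ph)];
          }
        }
      }
    }
  }
  return out;
}

// scatter-add of column gradients back onto the padded input
static void col2im_same(const mat& cols, double* dx, int H, int W, int C,
                        int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = c * kh * kw + dj * kh + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, ph - di);
          const int i1 = std::min(H, H + ph - di);
          for (int i = i0; i < i1; ++i) {
            xc[(size_t)sj * H + (i + di - ph)] += cols(row, (size_t)j * H + i);
          }
        }
      }
    }
  }
}

static Rcpp::NumericVector alloc4(int d1, int d2, int d3, int d4) {
  Rcpp::NumericVector out((size_t)d1 * d2 * d3 * d4);
  out.attr("dim") = Rcpp::IntegerVector::create(d1, d2, d3, d4);
  return out;
}

static void get_dims4(const Rcpp::NumericVector& a, int* d) {
  Rcpp::IntegerVector dim = a.attr("dim");
  if (dim.size() != 4) Rcpp::stop("expected a 4-D array");
  for (int k = 0; k < 4; ++k) d[k] = dim[k];
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_forward(Rcpp::NumericVector x,
                                   Rcpp::NumericVector w,
                                   Rcpp::NumericVector b) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) Rcpp::stop("input channels (%d) do not match weights (%d)", C, Cin);
  const int K = kh * kw * Cin;
  const mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true); // K x Cout
  const vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  Rcpp::NumericVector y = alloc4(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    mat cols = im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw);
    mat out = Wm.t() * cols; // Cout x HW
    out.each_col() += bv;
    // write transposed so channel is the third dimension
    double* yp = y.begin() + (size_t)n * H * W * Cout;
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)H * W; ++p)
        yp[(size_t)c * H * W + p] = out(c, p);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                           Rcpp::NumericVector dy) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int K = kh * kw * Cin;
  const mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  Rcpp::NumericVector dx = alloc4(H, W, C, N);
  Rcpp::NumericVector dw = alloc4(kh, kw, Cin, Cout);
  Rcpp::NumericVector db(Cout);
  mat dWm(dw.begin(), K, Cout, false, true);
  vec dbv(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    mat cols = im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw);
    // read dy slice as Cout x HW
    const double* dyp = dy.begin() + (size_t)n * H * W * Cout;
    mat dym(Cout, (size_t)H * W);
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)H * W; ++p)
        dym(c, p) = dyp[(size_t)c * H * W + p];
    dWm += cols * dym.t();       // K x Cout
    dbv += sum(dym, 1);
    mat dcols = Wm * dym;        // K x HW
    col2im_same(dcols, dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
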