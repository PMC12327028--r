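#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2D convolutional primitives for the compact U-Net.
// Feature maps are arma::cube with dimensions (H, W, C); 3x3 kernels use
// same-padding. Weight matrices are (Cout x 9*Cin) with column index
// k = dr + 3*dc + 9*ci (0-based), matching R's column-major flattening of a
// (3, 3, Cin, Cout) array.

static arma::mat im2col3(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(9 * C, (size_t)H * W, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int k = (dr + 1) + 3 * (dc + 1) + 9 * ci;
        for (int c = 0; c < W; ++c) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          for (int r = 0; r < H; ++r) {
            int rr = r + dr;
            if (rr < 0 || rr >= H) continue;
            cols(k, r + (size_t)H * c) = x(rr, cc, ci);
          }
        }
      }
  return cols;
}

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
arma::cube conv2d_forward_cpp(const arma::cube &x, const arma::mat &w,
                              const arma::vec &b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  arma::mat cols = im2col3(x);
  arma::mat out = w * cols;
  out.each_col() += b;
  arma::cube y(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    y.slice(co) = arma::reshape(out.row(co), H, W);
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(const arma::cube &x, const arma::mat &w,
                         const arma::cube &gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat cols = im2col3(x);
  arma::mat gy_mat(Cout, (size_t)H * W);
  for (int co = 0; co < Cout; ++co)
    gy_mat.row(co) = arma::vectorise(gy.slice(co)).t();
  arma::mat gw = gy_mat * cols.t();
  arma::vec gb = arma::sum(gy_mat, 1);
  arma::mat gcols = w.t() * gy_mat;  // (9Cin x HW)
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci)
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int k = (dr + 1) + 3 * (dc + 1) + 9 * ci;
        for (int c = 0; c < W; ++c) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          for (int r = 0; r < H; ++r) {
            int rr = r + dr;
            if (rr < 0 || rr >= H) continue;
            gx(rr, cc, ci) += gcols(k, r + (size_t)H * c);
          }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool2_forward_cpp")]]
List maxpool2_forward_cpp(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index within slice of the argmax
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            int rr = 2 * r + dr, cc = 2 * c + dc;
            double v = x(rr, cc, ch);
            if (v > best) {
              best = v;
              bi = rr + (arma::uword)H * cc;
            }
          }
        y(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward_cpp")]]
arma::cube maxpool2_backward_cpp(const arma::cube &gy, const arma::ucube &idx,
                                 int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double *slice = gx.slice_memptr(ch);
    for (arma::uword j = 0; j < gy.n_rows * gy.n_cols; ++j) {
      slice[idx.slice(ch)(j)] += gy.slice(ch)(j);
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample2_forward_cpp")]]
arma::cube upsample2_forward_cpp(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = x(r, c, ch);
        y(2 * r, 2 * c, ch) = v;
        y(2 * r + 1, 2 * c, ch) = v;
        y(2 * r, 2 * c + 1, ch) = v;
        y(2 * r + 1, 2 * c + 1, ch) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward_cpp")]]
arma::cube upsample2_backward_cpp(const arma::cube &gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        gx(r, c, ch) = gy(2 * r, 2 * c, ch) + gy(2 * r + 1, 2 * c, ch) +
                       gy(2 * r, 2 * c + 1, ch) + gy(2 * r + 1, 2 * c + 1, ch);
  return gx;
}
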