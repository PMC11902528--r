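// Convolution kernels for the package's small autograd engine.
// Tensors are single-sample arrays laid out (h, w, c) column-major, matching
// R arrays; conv weights are (k, k, cin, cout). Convolutions use an
// im2col-transposed layout + GEMM; the 2x2 stride-2 transposed convolution
// is four GEMMs with strided scatter/gather; 2x2 max pooling is direct.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// patches matrix in transposed layout: (oh*ow, cin*k*k), so that for fixed
// patch column the inner oy loop is contiguous.
static arma::mat im2colT(const arma::cube& x, int k, int stride, int pad,
                         int oh, int ow) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int N = oh * ow;
  arma::mat cols(N, cin * k * k, arma::fill::zeros);
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  for (int ci = 0; ci < cin; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + kx * k + ci * k * k;
        // oy range with iy = oy*stride + ky - pad inside [0, h)
        int oy0 = 0;
        while (oy0 * stride + ky - pad < 0) ++oy0;
        int oy1 = oh;
        while (oy1 > oy0 && (oy1 - 1) * stride + ky - pad >= h) --oy1;
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= w) continue;
          const double* xcol = xp + (std::size_t)ci * h * w + (std::size_t)ix * h
                               + ky - pad;
          double* ccol = cp + (std::size_t)col * N + (std::size_t)ox * oh;
          for (int oy = oy0; oy < oy1; ++oy) ccol[oy] = xcol[oy * stride];
        }
      }
    }
  }
  return cols;
}

static void col2imT_add(arma::cube& dx, const arma::mat& dcolsT, int k,
                        int stride, int pad, int oh, int ow) {
  const int h = dx.n_rows, w = dx.n_cols, cin = dx.n_slices;
  const int N = oh * ow;
  double* xp = dx.memptr();
  const double* cp = dcolsT.memptr();
  for (int ci = 0; ci < cin; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + kx * k + ci * k * k;
        int oy0 = 0;
        while (oy0 * stride + ky - pad < 0) ++oy0;
        int oy1 = oh;
        while (oy1 > oy0 && (oy1 - 1) * stride + ky - pad >= h) --oy1;
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= w) continue;
          double* xcol = xp + (std::size_t)ci * h * w + (std::size_t)ix * h
                         + ky - pad;
          const double* ccol = cp + (std::size_t)col * N + (std::size_t)ox * oh;
          for (int oy = oy0; oy < oy1; ++oy) xcol[oy * stride] += ccol[oy];
        }
      }
    }
  }
}

static arma::mat weight_mat(const NumericVector& Wv, int k, int cin, int cout) {
  // (cin*k*k, cout); Wv indexed [ky + kx*k + ci*k*k + co*k*k*cin]
  return arma::mat(const_cast<double*>(&Wv[0]), cin * k * k, cout, false, true);
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const NumericVector& Wv,
                          const arma::vec& b, int k, int stride, int pad) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = b.n_elem;
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  arma::mat colsT = im2colT(x, k, stride, pad, oh, ow);
  arma::mat Wm = weight_mat(Wv, k, cin, cout);
  arma::mat Y = colsT * Wm;  // (oh*ow, cout)
  Y.each_row() += b.t();
  arma::cube y(oh, ow, cout);
  std::memcpy(y.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::cube& x, const NumericVector& Wv,
                    const arma::cube& dy, int k, int stride, int pad) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int oh = dy.n_rows, ow = dy.n_cols, cout = dy.n_slices;
  arma::mat colsT = im2colT(x, k, stride, pad, oh, ow);
  arma::mat Wm = weight_mat(Wv, k, cin, cout);
  const arma::mat dY(const_cast<double*>(dy.memptr()), oh * ow, cout, false, true);
  arma::mat dWm = colsT.t() * dY;            // (cin*k*k, cout)
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcolsT = dY * Wm.t();            // (oh*ow, cin*k*k)
  arma::cube dx(h, w, cin, arma::fill::zeros);
  col2imT_add(dx, dcolsT, k, stride, pad, oh, ow);
  NumericVector dW(Wv.size());
  std::memcpy(&dW[0], dWm.memptr(), sizeof(double) * dWm.n_elem);
  dW.attr("dim") = Wv.attr("dim");
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
arma::cube convt2_fwd_cpp(const arma::cube& x, const NumericVector& Wv,
                          const arma::vec& b) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = b.n_elem;
  const arma::mat Xm(const_cast<double*>(x.memptr()), h * w, cin, false, true);
  arma::cube y(2 * h, 2 * w, cout);
  for (int co = 0; co < cout; ++co) y.slice(co).fill(b(co));
  double* yp = y.memptr();
  const int H = 2 * h, W = 2 * w;
  for (int kx = 0; kx < 2; ++kx) {
    for (int ky = 0; ky < 2; ++ky) {
      arma::mat Wk(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wk(ci, co) = Wv[ky + kx * 2 + ci * 4 + co * 4 * cin];
      arma::mat Yk = Xm * Wk;  // (h*w, cout)
      const double* ykp = Yk.memptr();
      for (int co = 0; co < cout; ++co)
        for (int ix = 0; ix < w; ++ix) {
          double* ycol = yp + (std::size_t)co * H * W + (std::size_t)(2 * ix + kx) * H + ky;
          const double* ykcol = ykp + (std::size_t)co * h * w + (std::size_t)ix * h;
          for (int iy = 0; iy < h; ++iy) ycol[2 * iy] += ykcol[iy];
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2_bwd_cpp(const arma::cube& x, const NumericVector& Wv,
                    const arma::cube& dy) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = dy.n_slices;
  const int H = dy.n_rows, W = dy.n_cols;
  const arma::mat Xm(const_cast<double*>(x.memptr()), h * w, cin, false, true);
  const double* dyp = dy.memptr();
  arma::mat dXm(h * w, cin, arma::fill::zeros);
  NumericVector dW(Wv.size());
  arma::vec db(cout, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) db(co) = arma::accu(dy.slice(co));
  for (int kx = 0; kx < 2; ++kx) {
    for (int ky = 0; ky < 2; ++ky) {
      arma::mat dYk(h * w, cout);
      double* dykp = dYk.memptr();
      for (int co = 0; co < cout; ++co)
        for (int ix = 0; ix < w; ++ix) {
          const double* dcol = dyp + (std::size_t)co * H * W + (std::size_t)(2 * ix + kx) * H + ky;
          double* dykcol = dykp + (std::size_t)co * h * w + (std::size_t)ix * h;
          for (int iy = 0; iy < h; ++iy) dykcol[iy] = dcol[2 * iy];
        }
      arma::mat Wk(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wk(ci, co) = Wv[ky + kx * 2 + ci * 4 + co * 4 * cin];
      dXm += dYk * Wk.t();
      arma::mat dWk = Xm.t() * dYk;  // (cin, cout)
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          dW[ky + kx * 2 + ci * 4 + co * 4 * cin] = dWk(ci, co);
    }
  }
  arma::cube dx(h, w, cin);
  std::memcpy(dx.memptr(), dXm.memptr(), sizeof(double) * dXm.n_elem);
  dW.attr("dim") = Wv.attr("dim");
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int oh = h / 2, ow = w / 2;
  arma::cube y(oh, ow, c);
  IntegerVector idx(oh * ow * c);  // linear index into x of each max
  for (int ci = 0; ci < c; ++ci)
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy) {
        double best = -1e300; int bi = 0;
        for (int kx = 0; kx < 2; ++kx)
          for (int ky = 0; ky < 2; ++ky) {
            const int iy = 2 * oy + ky, ix = 2 * ox + kx;
            const double v = x(iy, ix, ci);
            if (v > best) { best = v; bi = iy + ix * h + ci * h * w; }
          }
        y(oy, ox, ci) = best;
        idx[oy + ox * oh + ci * oh * ow] = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const IntegerVector& idx, const arma::cube& dy,
                            int h, int w) {
  const int c = dy.n_slices, oh = dy.n_rows, ow = dy.n_cols;
  arma::cube dx(h, w, c, arma::fill::zeros);
  const double* dyp = dy.memptr();
  double* dxp = dx.memptr();
  for (int i = 0; i < oh * ow * c; ++i) dxp[idx[i]] += dyp[i];
  return dx;
}
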