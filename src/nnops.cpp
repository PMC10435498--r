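// Low-level kernels for the twin convolutional encoder.
//
// Batches are column-major R arrays of dim (side, side, channels, n).
// Convolutions are "valid" (no padding), stride 1; pooling is max-pool
// with a square window and equal stride (LeNet convention).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(arma::uword r, arma::uword c, arma::uword ch,
                               arma::uword n, arma::uword s, arma::uword C) {
  return r + s * (c + s * (ch + C * n));
}

// Gather one sample's patches into cols (k*k*C x o*o).
// Patch feature order: kr + k*kc + k*k*ch; column order: orow + o*ocol.
static void im2col_one(const double* x, arma::mat& cols, arma::uword s,
                       arma::uword C, arma::uword k, arma::uword o) {
  for (arma::uword ch = 0; ch < C; ++ch) {
    for (arma::uword kc = 0; kc < k; ++kc) {
      for (arma::uword kr = 0; kr < k; ++kr) {
        arma::uword f = kr + k * kc + k * k * ch;
        for (arma::uword oc = 0; oc < o; ++oc) {
          const double* src = x + (kr) + s * (oc + kc) + s * s * ch;
          double* dst = cols.colptr(0) + f; // cols is (kkC x o*o), col stride kkC
          for (arma::uword orow = 0; orow < o; ++orow) {
            dst[(orow + o * oc) * cols.n_rows] = src[orow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".convForward")]]
NumericVector conv_forward(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  arma::uword s = xd[0], C = xd[2], n = xd[3];
  arma::uword F = w.nrow(), kkC = w.ncol();
  arma::uword k = (arma::uword)std::lround(std::sqrt((double)(kkC / C)));
  if (k * k * C != kkC) stop("weight shape inconsistent with input channels");
  if (s < k) stop("input side smaller than kernel");
  arma::uword o = s - k + 1;

  arma::mat W(w.begin(), F, kkC, false);
  arma::vec B(b.begin(), F, false);
  NumericVector y(o * o * F * n);
  y.attr("dim") = IntegerVector::create((int)o, (int)o, (int)F, (int)n);

  arma::mat cols(kkC, o * o);
  arma::mat Y(F, o * o);
  for (arma::uword i = 0; i < n; ++i) {
    im2col_one(x.begin() + s * s * C * i, cols, s, C, k, o);
    Y = W * cols;
    Y.each_col() += B;
    // Y(f, orow + o*ocol) -> y(orow, ocol, f, i)
    double* yp = y.begin() + o * o * F * i;
    for (arma::uword f = 0; f < F; ++f)
      for (arma::uword cidx = 0; cidx < o * o; ++cidx)
        yp[cidx + o * o * f] = Y(f, cidx);
  }
  return y;
}

// [[Rcpp::export(name = ".convBackward")]]
List conv_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                   bool want_dx = true) {
  IntegerVector xd = x.attr("dim");
  arma::uword s = xd[0], C = xd[2], n = xd[3];
  arma::uword F = w.nrow(), kkC = w.ncol();
  arma::uword k = (arma::uword)std::lround(std::sqrt((double)(kkC / C)));
  arma::uword o = s - k + 1;

  arma::mat W(w.begin(), F, kkC, false);
  NumericVector dx(want_dx ? x.size() : 0);
  if (want_dx) dx.attr("dim") = x.attr("dim");
  arma::mat dW(F, kkC, arma::fill::zeros);
  arma::vec dB(F, arma::fill::zeros);

  arma::mat cols(kkC, o * o);
  arma::mat dY(F, o * o);
  arma::mat dcols(kkC, o * o);
  for (arma::uword i = 0; i < n; ++i) {
    const double* xb = x.begin() + s * s * C * i;
    im2col_one(xb, cols, s, C, k, o);
    const double* dyp = dy.begin() + o * o * F * i;
    for (arma::uword f = 0; f < F; ++f)
      for (arma::uword cidx = 0; cidx < o * o; ++cidx)
        dY(f, cidx) = dyp[cidx + o * o * f];
    dW += dY * cols.t();
    dB += arma::sum(dY, 1);
    if (!want_dx) continue;
    dcols = W.t() * dY;
    // scatter-add dcols back to dx (col2im)
    double* dxb = dx.begin() + s * s * C * i;
    for (arma::uword ch = 0; ch < C; ++ch)
      for (arma::uword kc = 0; kc < k; ++kc)
        for (arma::uword kr = 0; kr < k; ++kr) {
          arma::uword f = kr + k * kc + k * k * ch;
          for (arma::uword oc = 0; oc < o; ++oc) {
            double* dst = dxb + kr + s * (oc + kc) + s * s * ch;
            for (arma::uword orow = 0; orow < o; ++orow)
              dst[orow] += dcols(f, orow + o * oc);
          }
        }
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = wrap(dW),
                      _["db"] = wrap(dB));
}

// [[Rcpp::export(name = ".poolForward")]]
List pool_forward(NumericVector x, int size) {
  IntegerVector xd = x.attr("dim");
  arma::uword s = xd[0], C = xd[2], n = xd[3];
  arma::uword p = (arma::uword)size;
  arma::uword o = s / p;
  NumericVector y(o * o * C * n);
  IntegerVector amax(o * o * C * n);
  y.attr("dim") = IntegerVector::create((int)o, (int)o, (int)C, (int)n);
  amax.attr("dim") = y.attr("dim");

  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword ch = 0; ch < C; ++ch)
      for (arma::uword oc = 0; oc < o; ++oc)
        for (arma::uword orow = 0; orow < o; ++orow) {
          double best = -HUGE_VAL;
          arma::uword barg = 0;
          for (arma::uword dc = 0; dc < p; ++dc)
            for (arma::uword dr = 0; dr < p; ++dr) {
              arma::uword xi = idx4(orow * p + dr, oc * p + dc, ch, i, s, C);
              if (x[xi] > best) { best = x[xi]; barg = xi; }
            }
          arma::uword yi = orow + o * (oc + o * (ch + C * i));
          y[yi] = best;
          amax[yi] = (int)barg; // 0-based linear index into x
        }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".poolBackward")]]
NumericVector pool_backward(NumericVector dy, IntegerVector amax,
                            IntegerVector xdim) {
  arma::uword len = 1;
  for (int d = 0; d < xdim.size(); ++d) len *= (arma::uword)xdim[d];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".geluForward")]]
NumericVector gelu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    y[i] = v * 0.5 * (1.0 + std::erf(v * M_SQRT1_2));
  }
  return y;
}

// [[Rcpp::export(name = ".geluBackward")]]
NumericVector gelu_backward(NumericVector x, NumericVector dy) {
  static const double inv_sqrt2pi = 0.3989422804014327;
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    double phi = 0.5 * (1.0 + std::erf(v * M_SQRT1_2));
    double dens = inv_sqrt2pi * std::exp(-0.5 * v * v);
    dx[i] = dy[i] * (phi + v * dens);
  }
  return dx;
}
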