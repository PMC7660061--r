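// Minimal batched conv / pooling primitives for the tiny classifier engine.
// Layout conventions (R column-major):
//   activations: array dim c(H, W, C, N)
//   conv kernels: array dim c(kh, kw, Cin, Cout)
// im2col rows are indexed (ki, kj, c) in that (column-major) order, so a
// kernel array flattened by R's own ordering lines up with the column matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col_one(const double *x, int H, int W, int C,
                                   int kh, int kw, int stride, int pad,
                                   int oh, int ow) {
  arma::mat col(kh * kw * C, oh * ow, arma::fill::zeros);
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      int outIdx = orow + oh * oc;
      int r0 = orow * stride - pad;
      int c0 = oc * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          int cc = c0 + kj;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int rr = r0 + ki;
            if (rr < 0 || rr >= H) continue;
            col(ki + kh * (kj + kw * c), outIdx) = x[rr + H * (cc + W * c)];
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_one(const arma::mat &col, double *dx, int H, int W,
                              int C, int kh, int kw, int stride, int pad,
                              int oh, int ow) {
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      int outIdx = orow + oh * oc;
      int r0 = orow * stride - pad;
      int c0 = oc * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          int cc = c0 + kj;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int rr = r0 + ki;
            if (rr < 0 || rr >= H) continue;
            dx[rr + H * (cc + W * c)] += col(ki + kh * (kj + kw * c), outIdx);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".convForward")]]
NumericVector convForward(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("kernel input channels do not match activations");
  int oh = (H + 2 * pad - kh) / stride + 1;
  int ow = (W + 2 * pad - kw) / stride + 1;
  arma::mat wmat(const_cast<double *>(w.begin()), kh * kw * C, Cout, false);
  arma::vec bvec(const_cast<double *>(b.begin()), Cout, false);
  NumericVector out(oh * ow * Cout * N);
  out.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_one(x.begin() + (R_xlen_t)n * H * W * C, H, W, C,
                               kh, kw, stride, pad, oh, ow);
    arma::mat o = wmat.t() * col;           // Cout x (oh*ow)
    o.each_col() += bvec;
    // o is (Cout, oh*ow); output layout wants (oh, ow, Cout)
    arma::mat ot = o.t();                   // (oh*ow, Cout), column-major ok
    std::copy(ot.begin(), ot.end(), out.begin() + (R_xlen_t)n * oh * ow * Cout);
  }
  return out;
}

// [[Rcpp::export(name = ".convBackward")]]
List convBackward(NumericVector x, NumericVector w, NumericVector dout,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector od = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int oh = od[0], ow = od[1];
  arma::mat wmat(const_cast<double *>(w.begin()), kh * kw * C, Cout, false);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dwmat(kh * kw * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_one(x.begin() + (R_xlen_t)n * H * W * C, H, W, C,
                               kh, kw, stride, pad, oh, ow);
    // recover (Cout, oh*ow) gradient from (oh, ow, Cout) slab
    arma::mat dot(const_cast<double *>(dout.begin()) + (R_xlen_t)n * oh * ow * Cout,
                  oh * ow, Cout, false);
    arma::mat dmat = dot.t();
    dwmat += col * dot;                     // (khkwC, Cout)
    db += arma::sum(dmat, 1);
    arma::mat dcol = wmat * dmat;           // (khkwC, oh*ow)
    col2im_one(dcol, dx.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw,
               stride, pad, oh, ow);
  }
  NumericVector dwr(dwmat.begin(), dwmat.end());
  dwr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxPoolForward")]]
List maxPoolForward(NumericVector x, int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int oh = (H + 2 * pad - kh) / stride + 1;
  int ow = (W + 2 * pad - kw) / stride + 1;
  NumericVector out(oh * ow * C * N);
  IntegerVector arg(oh * ow * C * N);      // flat index into the input slab
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (R_xlen_t)n * H * W * C;
    R_xlen_t base = (R_xlen_t)n * oh * ow * C;
    for (int c = 0; c < C; ++c) {
      for (int oc = 0; oc < ow; ++oc) {
        for (int orow = 0; orow < oh; ++orow) {
          double best = R_NegInf;
          int bestIdx = -1;
          int r0 = orow * stride - pad, c0 = oc * stride - pad;
          for (int kj = 0; kj < kw; ++kj) {
            int cc = c0 + kj;
            if (cc < 0 || cc >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int rr = r0 + ki;
              if (rr < 0 || rr >= H) continue;
              int idx = rr + H * (cc + W * c);
              if (xs[idx] > best) { best = xs[idx]; bestIdx = idx; }
            }
          }
          R_xlen_t o = base + orow + oh * (oc + ow * c);
          out[o] = (bestIdx < 0) ? 0.0 : best;
          arg[o] = bestIdx;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
NumericVector maxPoolBackward(IntegerVector argmax, NumericVector dout,
                              IntegerVector inDim) {
  IntegerVector od = dout.attr("dim");
  int oh = od[0], ow = od[1], C = od[2], N = od[3];
  int H = inDim[0], W = inDim[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = inDim;
  R_xlen_t slab = (R_xlen_t)H * W * C;
  R_xlen_t oslab = (R_xlen_t)oh * ow * C;
  for (int n = 0; n < N; ++n) {
    for (R_xlen_t i = 0; i < oslab; ++i) {
      int a = argmax[n * oslab + i];
      if (a >= 0) dx[n * slab + a] += dout[n * oslab + i];
    }
  }
  return dx;
}
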