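// Minimal 2D convolution kernels for the recurrent UNet.
//
// Feature maps are (H, W, C) arrays. Convolution weights are
// (kh, kw, cin, cout); transpose-convolution weights are
// (kh, kw, cout, cin). With these layouts the column-major R array is
// already the GEMM operand (patch index = ki + kh*(kj + kw*channel)),
// so no repacking is needed. Arithmetic runs in single precision with
// double interfaces to R. im2col gathers, for every target grid
// position g, the source patch anchored at s*g - pad + k, so the same
// two helpers serve conv forward/backward and transpose-conv
// forward/backward.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static fcube to_fcube(const Rcpp::NumericVector &x, int &h, int &w, int &c) {
  Rcpp::IntegerVector d = x.attr("dim");
  h = d[0]; w = d[1]; c = (d.size() > 2) ? d[2] : 1;
  fcube out(h, w, c);
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

static Rcpp::NumericVector from_fcube(const fcube &x) {
  Rcpp::NumericVector out(x.n_elem);
  std::copy(x.begin(), x.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create((int)x.n_rows, (int)x.n_cols,
                                                (int)x.n_slices);
  return out;
}

// weight array -> (kh*kw*c3 x c4) float matrix, a pure cast
static fmat to_fmat_w(const Rcpp::NumericVector &w, int &kh, int &kw,
                      int &c3, int &c4) {
  Rcpp::IntegerVector d = w.attr("dim");
  kh = d[0]; kw = d[1]; c3 = d[2]; c4 = d[3];
  fmat out((size_t)kh * kw * c3, c4);
  std::copy(w.begin(), w.end(), out.begin());
  return out;
}

static Rcpp::NumericVector pack_dw(const fmat &dW, int kh, int kw, int c3,
                                   int c4) {
  Rcpp::NumericVector out((size_t)kh * kw * c3 * c4);
  std::copy(dW.begin(), dW.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(kh, kw, c3, c4);
  return out;
}

static fmat im2col(const fcube &src, int kh, int kw, int stride, int pad,
                   int hgrid, int wgrid) {
  const int C = src.n_slices, H = src.n_rows, W = src.n_cols;
  fmat out(kh * kw * C, (size_t)hgrid * wgrid, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const fmat &sl = src.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int gj = 0; gj < wgrid; ++gj) {
          const int sj = stride * gj - pad + kj;
          if (sj < 0 || sj >= W) continue;
          float *op = out.colptr((size_t)gj * hgrid) + row;
          for (int gi = 0; gi < hgrid; ++gi) {
            const int si = stride * gi - pad + ki;
            if (si >= 0 && si < H)
              op[(size_t)gi * out.n_rows] = sl(si, sj);
          }
        }
      }
    }
  }
  return out;
}

static fcube col2im(const fmat &cols, int kh, int kw, int C, int hgrid,
                    int wgrid, int htgt, int wtgt, int stride, int pad) {
  fcube out(htgt, wtgt, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat &sl = out.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int gj = 0; gj < wgrid; ++gj) {
          const int tj = stride * gj - pad + kj;
          if (tj < 0 || tj >= wtgt) continue;
          const float *cp = cols.colptr((size_t)gj * hgrid) + row;
          for (int gi = 0; gi < hgrid; ++gi) {
            const int ti = stride * gi - pad + ki;
            if (ti >= 0 && ti < htgt)
              sl(ti, tj) += cp[(size_t)gi * cols.n_rows];
          }
        }
      }
    }
  }
  return out;
}

static int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cppConvFwd")]]
Rcpp::NumericVector conv_fwd(const Rcpp::NumericVector &x,
                             const Rcpp::NumericVector &w,
                             const Rcpp::NumericVector &b, int stride,
                             int pad) {
  int H, W, C, kh, kw, cin, cout;
  fcube xc = to_fcube(x, H, W, C);
  fmat Wf = to_fmat_w(w, kh, kw, cin, cout);   // (kh*kw*cin) x cout
  const int ho = out_size(H, kh, stride, pad);
  const int wo = out_size(W, kw, stride, pad);
  fmat K = im2col(xc, kh, kw, stride, pad, ho, wo);
  fmat Y = K.t() * Wf;                         // (ho*wo) x cout
  fcube out(ho, wo, cout);
  for (int o = 0; o < cout; ++o)
    out.slice(o) = reshape(Y.col(o), ho, wo) + (float)b[o % b.size()];
  return from_fcube(out);
}

// [[Rcpp::export(name = ".cppConvBwd")]]
Rcpp::List conv_bwd(const Rcpp::NumericVector &x,
                    const Rcpp::NumericVector &w,
                    const Rcpp::NumericVector &dyv, int stride, int pad,
                    bool need_dx) {
  int H, W, C, ho, wo, co, kh, kw, cin, cout;
  fcube xc = to_fcube(x, H, W, C);
  fcube dy = to_fcube(dyv, ho, wo, co);
  fmat Wf = to_fmat_w(w, kh, kw, cin, cout);
  fmat K = im2col(xc, kh, kw, stride, pad, ho, wo);
  fmat dY((size_t)ho * wo, cout);              // (pix) x cout
  for (int o = 0; o < cout; ++o)
    dY.col(o) = vectorise(dy.slice(o));
  fmat dW = K * dY;                            // (kh*kw*cin) x cout
  Rcpp::NumericVector db(cout);
  for (int o = 0; o < cout; ++o) db[o] = accu(dy.slice(o));
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dw") = pack_dw(dW, kh, kw, cin, cout),
      Rcpp::Named("db") = db);
  if (need_dx) {
    fmat dK = Wf * dY.t();                     // (kh*kw*cin) x pix
    out["dx"] = from_fcube(
        col2im(dK, kh, kw, cin, ho, wo, H, W, stride, pad));
  }
  return out;
}

// [[Rcpp::export(name = ".cppTConvFwd")]]
Rcpp::NumericVector tconv_fwd(const Rcpp::NumericVector &x,
                              const Rcpp::NumericVector &w,
                              const Rcpp::NumericVector &b, int stride,
                              int pad) {
  int hi, wi, C, kh, kw, cout, cin;
  fcube xc = to_fcube(x, hi, wi, C);
  fmat Wt = to_fmat_w(w, kh, kw, cout, cin);   // (kh*kw*cout) x cin
  const int ho = (hi - 1) * stride + kh - 2 * pad;
  const int wo = (wi - 1) * stride + kw - 2 * pad;
  fmat X((size_t)hi * wi, cin);
  for (int c = 0; c < cin; ++c)
    X.col(c) = vectorise(xc.slice(c));
  fmat cols = Wt * X.t();                      // (kh*kw*cout) x pix
  fcube out = col2im(cols, kh, kw, cout, hi, wi, ho, wo, stride, pad);
  for (int o = 0; o < cout; ++o)
    out.slice(o) += (float)b[o % b.size()];
  return from_fcube(out);
}

// [[Rcpp::export(name = ".cppTConvBwd")]]
Rcpp::List tconv_bwd(const Rcpp::NumericVector &x,
                     const Rcpp::NumericVector &w,
                     const Rcpp::NumericVector &dyv, int stride, int pad,
                     bool need_dx) {
  int hi, wi, C, ho, wo, co, kh, kw, cout, cin;
  fcube xc = to_fcube(x, hi, wi, C);
  fcube dy = to_fcube(dyv, ho, wo, co);
  fmat Wt = to_fmat_w(w, kh, kw, cout, cin);
  fmat dCols = im2col(dy, kh, kw, stride, pad, hi, wi); // (kh*kw*cout) x pix
  fmat X((size_t)hi * wi, cin);
  for (int c = 0; c < cin; ++c)
    X.col(c) = vectorise(xc.slice(c));
  fmat dW = dCols * X;                         // (kh*kw*cout) x cin
  Rcpp::NumericVector db(cout);
  for (int o = 0; o < cout; ++o) db[o] = accu(dy.slice(o));
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dw") = pack_dw(dW, kh, kw, cout, cin),
      Rcpp::Named("db") = db);
  if (need_dx) {
    fmat dX = dCols.t() * Wt;                  // pix x cin
    fcube dxc(hi, wi, cin);
    for (int c = 0; c < cin; ++c)
      dxc.slice(c) = reshape(dX.col(c), hi, wi);
    out["dx"] = from_fcube(dxc);
  }
  return out;
}

// In-place Adam update over a list of parameter arrays. params, m and v
// are owned by the optimiser (deep-copied before the first step), so the
// in-place mutation never leaks into user-visible objects.
// [[Rcpp::export(name = ".cppAdamStep")]]
void adam_step(Rcpp::List params, Rcpp::List grads, Rcpp::List m,
               Rcpp::List v, int t, double lr, double beta1, double beta2,
               double eps) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int i = 0; i < params.size(); ++i) {
    Rcpp::NumericVector p = params[i], g = grads[i], mi = m[i], vi = v[i];
    const R_xlen_t n = p.size();
    for (R_xlen_t j = 0; j < n; ++j) {
      mi[j] = beta1 * mi[j] + (1.0 - beta1) * g[j];
      vi[j] = beta2 * vi[j] + (1.0 - beta2) * g[j] * g[j];
      p[j] -= lr * (mi[j] / bc1) / (std::sqrt(vi[j] / bc2) + eps);
    }
  }
}

// Double-precision convolution for the loss side (SSIM windows, feature
// extractor): gradient checks against finite differences need the loss
// computed at full precision; these small convolutions are not on the
// training hot path.

static mat im2col_d(const cube &src, int kh, int kw, int stride, int pad,
                    int hgrid, int wgrid) {
  const int C = src.n_slices, H = src.n_rows, W = src.n_cols;
  mat out(kh * kw * C, (size_t)hgrid * wgrid, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int gj = 0; gj < wgrid; ++gj) {
          const int sj = stride * gj - pad + kj;
          if (sj < 0 || sj >= W) continue;
          for (int gi = 0; gi < hgrid; ++gi) {
            const int si = stride * gi - pad + ki;
            if (si >= 0 && si < H)
              out(row, (size_t)gj * hgrid + gi) = src(si, sj, c);
          }
        }
      }
  return out;
}

// [[Rcpp::export(name = ".cppConvFwdD")]]
Rcpp::NumericVector conv_fwd_d(const Rcpp::NumericVector &x,
                               const Rcpp::NumericVector &w,
                               const Rcpp::NumericVector &b, int stride,
                               int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = (xd.size() > 2) ? xd[2] : 1;
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  cube xc(const_cast<double *>(x.begin()), H, W, C, false);
  mat Wf(const_cast<double *>(w.begin()), (size_t)kh * kw * cin, cout,
         false);
  const int ho = out_size(H, kh, stride, pad);
  const int wo = out_size(W, kw, stride, pad);
  mat K = im2col_d(xc, kh, kw, stride, pad, ho, wo);
  mat Y = K.t() * Wf;
  cube out(ho, wo, cout);
  for (int o = 0; o < cout; ++o)
    out.slice(o) = reshape(Y.col(o), ho, wo) + b[o % b.size()];
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = Rcpp::IntegerVector::create(ho, wo, cout);
  return res;
}

// [[Rcpp::export(name = ".cppConvBwdDataD")]]
Rcpp::NumericVector conv_bwd_data_d(const Rcpp::NumericVector &xdim,
                                    const Rcpp::NumericVector &w,
                                    const Rcpp::NumericVector &dyv,
                                    int stride, int pad) {
  Rcpp::IntegerVector wd = w.attr("dim"), dd = dyv.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int ho = dd[0], wo = dd[1];
  const int H = (int)xdim[0], W = (int)xdim[1];
  mat Wf(const_cast<double *>(w.begin()), (size_t)kh * kw * cin, cout,
         false);
  mat dY((size_t)ho * wo, cout);
  std::copy(dyv.begin(), dyv.end(), dY.begin());
  mat dK = Wf * dY.t();
  // col2im accumulate (double)
  cube dx(H, W, cin, fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int gj = 0; gj < wo; ++gj) {
          const int tj = stride * gj - pad + kj;
          if (tj < 0 || tj >= W) continue;
          for (int gi = 0; gi < ho; ++gi) {
            const int ti = stride * gi - pad + ki;
            if (ti >= 0 && ti < H)
              dx(ti, tj, c) += dK(row, (size_t)gj * ho + gi);
          }
        }
      }
  Rcpp::NumericVector res(dx.begin(), dx.end());
  res.attr("dim") = Rcpp::IntegerVector::create(H, W, cin);
  return res;
}
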