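#include <Rcpp.h>
using namespace Rcpp;

// Direct 2-D convolution on arrays stored (H, W, C), column-major.
// The weight matrix is (C_out x k*k*C_in) with the column index
// ordered (dh, dw, c_in), dh fastest -- the column-major flattening
// of an R array of dim (k, k, C_in) per output channel.

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, int H, int W, int C,
                             NumericMatrix Wm, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Cout = Wm.nrow();
  NumericVector y((R_xlen_t)Ho * Wo * Cout);
  const double *xp = x.begin();
  const double *wp = Wm.begin();
  double *yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double *yc = yp + (R_xlen_t)Ho * Wo * co;
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (R_xlen_t)H * W * c;
      for (int dw = 0; dw < k; ++dw) {
        for (int dh = 0; dh < k; ++dh) {
          int row = dh + k * dw + k * k * c;
          double coeff = wp[co + (R_xlen_t)Cout * row];
          if (coeff == 0.0) continue;
          for (int j = 0; j < Wo; ++j) {
            int wsrc = j * stride - pad + dw;
            if (wsrc < 0 || wsrc >= W) continue;
            const double *xcol = xc + (R_xlen_t)H * wsrc;
            double *ycol = yc + (R_xlen_t)Ho * j;
            int h0 = -pad + dh;
            int i_lo = 0, i_hi = Ho;
            while (i_lo < Ho && h0 + i_lo * stride < 0) ++i_lo;
            while (i_hi > i_lo && h0 + (i_hi - 1) * stride >= H) --i_hi;
            if (stride == 1) {
              const double *xs = xcol + h0;
              for (int i = i_lo; i < i_hi; ++i) ycol[i] += coeff * xs[i];
            } else {
              for (int i = i_lo; i < i_hi; ++i)
                ycol[i] += coeff * xcol[h0 + i * stride];
            }
          }
        }
      }
    }
  }
  return y;
}

// Backward pass: gradients for the input and the weight matrix.

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector dy, int H, int W, int C,
                    NumericMatrix Wm, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Cout = Wm.nrow();
  NumericVector dx((R_xlen_t)H * W * C);
  NumericMatrix dW(Cout, k * k * C);
  const double *xp = x.begin();
  const double *wp = Wm.begin();
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  double *dwp = dW.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *dyc = dyp + (R_xlen_t)Ho * Wo * co;
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (R_xlen_t)H * W * c;
      double *dxc = dxp + (R_xlen_t)H * W * c;
      for (int dw = 0; dw < k; ++dw) {
        for (int dh = 0; dh < k; ++dh) {
          int row = dh + k * dw + k * k * c;
          double coeff = wp[co + (R_xlen_t)Cout * row];
          double acc = 0.0;
          for (int j = 0; j < Wo; ++j) {
            int wsrc = j * stride - pad + dw;
            if (wsrc < 0 || wsrc >= W) continue;
            const double *xcol = xc + (R_xlen_t)H * wsrc;
            double *dxcol = dxc + (R_xlen_t)H * wsrc;
            const double *gcol = dyc + (R_xlen_t)Ho * j;
            int h0 = -pad + dh;
            int i_lo = 0, i_hi = Ho;
            while (i_lo < Ho && h0 + i_lo * stride < 0) ++i_lo;
            while (i_hi > i_lo && h0 + (i_hi - 1) * stride >= H) --i_hi;
            for (int i = i_lo; i < i_hi; ++i) {
              int hsrc = h0 + i * stride;
              double g = gcol[i];
              dxcol[hsrc] += coeff * g;
              acc += g * xcol[hsrc];
            }
          }
          dwp[co + (R_xlen_t)Cout * row] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dW);
}

// Depthwise k x k convolution, one filter per channel, zero padding.

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int C,
                             NumericVector w, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  const double *xp = x.begin();
  const double *wp = w.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *wc = wp + (R_xlen_t)k * k * c;
    const double *xc = xp + (R_xlen_t)H * W * c;
    double *yc = yp + (R_xlen_t)Ho * Wo * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double coeff = wc[dh + k * dw];
        for (int j = 0; j < Wo; ++j) {
          int wsrc = j * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          const double *xcol = xc + (R_xlen_t)H * wsrc;
          double *ycol = yc + (R_xlen_t)Ho * j;
          int h0 = -pad + dh;
          int i_lo = 0, i_hi = Ho;
          while (i_lo < Ho && h0 + i_lo * stride < 0) ++i_lo;
          while (i_hi > i_lo && h0 + (i_hi - 1) * stride >= H) --i_hi;
          for (int i = i_lo; i < i_hi; ++i)
            ycol[i] += coeff * xcol[h0 + i * stride];
        }
      }
    }
  }
  return y;
}

// Backward pass of the depthwise convolution.

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector dy, int H, int W, int C,
                    NumericVector w, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C);
  NumericVector dw_out((R_xlen_t)k * k * C);
  const double *xp = x.begin();
  const double *wp = w.begin();
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  double *dwp = dw_out.begin();
  for (int c = 0; c < C; ++c) {
    const double *wc = wp + (R_xlen_t)k * k * c;
    const double *xc = xp + (R_xlen_t)H * W * c;
    const double *dyc = dyp + (R_xlen_t)Ho * Wo * c;
    double *dxc = dxp + (R_xlen_t)H * W * c;
    double *dwc = dwp + (R_xlen_t)k * k * c;
    for (int dwi = 0; dwi < k; ++dwi) {
      for (int dh = 0; dh < k; ++dh) {
        double coeff = wc[dh + k * dwi];
        double acc = 0.0;
        for (int j = 0; j < Wo; ++j) {
          int wsrc = j * stride - pad + dwi;
          if (wsrc < 0 || wsrc >= W) continue;
          const double *xcol = xc + (R_xlen_t)H * wsrc;
          double *dxcol = dxc + (R_xlen_t)H * wsrc;
          const double *gcol = dyc + (R_xlen_t)Ho * j;
          int h0 = -pad + dh;
          int i_lo = 0, i_hi = Ho;
          while (i_lo < Ho && h0 + i_lo * stride < 0) ++i_lo;
          while (i_hi > i_lo && h0 + (i_hi - 1) * stride >= H) --i_hi;
          for (int i = i_lo; i < i_hi; ++i) {
            int hsrc = h0 + i * stride;
            double g = gcol[i];
            dxcol[hsrc] += coeff * g;
            acc += g * xcol[hsrc];
          }
        }
        dwc[dh + k * dwi] += acc;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw_out);
}

// Per-channel normalization helpers. x is (H*W, C) column-major.

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, int hw, int C, NumericVector gamma,
                NumericVector beta, NumericVector mu, NumericVector invstd) {
  NumericVector xhat((R_xlen_t)hw * C), y((R_xlen_t)hw * C);
  const double *xp = x.begin();
  double *hp = xhat.begin(), *yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
    const double *xc = xp + (R_xlen_t)hw * c;
    double *hc = hp + (R_xlen_t)hw * c, *yc = yp + (R_xlen_t)hw * c;
    for (int i = 0; i < hw; ++i) {
      double h = (xc[i] - m) * is;
      hc[i] = h;
      yc[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// [[Rcpp::export]]
NumericVector bn_bwd_cpp(NumericVector xhat, NumericVector dy, int hw, int C,
                         NumericVector gamma, NumericVector invstd,
                         bool train) {
  NumericVector dx((R_xlen_t)hw * C);
  const double *hp = xhat.begin(), *dp = dy.begin();
  double *op = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], is = invstd[c];
    const double *hc = hp + (R_xlen_t)hw * c, *dc = dp + (R_xlen_t)hw * c;
    double *oc = op + (R_xlen_t)hw * c;
    if (train) {
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < hw; ++i) {
        double dh = dc[i] * g;
        s1 += dh;
        s2 += dh * hc[i];
      }
      double m1 = s1 / hw, m2 = s2 / hw;
      for (int i = 0; i < hw; ++i)
        oc[i] = (dc[i] * g - m1 - hc[i] * m2) * is;
    } else {
      for (int i = 0; i < hw; ++i) oc[i] = dc[i] * g * is;
    }
  }
  return dx;
}

// Channel means and biased variances of x viewed as (H*W, C).

// [[Rcpp::export]]
List channel_stats_cpp(NumericVector x, int hw, int C) {
  NumericVector mu(C), v(C);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)hw * c;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    double m = s / hw;
    mu[c] = m;
    v[c] = s2 / hw - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}
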