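// Convolution primitives for the surrogate networks.
//
// Tensors are R arrays in (H, W, C, N) layout (column-major). Convolution
// weights are (Cout x k*k*Cin) matrices whose column index runs kernel-row
// fastest, then kernel-col, then input channel. The im2col buffer is kept
// transposed — rows are output pixels (oh fastest, then ow, then sample) —
// so that both its construction and the col2im scatter reduce to contiguous
// block copies/adds, and each layer costs a single BLAS gemm over the whole
// minibatch. Transpose-convolution weights are (Cout, Cin, k, k) arrays;
// their spatial loops are small (bottleneck/decoder feature maps), so they
// use direct accumulation. Plain convolutions are stride 1 (the
// architectures preserve or collapse size via padding / valid kernels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector make4d(int a, int b, int c, int d,
                                   bool zero = true) {
  // no_init skips R's zero-fill — only for buffers that are fully overwritten
  NumericVector v = zero ? NumericVector((size_t)a * b * c * d)
                         : NumericVector(no_init((size_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Grow-only scratch buffers reused across calls (R is single-threaded;
// these hold call-local intermediates only, never state).
static std::vector<double>& scratch(int which, size_t n) {
  static std::vector<double> bufs[3];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

static inline IntegerVector tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) tensor");
  return d;
}

// colsT: (Ho*Wo*N) x (k*k*C); column q = kr + k*kc + k*k*c holds the input
// value at (oh + kr - pad, ow + kc - pad) for every output pixel/sample.
static void im2colT(const double* x, int H, int W, int C, int N,
                    int k, int pad, int Ho, int Wo, arma::mat& colsT) {
  const size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int q = kr + k * kc + k * k * c;
        double* col = colsT.colptr(q);
        int lo = std::max(0, pad - kr), hi = std::min(Ho, H + pad - kr);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          double* dst = col + HoWo * n;
          for (int ow = 0; ow < Wo; ++ow, dst += Ho) {
            int iw = ow + kc - pad;
            if (iw < 0 || iw >= W) { std::fill(dst, dst + Ho, 0.0); continue; }
            const double* src = xc + (size_t)H * iw + (lo + kr - pad);
            if (lo > 0) std::fill(dst, dst + lo, 0.0);
            std::copy(src, src + (hi - lo), dst + lo);
            if (hi < Ho) std::fill(dst + hi, dst + Ho, 0.0);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericMatrix Wm, NumericVector b,
                        int k, int pad) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wm.nrow();
  int kkC = k * k * C;
  if (Wm.ncol() != kkC) stop("weight shape mismatch");
  int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  const size_t HoWo = (size_t)Ho * Wo, M = HoWo * N;

  arma::mat Wa(Wm.begin(), Cout, kkC, false, true);
  arma::mat colsT(scratch(0, M * kkC).data(), M, kkC, false, true);
  im2colT(x.begin(), H, W, C, N, k, pad, Ho, Wo, colsT);
  arma::mat out(scratch(1, M * Cout).data(), M, Cout, false, true);
  out = colsT * Wa.t();  // M x Cout

  NumericVector y = make4d(Ho, Wo, Cout, N, false);
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* src = out.colptr(co);
    double bc = b[co];
    for (int n = 0; n < N; ++n) {
      double* dst = yp + HoWo * (co + (size_t)Cout * n);
      const double* s = src + HoWo * n;
      for (size_t j = 0; j < HoWo; ++j) dst[j] = s[j] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericMatrix Wm, NumericVector dy,
               int k, int pad, bool need_dx = true) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = tensor_dims(dy);
  int Ho = dd[0], Wo = dd[1], Cout = dd[2];
  int kkC = k * k * C;
  if (Wm.nrow() != Cout || Wm.ncol() != kkC) stop("weight shape mismatch");
  if (dd[3] != N) stop("batch mismatch");
  const size_t HoWo = (size_t)Ho * Wo, M = HoWo * N;

  arma::mat Wa(Wm.begin(), Cout, kkC, false, true);
  arma::mat colsT(scratch(0, M * kkC).data(), M, kkC, false, true);
  im2colT(x.begin(), H, W, C, N, k, pad, Ho, Wo, colsT);

  arma::mat dyT(scratch(1, M * Cout).data(), M, Cout, false, true);
  const double* dyp = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    double* dst = dyT.colptr(co);
    for (int n = 0; n < N; ++n)
      std::copy(dyp + HoWo * (co + (size_t)Cout * n),
                dyp + HoWo * (co + (size_t)Cout * n) + HoWo,
                dst + HoWo * n);
  }

  arma::mat G = colsT.t() * dyT;          // kkC x Cout
  arma::mat dW = G.t();
  arma::rowvec db = arma::sum(dyT, 0);

  NumericVector dx = make4d(H, W, C, N);
  if (need_dx) {
    arma::mat dcolsT(scratch(2, M * kkC).data(), M, kkC, false, true);
    dcolsT = dyT * Wa;                    // M x kkC
    double* dxp = dx.begin();
    for (int c = 0; c < C; ++c) {
      for (int kc = 0; kc < k; ++kc) {
        for (int kr = 0; kr < k; ++kr) {
          int q = kr + k * kc + k * k * c;
          const double* col = dcolsT.colptr(q);
          int lo = std::max(0, pad - kr), hi = std::min(Ho, H + pad - kr);
          for (int n = 0; n < N; ++n) {
            double* dxc = dxp + (size_t)H * W * (c + (size_t)C * n);
            const double* src = col + HoWo * n;
            for (int ow = 0; ow < Wo; ++ow) {
              int iw = ow + kc - pad;
              if (iw < 0 || iw >= W) continue;
              double* dst = dxc + (size_t)H * iw + (lo + kr - pad);
              const double* s = src + (size_t)Ho * ow;
              for (int oh = lo; oh < hi; ++oh) dst[oh - lo] += s[oh];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = wrap(arma::vec(db.t())));
}

// [[Rcpp::export]]
NumericVector tconv2d_fw(NumericVector x, NumericVector Wt, NumericVector b,
                         int stride, int pad) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = Wt.attr("dim");
  if (wd.size() != 4 || wd[1] != Cin) stop("tconv weight shape mismatch");
  int Cout = wd[0], k = wd[2];
  if (wd[3] != k) stop("tconv kernel must be square");
  int Ho = (H - 1) * stride + k - 2 * pad;
  int Wo = (W - 1) * stride + k - 2 * pad;
  if (Ho < 1 || Wo < 1) stop("degenerate transpose-conv output");
  const size_t HW = (size_t)H * W, Mp = HW * N;
  const int kkCo = k * k * Cout;

  // xT: (H*W*N) x Cin, gathered channel-major
  arma::mat xT(scratch(0, Mp * Cin).data(), Mp, Cin, false, true);
  const double* xp = x.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    double* dst = xT.colptr(ci);
    for (int n = 0; n < N; ++n)
      std::copy(xp + HW * (ci + (size_t)Cin * n),
                xp + HW * (ci + (size_t)Cin * n) + HW, dst + HW * n);
  }
  // Wf: Cin x (Cout*k*k); column q = co + Cout*(kr + k*kc)
  arma::mat Wf(scratch(1, (size_t)Cin * kkCo).data(), Cin, kkCo, false, true);
  const double* wp = Wt.begin();
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr)
      for (int ci = 0; ci < Cin; ++ci) {
        const double* wk = wp + (size_t)Cout *
          (ci + (size_t)Cin * (kr + (size_t)k * kc));
        for (int co = 0; co < Cout; ++co)
          Wf(ci, co + Cout * (kr + k * kc)) = wk[co];
      }
  arma::mat P(scratch(2, Mp * kkCo).data(), Mp, kkCo, false, true);
  P = xT * Wf;  // contribution of each input pixel to each (co, kr, kc)

  NumericVector y = make4d(Ho, Wo, Cout, N, false);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* yc = yp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      double bc = b[co];
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j) yc[j] = bc;
    }
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr)
      for (int co = 0; co < Cout; ++co) {
        const double* col = P.colptr(co + Cout * (kr + k * kc));
        for (int n = 0; n < N; ++n) {
          double* yc = yp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
          for (int w = 0; w < W; ++w) {
            int ow = w * stride + kc - pad;
            if (ow < 0 || ow >= Wo) continue;
            const double* src = col + HW * n + (size_t)H * w;
            double* dst = yc + (size_t)Ho * ow;
            for (int h = 0; h < H; ++h) {
              int oh = h * stride + kr - pad;
              if (oh >= 0 && oh < Ho) dst[oh] += src[h];
            }
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
List tconv2d_bw(NumericVector x, NumericVector Wt, NumericVector dy,
                int stride, int pad) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = Wt.attr("dim");
  int Cout = wd[0], k = wd[2];
  IntegerVector dd = tensor_dims(dy);
  int Ho = dd[0], Wo = dd[1];
  if (dd[2] != Cout || dd[3] != N) stop("gradient shape mismatch");
  const size_t HW = (size_t)H * W, Mp = HW * N;
  const int kkCo = k * k * Cout;

  // G: (H*W*N) x (Cout*k*k); G(row, q) = dy at the pixel this input position
  // touched through kernel offset (kr, kc), or 0 outside the output.
  arma::mat G(scratch(0, Mp * kkCo).data(), Mp, kkCo, false, true);
  const double* dyp = dy.begin();
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr)
      for (int co = 0; co < Cout; ++co) {
        double* col = G.colptr(co + Cout * (kr + k * kc));
        for (int n = 0; n < N; ++n) {
          const double* dyc = dyp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
          for (int w = 0; w < W; ++w) {
            int ow = w * stride + kc - pad;
            double* dst = col + HW * n + (size_t)H * w;
            if (ow < 0 || ow >= Wo) { std::fill(dst, dst + H, 0.0); continue; }
            const double* src = dyc + (size_t)Ho * ow;
            for (int h = 0; h < H; ++h) {
              int oh = h * stride + kr - pad;
              dst[h] = (oh >= 0 && oh < Ho) ? src[oh] : 0.0;
            }
          }
        }
      }

  arma::mat xT(scratch(1, Mp * Cin).data(), Mp, Cin, false, true);
  const double* xp = x.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    double* dst = xT.colptr(ci);
    for (int n = 0; n < N; ++n)
      std::copy(xp + HW * (ci + (size_t)Cin * n),
                xp + HW * (ci + (size_t)Cin * n) + HW, dst + HW * n);
  }

  arma::mat dWf = xT.t() * G;  // Cin x (Cout*k*k)
  NumericVector dW = make4d(Cout, Cin, k, k, false);
  double* dWp = dW.begin();
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr)
      for (int ci = 0; ci < Cin; ++ci) {
        double* dWk = dWp + (size_t)Cout *
          (ci + (size_t)Cin * (kr + (size_t)k * kc));
        for (int co = 0; co < Cout; ++co)
          dWk[co] = dWf(ci, co + Cout * (kr + k * kc));
      }

  // Wf as in forward for dx = G * Wf.t()
  arma::mat Wf(scratch(2, (size_t)Cin * kkCo).data(), Cin, kkCo, false, true);
  const double* wp = Wt.begin();
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr)
      for (int ci = 0; ci < Cin; ++ci) {
        const double* wk = wp + (size_t)Cout *
          (ci + (size_t)Cin * (kr + (size_t)k * kc));
        for (int co = 0; co < Cout; ++co)
          Wf(ci, co + Cout * (kr + k * kc)) = wk[co];
      }
  arma::mat dxT = G * Wf.t();  // Mp x Cin

  NumericVector dx = make4d(H, W, Cin, N, false);
  double* dxp = dx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = dxT.colptr(ci);
    for (int n = 0; n < N; ++n)
      std::copy(src + HW * n, src + HW * n + HW,
                dxp + HW * (ci + (size_t)Cin * n));
  }

  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      double sum = 0.0;
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j) sum += dyc[j];
      db[co] += sum;
    }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Leaky-ReLU forward/backward (slope 0 = plain ReLU); preserves dim.
// [[Rcpp::export]]
NumericVector act_fw(NumericVector x, double slope) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// [[Rcpp::export]]
NumericVector act_bw(NumericVector x, NumericVector dy, double slope) {
  if (x.size() != dy.size()) stop("activation gradient size mismatch");
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = dy.attr("dim");
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    op[i] = xp[i] > 0 ? dp[i] : slope * dp[i];
  return dx;
}

// Batch norm over (H, W, N) per channel; population variance.
// [[Rcpp::export]]
List bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
           NumericVector running_mean, NumericVector running_var,
           double momentum, double eps, bool training) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double cnt = (double)HW * N;

  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  NumericVector mu(C), inv_sd(C);
  NumericVector new_rm = clone(running_mean), new_rv = clone(running_var);
  const double* xp = x.begin();
  double* yp = y.begin();

  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + HW * (c + (size_t)C * n);
        for (size_t j = 0; j < HW; ++j) { s += xc[j]; s2 += xc[j] * xc[j]; }
      }
      m = s / cnt;
      v = s2 / cnt - m * m;
      if (v < 0) v = 0;
      new_rm[c] = (1 - momentum) * new_rm[c] + momentum * m;
      new_rv[c] = (1 - momentum) * new_rv[c] + momentum * v;
    } else {
      m = running_mean[c];
      v = running_var[c];
    }
    double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    inv_sd[c] = is;
    double g = gamma[c] * is, bshift = beta[c] - gamma[c] * is * m;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      double* yc = yp + HW * (c + (size_t)C * n);
      for (size_t j = 0; j < HW; ++j) yc[j] = g * xc[j] + bshift;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv_sd"] = inv_sd,
                      _["running_mean"] = new_rm, _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List bn_bw(NumericVector x, NumericVector dy, NumericVector gamma,
           NumericVector mu, NumericVector inv_sd, bool training) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double cnt = (double)HW * N;

  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = x.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();

  for (int c = 0; c < C; ++c) {
    double is = inv_sd[c], m = mu[c];
    double s_dy = 0.0, s_dyxh = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      const double* gc = dyp + HW * (c + (size_t)C * n);
      for (size_t j = 0; j < HW; ++j) {
        s_dy += gc[j];
        s_dyxh += gc[j] * (xc[j] - m) * is;
      }
    }
    dgamma[c] = s_dyxh;
    dbeta[c] = s_dy;
    if (training) {
      double a = gamma[c] * is;
      double mean_dy = s_dy / cnt, mean_dyxh = s_dyxh / cnt;
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + HW * (c + (size_t)C * n);
        const double* gc = dyp + HW * (c + (size_t)C * n);
        double* oc = dxp + HW * (c + (size_t)C * n);
        for (size_t j = 0; j < HW; ++j) {
          double xh = (xc[j] - m) * is;
          oc[j] = a * (gc[j] - mean_dy - xh * mean_dyxh);
        }
      }
    } else {
      double a = gamma[c] * is;
      for (int n = 0; n < N; ++n) {
        const double* gc = dyp + HW * (c + (size_t)C * n);
        double* oc = dxp + HW * (c + (size_t)C * n);
        for (size_t j = 0; j < HW; ++j) oc[j] = a * gc[j];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
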