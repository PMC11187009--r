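// Low-level tensor kernels for the layer-graph engine.
// Layout convention: feature arrays are R arrays dim (C, H, W, N), column-major.
// Conv weights are R matrices dim (Cout, (Cin/groups)*K*K); column index
// r = ci_local*K*K + kh*K + kw matches the im2col row layout below.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// gather one image's channels [c0, c0+Cg) into the im2col matrix
static void im2col(const double* x, int C, int H, int W, int c0, int Cg,
                   int K, int stride, int pad, arma::mat& M) {
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int col = oh + Ho * ow;
      double* mcol = M.colptr(col);
      for (int kw = 0; kw < K; ++kw) {
        const int iw = ow * stride - pad + kw;
        for (int kh = 0; kh < K; ++kh) {
          const int ih = oh * stride - pad + kh;
          const bool inside = (ih >= 0 && ih < H && iw >= 0 && iw < W);
          for (int ci = 0; ci < Cg; ++ci) {
            const int r = ci * K * K + kh * K + kw;
            mcol[r] = inside ? x[(c0 + ci) + C * (ih + (long)H * iw)] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-accumulate the im2col gradient back onto the input gradient
static void col2im(const arma::mat& M, double* dx, int C, int H, int W, int c0,
                   int Cg, int K, int stride, int pad) {
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int col = oh + Ho * ow;
      const double* mcol = M.colptr(col);
      for (int kw = 0; kw < K; ++kw) {
        const int iw = ow * stride - pad + kw;
        if (iw < 0 || iw >= W) continue;
        for (int kh = 0; kh < K; ++kh) {
          const int ih = oh * stride - pad + kh;
          if (ih < 0 || ih >= H) continue;
          for (int ci = 0; ci < Cg; ++ci) {
            const int r = ci * K * K + kh * K + kw;
            dx[(c0 + ci) + C * (ih + (long)H * iw)] += mcol[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix w,
                            Nullable<NumericVector> bias, int K, int stride,
                            int pad, int groups) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], N = d.size() > 3 ? d[3] : 1;
  const int Cout = w.nrow(), Cg = C / groups, CoutG = Cout / groups;
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector y(((long)Cout) * Ho * Wo * N);
  arma::mat Wm(w.begin(), Cout, w.ncol(), false, true);
  arma::mat M(Cg * K * K, Ho * Wo);
  const bool has_b = bias.isNotNull();
  NumericVector b = has_b ? NumericVector(bias) : NumericVector(0);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long)n * C * H * W;
    double* yn = y.begin() + (long)n * Cout * Ho * Wo;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, C, H, W, g * Cg, Cg, K, stride, pad, M);
      arma::mat Yg = Wm.rows(g * CoutG, (g + 1) * CoutG - 1) * M;
      for (int col = 0; col < Ho * Wo; ++col)
        for (int co = 0; co < CoutG; ++co)
          yn[(g * CoutG + co) + (long)Cout * col] = Yg(co, col);
    }
    if (has_b)
      for (int col = 0; col < Ho * Wo; ++col)
        for (int co = 0; co < Cout; ++co) yn[co + (long)Cout * col] += b[co];
  }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix w, NumericVector dy, int K,
                   int stride, int pad, int groups, bool has_bias) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], N = d.size() > 3 ? d[3] : 1;
  const int Cout = w.nrow(), Cg = C / groups, CoutG = Cout / groups;
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector dx(x.size());
  NumericMatrix dw(w.nrow(), w.ncol());
  NumericVector db(has_bias ? Cout : 0);
  arma::mat Wm(w.begin(), Cout, w.ncol(), false, true);
  arma::mat dWm(dw.begin(), Cout, dw.ncol(), false, true);
  arma::mat M(Cg * K * K, Ho * Wo), dYg(CoutG, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long)n * C * H * W;
    const double* dyn = dy.begin() + (long)n * Cout * Ho * Wo;
    double* dxn = dx.begin() + (long)n * C * H * W;
    for (int g = 0; g < groups; ++g) {
      for (int col = 0; col < Ho * Wo; ++col)
        for (int co = 0; co < CoutG; ++co)
          dYg(co, col) = dyn[(g * CoutG + co) + (long)Cout * col];
      im2col(xn, C, H, W, g * Cg, Cg, K, stride, pad, M);
      dWm.rows(g * CoutG, (g + 1) * CoutG - 1) += dYg * M.t();
      arma::mat dM = Wm.rows(g * CoutG, (g + 1) * CoutG - 1).t() * dYg;
      col2im(dM, dxn, C, H, W, g * Cg, Cg, K, stride, pad);
    }
    if (has_bias)
      for (int col = 0; col < Ho * Wo; ++col)
        for (int co = 0; co < Cout; ++co) db[co] += dyn[co + (long)Cout * col];
  }
  dx.attr("dim") = d;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int K, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], N = d.size() > 3 ? d[3] : 1;
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector y(((long)C) * Ho * Wo * N);
  IntegerVector idx(y.size());  // 1-based linear index into x, for backward
  for (int n = 0; n < N; ++n) {
    const long xoff = (long)n * C * H * W, yoff = (long)n * C * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; long bi = -1;
          for (int kw = 0; kw < K; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              const long li = xoff + c + C * (ih + (long)H * iw);
              if (x[li] > best) { best = x[li]; bi = li; }
            }
          }
          const long lo = yoff + c + (long)C * (oh + (long)Ho * ow);
          y[lo] = best;
          idx[lo] = (int)(bi + 1);
        }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  long n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  for (long i = 0; i < (long)dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
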