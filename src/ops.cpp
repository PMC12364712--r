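// Low-level image-tensor primitives for the translator/discriminator stack.
// Layout convention: batched tensors are R arrays dim (H, W, C, N), column-major.
// Convolutions are cross-correlations (deep-learning convention) with symmetric
// zero padding; backward passes are exact adjoints of the forward ops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col: returns P x K matrix, P = Ho*Wo (col index p = ho + Ho*wo),
// K = k*k*Cin (row index r = kh + k*kw + k*k*ci)
static void im2col(const double* x, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& Cmat) {
  const int P = Ho * Wo;
  Cmat.zeros(P, k * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        double* col = Cmat.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            col[ho + (size_t)Ho * wo] = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& Cmat, double* x, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        const double* col = Cmat.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims incompatible with input");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("output size would be non-positive");
  NumericVector out(Ho * Wo * (size_t)Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat Cmat;
  const int P = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Ho, Wo, Cmat);
    arma::mat Y = Cmat * Wm;            // P x Cout
    Y.each_row() += bv;
    std::copy(Y.memptr(), Y.memptr() + (size_t)P * Cout,
              out.begin() + (size_t)n * P * Cout);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector dy, NumericVector w,
                                  int stride, int pad, int H, int W) {
  int Ho, Wo, Cout, N;
  get_dims4(dy, Ho, Wo, Cout, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2];
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  const int P = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout, P, Cout, false, true);
    arma::mat dC = dY * Wm.t();         // P x K
    col2im(dC, dx.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Ho, Wo);
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_weights(NumericVector x, NumericVector dy,
                            int k, int stride, int pad) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  int Ho, Wo, Cout, N2;
  get_dims4(dy, Ho, Wo, Cout, N2);
  if (N2 != N) stop("batch mismatch");
  arma::mat dWm(k * k * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat Cmat;
  const int P = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Ho, Wo, Cmat);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout, P, Cout, false, true);
    dWm += Cmat.t() * dY;
    db += arma::sum(dY, 0);
  }
  NumericVector dw(dWm.memptr(), dWm.memptr() + dWm.n_elem);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dw"] = dw, _["db"] = NumericVector(db.begin(), db.end()));
}

// nearest-neighbour upsampling by an integer factor
// [[Rcpp::export]]
NumericVector cpp_upsample_nn(NumericVector x, int f) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = H * f, Wo = W * f;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)(n * C + c) * H * W;
      double* yo = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const int wi = wo / f;
        for (int ho = 0; ho < Ho; ++ho)
          yo[ho + (size_t)Ho * wo] = xi[(ho / f) + (size_t)H * wi];
      }
    }
  return out;
}

// adjoint of nearest-neighbour upsampling (block sum)
// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector dy, int f) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  const int H = Ho / f, W = Wo / f;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gi = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      double* go = out.begin() + (size_t)(n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          go[(ho / f) + (size_t)H * (wo / f)] += gi[ho + (size_t)Ho * wo];
    }
  return out;
}

// block-average pooling by an integer factor (used to resample H&E onto the marker grid)
// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int f) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = H / f, Wo = W / f;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (f * f);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)(n * C + c) * H * W;
      double* yo = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int dw = 0; dw < f; ++dw)
            for (int dh = 0; dh < f; ++dh)
              s += xi[(ho * f + dh) + (size_t)H * (wo * f + dw)];
          yo[ho + (size_t)Ho * wo] = s * inv;
        }
    }
  return out;
}

// separable Gaussian smoothing with zero padding, applied per channel/sample;
// self-adjoint (symmetric kernel + zero padding), so also used as its own backward
// [[Rcpp::export]]
NumericVector cpp_blur_sep(NumericVector x, NumericVector kern) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int kl = kern.size(), rad = (kl - 1) / 2;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<double> tmp((size_t)H * W);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)(n * C + c) * H * W;
      double* yo = out.begin() + (size_t)(n * C + c) * H * W;
      // vertical pass
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            const int hh = h + t;
            if (hh >= 0 && hh < H) s += kern[t + rad] * xi[hh + (size_t)H * w];
          }
          tmp[h + (size_t)H * w] = s;
        }
      // horizontal pass
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            const int ww = w + t;
            if (ww >= 0 && ww < W) s += kern[t + rad] * tmp[h + (size_t)H * ww];
          }
          yo[h + (size_t)H * w] = s;
        }
    }
  return out;
}

// decimation (keep every f-th pixel starting at 0) and its adjoint (zero-stuffing)
// [[Rcpp::export]]
NumericVector cpp_decimate(NumericVector x, int f) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = (H + f - 1) / f, Wo = (W + f - 1) / f;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)(n * C + c) * H * W;
      double* yo = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          yo[ho + (size_t)Ho * wo] = xi[(ho * f) + (size_t)H * (wo * f)];
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_decimate_bwd(NumericVector dy, int f, int H, int W) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gi = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      double* go = out.begin() + (size_t)(n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          go[(ho * f) + (size_t)H * (wo * f)] = gi[ho + (size_t)Ho * wo];
    }
  return out;
}
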