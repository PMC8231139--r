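// Dense numeric kernels for the U-Net: 3x3 same-padding convolution
// forward/backward via im2col + BLAS gemm, 2x2 max-pooling and 2x2
// transposed convolution. Arrays follow R column-major layout [H, W, C, N].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline Dimension dim4(int a, int b, int c, int d) {
  return Dimension(IntegerVector::create(a, b, c, d));
}

// K is (H*W) x (9*Cin); column index = kh + 3*kw + 9*cin, row = h + H*w.
// Column-major layout makes each (kh, kw, cin) fill a contiguous column,
// written as shifted copies of the image plane.
static inline void im2col3(const double* x, int H, int W, int Cin, arma::fmat& K) {
  const int HW = H * W;
  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = x + (std::size_t)cin * HW;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        float* Kc = K.colptr(kh + 3 * kw + 9 * cin);
        const int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          float* dst = Kc + (std::size_t)H * w;
          const int ws = w + dw;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0f);
            continue;
          }
          const double* src = xc + (std::size_t)H * ws;
          const int h0 = dh < 0 ? 1 : 0;       // first valid output h
          const int h1 = dh > 0 ? H - 1 : H;   // one past last valid h
          if (h0 > 0) dst[0] = 0.0f;
          if (h1 < H) dst[H - 1] = 0.0f;
          for (int h = h0; h < h1; ++h) dst[h] = (float)src[h + dh];
        }
      }
    }
  }
}

// scatter-add of dK (same layout as im2col3) back onto the input gradient
static inline void col2im3(const arma::fmat& dK, int H, int W, int Cin, double* dx) {
  const int HW = H * W;
  for (int cin = 0; cin < Cin; ++cin) {
    double* dxc = dx + (std::size_t)cin * HW;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const float* Kc = dK.colptr(kh + 3 * kw + 9 * cin);
        const int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const float* src = Kc + (std::size_t)H * w;
          double* dst = dxc + (std::size_t)H * ws;
          const int h0 = dh < 0 ? 1 : 0;
          const int h1 = dh > 0 ? H - 1 : H;
          for (int h = h0; h < h1; ++h) dst[h + dh] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != Cin)
    stop("weight dims incompatible with input");
  const int HW = H * W;
  NumericVector y(dim4(H, W, Cout, N));
  arma::mat Wd(w.begin(), 9 * Cin, Cout, false, true);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat K(HW, 9 * Cin);
  arma::fmat Yf(HW, Cout);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (std::size_t)n * HW * Cin, H, W, Cin, K);
    Yf = K * Wm;
    double* yp = y.begin() + (std::size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float* src = Yf.colptr(co);
      double* dst = yp + (std::size_t)co * HW;
      const double bc = b[co];
      for (int p = 0; p < HW; ++p) dst[p] = (double)src[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  const int HW = H * W;
  NumericVector dx(dim4(H, W, Cin, N));
  NumericVector dw(dim4(3, 3, Cin, Cout));
  NumericVector db(Cout);
  arma::mat Wd(w.begin(), 9 * Cin, Cout, false, true);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat dWf(9 * Cin, Cout, arma::fill::zeros);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::fmat K(HW, 9 * Cin);
  arma::fmat dK(HW, 9 * Cin);
  arma::fmat dYf(HW, Cout);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (std::size_t)n * HW * Cin, H, W, Cin, K);
    arma::mat dY(dy.begin() + (std::size_t)n * HW * Cout, HW, Cout, false, true);
    dYf = arma::conv_to<arma::fmat>::from(dY);
    dWf += K.t() * dYf;
    dbv += arma::sum(dY, 0).t();
    dK = dYf * Wm.t();
    col2im3(dK, H, W, Cin, dx.begin() + (std::size_t)n * HW * Cin);
  }
  arma::mat dWm(dw.begin(), 9 * Cin, Cout, false, true);
  dWm = arma::conv_to<arma::mat>::from(dWf);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(dim4(Ho, Wo, C, N));
  IntegerVector idx(dim4(Ho, Wo, C, N));
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const std::size_t planes = (std::size_t)C * N;
  for (std::size_t cn = 0; cn < planes; ++cn) {
    const double* xpl = xp + cn * H * W;
    double* ypl = yp + cn * Ho * Wo;
    int* ipl = ip + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -1e300;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            double v = xpl[(2 * ho + di) + (std::size_t)H * (2 * wo + dj)];
            if (v > best) { best = v; bi = di + 2 * dj; }
          }
        }
        ypl[ho + (std::size_t)Ho * wo] = best;
        ipl[ho + (std::size_t)Ho * wo] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(dim4(H, W, C, N));
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const std::size_t planes = (std::size_t)C * N;
  for (std::size_t cn = 0; cn < planes; ++cn) {
    const double* dypl = dyp + cn * Ho * Wo;
    const int* ipl = ip + cn * Ho * Wo;
    double* dxpl = dxp + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int bi = ipl[ho + (std::size_t)Ho * wo];
        int di = bi % 2, dj = bi / 2;
        dxpl[(2 * ho + di) + (std::size_t)H * (2 * wo + dj)] +=
          dypl[ho + (std::size_t)Ho * wo];
      }
  }
  return dx;
}

// 2x2 stride-2 transposed convolution: y[2h+dh, 2w+dw, co] =
// sum_ci x[h, w, ci] * w[dh, dw, ci, co]
// [[Rcpp::export]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  const int HW = H * W;
  NumericVector y(dim4(2 * H, 2 * W, Cout, N));
  for (int n = 0; n < N; ++n) {
    arma::mat X(x.begin() + (std::size_t)n * HW * Cin, HW, Cin, false, true);
    for (int dw2 = 0; dw2 < 2; ++dw2) {
      for (int dh = 0; dh < 2; ++dh) {
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = w[dh + 2 * dw2 + 4 * ci + 4 * (std::size_t)Cin * co];
        arma::mat Y = X * Wsub; // HW x Cout
        double* yp = y.begin() + (std::size_t)n * 4 * HW * Cout;
        for (int co = 0; co < Cout; ++co) {
          double* ypl = yp + (std::size_t)co * 4 * HW;
          for (int w2 = 0; w2 < W; ++w2)
            for (int h = 0; h < H; ++h)
              ypl[(2 * h + dh) + (std::size_t)2 * H * (2 * w2 + dw2)] =
                Y(h + (std::size_t)H * w2, co);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  const int HW = H * W;
  NumericVector dx(dim4(H, W, Cin, N));
  NumericVector dwv(dim4(2, 2, Cin, Cout));
  for (int n = 0; n < N; ++n) {
    arma::mat X(x.begin() + (std::size_t)n * HW * Cin, HW, Cin, false, true);
    arma::mat dX(dx.begin() + (std::size_t)n * HW * Cin, HW, Cin, false, true);
    const double* dyp = dy.begin() + (std::size_t)n * 4 * HW * Cout;
    for (int dw2 = 0; dw2 < 2; ++dw2) {
      for (int dh = 0; dh < 2; ++dh) {
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = w[dh + 2 * dw2 + 4 * ci + 4 * (std::size_t)Cin * co];
        arma::mat dYblk(HW, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* dypl = dyp + (std::size_t)co * 4 * HW;
          for (int w2 = 0; w2 < W; ++w2)
            for (int h = 0; h < H; ++h)
              dYblk(h + (std::size_t)H * w2, co) =
                dypl[(2 * h + dh) + (std::size_t)2 * H * (2 * w2 + dw2)];
        }
        dX += dYblk * Wsub.t();
        arma::mat dWsub = X.t() * dYblk;
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dwv[dh + 2 * dw2 + 4 * ci + 4 * (std::size_t)Cin * co] += dWsub(ci, co);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv);
}
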