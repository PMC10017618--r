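// Numeric kernels for the slice-wise U-Net and the surface-distance metric.
// Layout conventions match R: feature maps are (H, W, C, N) column-major
// arrays; 3x3 conv weights are (3, 3, Cin, Cout) so that reshaping to a
// (9*Cin, Cout) matrix is a no-op.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fill rows [row0, row0 + H*W) of `out` with the 3x3 im2col expansion of one
// sample. Inner runs over i are contiguous in source and target: memcpy.
static void im2col3_fill(const double* x, int H, int W, int Cin,
                         arma::mat& out, size_t row0) {
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j0 = 0; j0 < 3; ++j0) {
      for (int i0 = 0; i0 < 3; ++i0) {
        int di = i0 - 1, dj = j0 - 1;
        double* col = out.colptr(i0 + 3 * j0 + 9 * c) + row0;
        int ilo = std::max(0, -di), ihi = std::min(H, H - di);
        int jlo = std::max(0, -dj), jhi = std::min(W, W - dj);
        size_t run = (size_t)(ihi - ilo);
        for (int j = jlo; j < jhi; ++j)
          std::memcpy(col + (size_t)j * H + ilo,
                      xc + (size_t)(j + dj) * H + (ilo + di),
                      run * sizeof(double));
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D (H, W, C, N) array");
  return d;
}

// 3x3 same-padding convolution over the whole batch in one GEMM,
// y = conv(x, W) + b, optionally fused with ReLU.
// [[Rcpp::export(name = ".cpp_conv3_forward")]]
NumericVector cpp_conv3_forward(NumericVector x, NumericVector w, NumericVector b,
                                bool relu = false) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3 || wd[2] != Cin)
    stop("weight array must be (3, 3, Cin, Cout)");
  int Cout = wd[3];
  size_t hw = (size_t)H * W_;
  arma::mat Wm(w.begin(), 9 * Cin, Cout, false, true);
  arma::mat cols(hw * N, 9 * Cin);
  for (int n = 0; n < N; ++n)
    im2col3_fill(x.begin() + (size_t)n * hw * Cin, H, W_, Cin, cols, n * hw);
  arma::mat Y = cols * Wm;
  NumericVector y((size_t)hw * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W_, Cout, N);
  for (int n = 0; n < N; ++n) {
    for (int o = 0; o < Cout; ++o) {
      const double* src = Y.colptr(o) + (size_t)n * hw;
      double* dst = y.begin() + ((size_t)n * Cout + o) * hw;
      double bo = b[o];
      if (relu)
        for (size_t q = 0; q < hw; ++q) { double v = src[q] + bo; dst[q] = v > 0 ? v : 0; }
      else
        for (size_t q = 0; q < hw; ++q) dst[q] = src[q] + bo;
    }
  }
  return y;
}

// Backward of the (optionally ReLU-fused) 3x3 convolution. `y` is the stored
// forward output (post-activation); with relu the incoming gradient is gated
// by y > 0 before everything else. The input gradient is computed as a
// direct convolution of the gated gradient with the 180-degree-rotated
// kernel, which keeps the GEMM inner dimension at 9*Cout.
// [[Rcpp::export(name = ".cpp_conv3_backward")]]
List cpp_conv3_backward(NumericVector x, NumericVector w, NumericVector y,
                        NumericVector dy, bool relu = false) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  size_t hw = (size_t)H * W_;
  // gated gradient, array layout (H, W, Cout, N)
  NumericVector gdy((size_t)hw * Cout * N);
  gdy.attr("dim") = IntegerVector::create(H, W_, Cout, N);
  if (relu) {
    const double* ys = y.begin(); const double* s = dy.begin();
    double* t = gdy.begin();
    size_t total = (size_t)hw * Cout * N;
    for (size_t q = 0; q < total; ++q) t[q] = ys[q] > 0 ? s[q] : 0;
  } else {
    std::memcpy(gdy.begin(), dy.begin(), (size_t)hw * Cout * N * sizeof(double));
  }
  // GEMM layout of the gated gradient for dW and db
  arma::mat dY(hw * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o)
      std::memcpy(dY.colptr(o) + (size_t)n * hw,
                  gdy.begin() + ((size_t)n * Cout + o) * hw,
                  hw * sizeof(double));
  arma::mat cols(hw * N, 9 * Cin);
  for (int n = 0; n < N; ++n)
    im2col3_fill(x.begin() + (size_t)n * hw * Cin, H, W_, Cin, cols, n * hw);
  arma::mat dW = cols.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  // rotated kernel (9*Cout, Cin): Wflip[(i0,j0,o), c] = W[2-i0, 2-j0, c, o]
  arma::mat Wflip(9 * Cout, Cin);
  for (int c = 0; c < Cin; ++c)
    for (int o = 0; o < Cout; ++o)
      for (int j0 = 0; j0 < 3; ++j0)
        for (int i0 = 0; i0 < 3; ++i0)
          Wflip(i0 + 3 * j0 + 9 * o, c) =
            w[(2 - i0) + 3 * (2 - j0) + 9 * ((size_t)c + (size_t)Cin * o)];
  arma::mat colsg(hw * N, 9 * Cout);
  for (int n = 0; n < N; ++n)
    im2col3_fill(gdy.begin() + (size_t)n * hw * Cout, H, W_, Cout, colsg, n * hw);
  arma::mat dX = colsg * Wflip;
  NumericVector dx((size_t)hw * Cin * N);
  dx.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cin; ++c)
      std::memcpy(dx.begin() + ((size_t)n * Cin + c) * hw,
                  dX.colptr(c) + (size_t)n * hw, hw * sizeof(double));
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Instance normalization with affine parameters, optionally fused with ReLU.
// Each (channel, sample) group is normalized over its H*W pixels:
// y = relu(gamma * (x - mu) / sqrt(var + eps) + beta).
// [[Rcpp::export(name = ".cpp_in_forward")]]
List cpp_in_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    double eps = 1e-5, bool relu = true) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W_;
  NumericVector y((size_t)hw * C * N);
  y.attr("dim") = d;
  NumericVector mu(C * N), istd(C * N);
  for (int p = 0; p < C * N; ++p) {
    int c = p % C;
    const double* xp = x.begin() + (size_t)p * hw;
    double* yp = y.begin() + (size_t)p * hw;
    double m = 0, s2 = 0;
    for (size_t q = 0; q < hw; ++q) m += xp[q];
    m /= hw;
    for (size_t q = 0; q < hw; ++q) { double dlt = xp[q] - m; s2 += dlt * dlt; }
    double is = 1.0 / std::sqrt(s2 / hw + eps);
    mu[p] = m; istd[p] = is;
    double g = gamma[c], b = beta[c];
    for (size_t q = 0; q < hw; ++q) {
      double v = g * (xp[q] - m) * is + b;
      yp[q] = (relu && v < 0) ? 0 : v;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export(name = ".cpp_in_backward")]]
List cpp_in_backward(NumericVector x, NumericVector gamma, NumericVector mu,
                     NumericVector istd, NumericVector y, NumericVector dy,
                     bool relu = true) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W_;
  NumericVector dx((size_t)hw * C * N);
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> gdy(hw), xhat(hw);
  for (int p = 0; p < C * N; ++p) {
    int c = p % C;
    const double* xp = x.begin() + (size_t)p * hw;
    const double* yp = y.begin() + (size_t)p * hw;
    const double* dyp = dy.begin() + (size_t)p * hw;
    double* dxp = dx.begin() + (size_t)p * hw;
    double m = mu[p], is = istd[p], g = gamma[c];
    double s1 = 0, s2 = 0;
    for (size_t q = 0; q < hw; ++q) {
      double gd = (relu && yp[q] <= 0) ? 0 : dyp[q];
      double xh = (xp[q] - m) * is;
      gdy[q] = gd; xhat[q] = xh;
      s1 += gd; s2 += gd * xh;
    }
    dbeta[c] += s1;
    dgamma[c] += s2;
    double m1 = s1 / hw, m2 = s2 / hw;
    for (size_t q = 0; q < hw; ++q)
      dxp[q] = g * is * (gdy[q] - m1 - xhat[q] * m2);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 1x1 convolution (channel mixing); weights (Cin, Cout)
// [[Rcpp::export(name = ".cpp_conv1_forward")]]
NumericVector cpp_conv1_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 2 || wd[0] != Cin) stop("weight matrix must be (Cin, Cout)");
  int Cout = wd[1];
  arma::mat Wm(w.begin(), Cin, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((size_t)H * W_ * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W_, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)n * H * W_ * Cin,
                 H * W_, Cin, false, true);
    arma::mat yn = xn * Wm;
    yn.each_row() += bv;
    std::copy(yn.begin(), yn.end(), y.begin() + (size_t)n * H * W_ * Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv1_backward")]]
List cpp_conv1_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[1];
  arma::mat Wm(w.begin(), Cin, Cout, false, true);
  NumericVector dx((size_t)H * W_ * Cin * N);
  dx.attr("dim") = d;
  arma::mat dW(Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)n * H * W_ * Cin,
                 H * W_, Cin, false, true);
    arma::mat dyn(dy.begin() + (size_t)n * H * W_ * Cout, H * W_, Cout, false, true);
    dW += xn.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dxn = dyn * Wm.t();
    std::copy(dxn.begin(), dxn.end(), dx.begin() + (size_t)n * H * W_ * Cin);
  }
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; also returns the argmax for the backward pass
// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], C = d[2], N = d[3];
  if (H % 2 || W_ % 2) stop("maxpool needs even height and width");
  int Ho = H / 2, Wo = W_ / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* xp = x.begin() + p * H * W_;
    double* yp = y.begin() + p * Ho * Wo;
    int* ip = idx.begin() + p * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        int best = 2 * io + 2 * jo * H;
        double bv = xp[best];
        int cand[3] = {2 * io + 1 + 2 * jo * H, 2 * io + (2 * jo + 1) * H,
                       2 * io + 1 + (2 * jo + 1) * H};
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
        yp[io + jo * Ho] = bv;
        ip[io + jo * Ho] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx, int H, int W_) {
  IntegerVector d = dims4(dy);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W_ * C * N);
  dx.attr("dim") = IntegerVector::create(H, W_, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* dyp = dy.begin() + p * Ho * Wo;
    const int* ip = idx.begin() + p * Ho * Wo;
    double* dxp = dx.begin() + p * H * W_;
    for (int q = 0; q < Ho * Wo; ++q) dxp[ip[q]] += dyp[q];
  }
  return dx;
}

// 2x2 up-convolution (transposed convolution, stride 2): each of the four
// output phase offsets is an independent 1x1 convolution of the input.
// Weights (2, 2, Cin, Cout); output (2H, 2W, Cout, N). Optional fused ReLU.
// [[Rcpp::export(name = ".cpp_upconv2_forward")]]
NumericVector cpp_upconv2_forward(NumericVector x, NumericVector w, NumericVector b,
                                  bool relu = false) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 2 || wd[1] != 2 || wd[2] != Cin)
    stop("up-conv weight array must be (2, 2, Cin, Cout)");
  int Cout = wd[3];
  size_t hw = (size_t)H * W_;
  NumericVector y((size_t)4 * hw * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W_, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)n * hw * Cin,
                 hw, Cin, false, true);
    for (int j0 = 0; j0 < 2; ++j0) {
      for (int i0 = 0; i0 < 2; ++i0) {
        // weights of this phase: (Cin, Cout) slice at stride 4
        arma::mat Wo(Cin, Cout);
        for (int o = 0; o < Cout; ++o)
          for (int c = 0; c < Cin; ++c)
            Wo(c, o) = w[i0 + 2 * j0 + 4 * (c + (size_t)Cin * o)];
        arma::mat Yo = xn * Wo;
        for (int o = 0; o < Cout; ++o) {
          double* yp = y.begin() + ((size_t)n * Cout + o) * 4 * hw;
          const double* src = Yo.colptr(o);
          double bo = b[o];
          for (int j = 0; j < W_; ++j)
            for (int i = 0; i < H; ++i) {
              double v = src[(size_t)j * H + i] + bo;
              if (relu && v < 0) v = 0;
              yp[(size_t)(2 * j + j0) * 2 * H + (2 * i + i0)] = v;
            }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upconv2_backward")]]
List cpp_upconv2_backward(NumericVector x, NumericVector w, NumericVector y,
                          NumericVector dy, bool relu = false) {
  IntegerVector d = dims4(x);
  int H = d[0], W_ = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  size_t hw = (size_t)H * W_;
  NumericVector dx((size_t)hw * Cin * N);
  dx.attr("dim") = d;
  NumericVector dWout((size_t)4 * Cin * Cout);
  dWout.attr("dim") = wd;
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)n * hw * Cin,
                 hw, Cin, false, true);
    arma::mat dxn(dx.begin() + (size_t)n * hw * Cin, hw, Cin, false, true);
    for (int j0 = 0; j0 < 2; ++j0) {
      for (int i0 = 0; i0 < 2; ++i0) {
        arma::mat dYo(hw, Cout);
        for (int o = 0; o < Cout; ++o) {
          const double* dyp = dy.begin() + ((size_t)n * Cout + o) * 4 * hw;
          const double* yp = y.begin() + ((size_t)n * Cout + o) * 4 * hw;
          double* dst = dYo.colptr(o);
          double dbo = 0;
          for (int j = 0; j < W_; ++j)
            for (int i = 0; i < H; ++i) {
              size_t q = (size_t)(2 * j + j0) * 2 * H + (2 * i + i0);
              double g = dyp[q];
              if (relu && yp[q] <= 0) g = 0;
              dst[(size_t)j * H + i] = g;
              dbo += g;
            }
          db[o] += dbo;
        }
        arma::mat Wo(Cin, Cout);
        for (int o = 0; o < Cout; ++o)
          for (int c = 0; c < Cin; ++c)
            Wo(c, o) = w[i0 + 2 * j0 + 4 * (c + (size_t)Cin * o)];
        arma::mat dWo = xn.t() * dYo;
        for (int o = 0; o < Cout; ++o)
          for (int c = 0; c < Cin; ++c)
            dWout[i0 + 2 * j0 + 4 * (c + (size_t)Cin * o)] += dWo(c, o);
        dxn += dYo * Wo.t();
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = db);
}

// Directed nearest-neighbour distances between two boundary point sets, in mm.
// Points are (n x 3) matrices of voxel indices; spacing scales each axis.
// [[Rcpp::export(name = ".cpp_directed_distances")]]
NumericVector cpp_directed_distances(NumericMatrix from, NumericMatrix to,
                                     NumericVector spacing) {
  int n1 = from.nrow(), n2 = to.nrow();
  if (n2 == 0) stop("empty target point set");
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out(n1);
  for (int i = 0; i < n1; ++i) {
    double ax = from(i, 0) * sx, ay = from(i, 1) * sy, az = from(i, 2) * sz;
    double best = R_PosInf;
    for (int j = 0; j < n2; ++j) {
      double dx = ax - to(j, 0) * sx, dy = ay - to(j, 1) * sy, dz = az - to(j, 2) * sz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
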