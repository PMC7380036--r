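// Numerical kernels for the convolutional stages and image resampling.
//
// Image batches are R arrays with dim (H, W, C, N); a single image is
// (H, W, C).  Coordinates follow the package convention: (x, y) addresses
// the center of pixel column x, row y, 0-based.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx3(int r, int c, int k, int H, int W) {
  return (arma::uword)r + (arma::uword)H * ((arma::uword)c + (arma::uword)W * (arma::uword)k);
}

// Gather a padded im2col matrix for one image, laid out (H*W) x (kh*kw*Cin):
// for a fixed kernel tap and input channel the entries run contiguously over
// output rows, so whole column segments can be block-copied.
// Zero-filled outside the image ("same" padding, stride 1).
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, arma::mat& out) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  out.zeros();
  for (int ci = 0; ci < Cin; ++ci)
    for (int kc = 0; kc < kw; ++kc)
      for (int kr = 0; kr < kh; ++kr) {
        const int col = kr + kh * (kc + kw * ci);
        double* dst = out.colptr(col);
        const int r0 = std::max(0, ph - kr);            // first valid out row
        const int r1 = std::min(H, H + ph - kr);        // one past last
        if (r0 >= r1) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + kc - pw;
          if (sc < 0 || sc >= W) continue;
          std::memcpy(dst + r0 + (arma::uword)H * c,
                      x + (r0 + kr - ph) + (arma::uword)H * sc
                        + (arma::uword)H * W * ci,
                      (r1 - r0) * sizeof(double));
        }
      }
}

// Scatter-add the (H*W) x (kh*kw*Cin) gradient matrix back onto the image.
static void col2im_add(const arma::mat& g, int H, int W, int Cin,
                       int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci)
    for (int kc = 0; kc < kw; ++kc)
      for (int kr = 0; kr < kh; ++kr) {
        const int col = kr + kh * (kc + kw * ci);
        const double* src = g.colptr(col);
        const int r0 = std::max(0, ph - kr);
        const int r1 = std::min(H, H + ph - kr);
        if (r0 >= r1) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + kc - pw;
          if (sc < 0 || sc >= W) continue;
          double* d = dx + (r0 + kr - ph) + (arma::uword)H * sc
                        + (arma::uword)H * W * ci;
          const double* sp = src + r0 + (arma::uword)H * c;
          for (int r = 0; r < r1 - r0; ++r) d[r] += sp[r];
        }
      }
}

// [[Rcpp::export(name = ".cpp_conv2d_forward")]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int K = kh * kw * Cin, P = H * W;

  // weights as K x Cout
  arma::mat Wm(K, Cout);
  for (int co = 0; co < Cout; ++co)
    std::memcpy(Wm.colptr(co), w.begin() + (arma::uword)K * co, K * sizeof(double));
  arma::rowvec bv(b.begin(), Cout);

  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Xcol(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (arma::uword)P * Cin * n, H, W, Cin, kh, kw, Xcol);
    arma::mat Y = Xcol * Wm;          // P x Cout
    Y.each_row() += bv;
    std::memcpy(y.begin() + (arma::uword)P * Cout * n, Y.memptr(),
                (arma::uword)P * Cout * sizeof(double));
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  const int K = kh * kw * Cin, P = H * W;

  arma::mat Wm(K, Cout);
  for (int co = 0; co < Cout; ++co)
    std::memcpy(Wm.colptr(co), w.begin() + (arma::uword)K * co, K * sizeof(double));

  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dxv((R_xlen_t)H * W * Cin * N);
  dxv.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Xcol(P, K);

  for (int n = 0; n < N; ++n) {
    const arma::mat dY(const_cast<double*>(dy.begin()) + (arma::uword)P * Cout * n,
                       P, Cout, false, true);
    im2col(x.begin() + (arma::uword)P * Cin * n, H, W, Cin, kh, kw, Xcol);
    dW += Xcol.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dXcol = dY * Wm.t();    // P x K
    col2im_add(dXcol, H, W, Cin, kh, kw,
               dxv.begin() + (arma::uword)P * Cin * n);
  }

  NumericVector dwv((R_xlen_t)kh * kw * Cin * Cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    std::memcpy(dwv.begin() + (arma::uword)K * co, dW.colptr(co), K * sizeof(double));
  return List::create(_["dx"] = dxv, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2, stride-2 pooling; odd trailing rows/columns form partial windows
// (ceiling output size).  mode: 0 = max, 1 = average.
// [[Rcpp::export(name = ".cpp_pool2_forward")]]
List cpp_pool2_forward(NumericVector x, int mode) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax(mode == 0 ? y.size() : 0);

  const arma::uword planeIn = (arma::uword)H * W, planeOut = (arma::uword)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < C; ++k) {
      const double* xp = x.begin() + planeIn * (k + (arma::uword)C * n);
      double* yp = y.begin() + planeOut * (k + (arma::uword)C * n);
      int* ap = (mode == 0) ? amax.begin() + planeOut * (k + (arma::uword)C * n) : nullptr;
      for (int c = 0; c < Wo; ++c)
        for (int r = 0; r < Ho; ++r) {
          double best = -1e300, sum = 0; int cnt = 0, besti = -1;
          for (int dc = 0; dc < 2; ++dc) {
            const int sc = 2 * c + dc; if (sc >= W) continue;
            for (int dr = 0; dr < 2; ++dr) {
              const int sr = 2 * r + dr; if (sr >= H) continue;
              const double v = xp[sr + (arma::uword)H * sc];
              sum += v; ++cnt;
              if (v > best) { best = v; besti = sr + H * sc; }
            }
          }
          const arma::uword o = r + (arma::uword)Ho * c;
          yp[o] = (mode == 0) ? best : sum / cnt;
          if (ap) ap[o] = besti;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".cpp_pool2_backward")]]
NumericVector cpp_pool2_backward(NumericVector dy, IntegerVector amax,
                                 IntegerVector in_dim, int mode) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector dxv((R_xlen_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  const arma::uword planeIn = (arma::uword)H * W, planeOut = (arma::uword)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < C; ++k) {
      double* dxp = dxv.begin() + planeIn * (k + (arma::uword)C * n);
      const double* dyp = dy.begin() + planeOut * (k + (arma::uword)C * n);
      const int* ap = (mode == 0) ? amax.begin() + planeOut * (k + (arma::uword)C * n) : nullptr;
      for (int c = 0; c < Wo; ++c)
        for (int r = 0; r < Ho; ++r) {
          const arma::uword o = r + (arma::uword)Ho * c;
          if (mode == 0) {
            dxp[ap[o]] += dyp[o];
          } else {
            int cnt = 0;
            for (int dc = 0; dc < 2; ++dc) { if (2 * c + dc < W) for (int dr = 0; dr < 2; ++dr) if (2 * r + dr < H) ++cnt; }
            const double g = dyp[o] / cnt;
            for (int dc = 0; dc < 2; ++dc) {
              const int sc = 2 * c + dc; if (sc >= W) continue;
              for (int dr = 0; dr < 2; ++dr) {
                const int sr = 2 * r + dr; if (sr >= H) continue;
                dxp[sr + (arma::uword)H * sc] += g;
              }
            }
          }
        }
    }
  return dxv;
}

// Sample an output image whose pixel (xo, yo) reads the input at
// (x, y) = A [xo, yo]' + off.  interp: 0 = nearest, 1 = bilinear.
// [[Rcpp::export(name = ".cpp_affine_sample")]]
NumericVector cpp_affine_sample(NumericVector img, NumericVector A, NumericVector off,
                                int outH, int outW, double pad, int interp) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3];
  NumericVector out(Dimension(outH, outW, C));

  for (int xo = 0; xo < outW; ++xo)
    for (int yo = 0; yo < outH; ++yo) {
      const double xs = a11 * xo + a12 * yo + off[0];
      const double ys = a21 * xo + a22 * yo + off[1];
      if (interp == 0) {
        const int xi = (int)std::lround(xs), yi = (int)std::lround(ys);
        const bool in = xi >= 0 && xi < W && yi >= 0 && yi < H;
        for (int k = 0; k < C; ++k)
          out[idx3(yo, xo, k, outH, outW)] = in ? img[idx3(yi, xi, k, H, W)] : pad;
      } else {
        const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        const double fx = xs - x0, fy = ys - y0;
        for (int k = 0; k < C; ++k) {
          double acc = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dyy = 0; dyy < 2; ++dyy) {
              const int xi = x0 + dx, yi = y0 + dyy;
              const double wgt = (dx ? fx : 1 - fx) * (dyy ? fy : 1 - fy);
              const double v = (xi >= 0 && xi < W && yi >= 0 && yi < H)
                                 ? img[idx3(yi, xi, k, H, W)] : pad;
              acc += wgt * v;
            }
          out[idx3(yo, xo, k, outH, outW)] = acc;
        }
      }
    }
  return out;
}
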