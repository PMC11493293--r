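// Hot numeric kernels: im2col 2D convolution forward/backward, max pooling,
// and the Gauss-Seidel global-smoothness optical-flow solver. Tensors cross
// the R/C++ boundary as R arrays in (H, W, C, N) layout; weights as
// (kh, kw, Cin, Cout). All loops are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (rows: kh*kw*Cin ordered kh-fastest; cols: Ho*Wo
// ordered Ho-fastest) for one sample starting at pointer x (H x W x C).
static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   int stride, int pad, arma::mat& cols) {
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wx = wo * stride - pad + j;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hx = ho * stride - pad + i;
            double v = 0.0;
            if (hx >= 0 && hx < H && wx >= 0 && wx < W)
              v = x[hx + H * (wx + W * c)];
            cols(row, ho + Ho * wo) = v;
          }
        }
      }
    }
  }
}

// Scatter-add of an im2col-layout gradient back to image layout.
static void col2im(const arma::mat& cols, int H, int W, int C, int kh, int kw,
                   int stride, int pad, double* dx) {
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wx = wo * stride - pad + j;
          if (wx < 0 || wx >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hx = ho * stride - pad + i;
            if (hx < 0 || hx >= H) continue;
            dx[hx + H * (wx + W * c)] += cols(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat cols(kh * kw * Cin, Ho * Wo);
  arma::colvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, cols);
    arma::mat out = Wm.t() * cols;          // Cout x (Ho*Wo)
    out.each_col() += bv;
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + Ho * Wo * c] = out(c, p);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat cols(kh * kw * Cin, Ho * Wo);
  arma::mat dym(Cout, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < Ho * Wo; ++p)
        dym(c, p) = dyp[p + Ho * Wo * c];
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, cols);
    dWm += cols * dym.t();
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dym.row(c));
    arma::mat dcols = Wm * dym;             // (kh*kw*Cin) x (Ho*Wo)
    col2im(dcols, H, W, C, kh, kw, stride, pad,
           dx.begin() + static_cast<R_xlen_t>(n) * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("pool window larger than padded input");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());   // 0-based linear index into x of each max
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    const R_xlen_t base = static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int j = 0; j < kw; ++j) {
            const int wx = wo * stride - pad + j;
            if (wx < 0 || wx >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hx = ho * stride - pad + i;
              if (hx < 0 || hx >= H) continue;
              const R_xlen_t xi = hx + H * (wx + static_cast<R_xlen_t>(W) * c);
              if (xp[xi] > best) { best = xp[xi]; besti = base + xi; }
            }
          }
          // column-major target position ho + Ho*(wo + Wo*c) within sample
          const R_xlen_t yi = static_cast<R_xlen_t>(n) * Ho * Wo * C +
                              ho + Ho * (wo + static_cast<R_xlen_t>(Wo) * c);
          y[yi] = best;
          idx[yi] = static_cast<int>(besti);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector dy,
                         IntegerVector xdim) {
  R_xlen_t nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= xdim[i];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Global-smoothness optical-flow solver. Minimizes
//   E(u, v) = sum (Ix u + Iy v + It)^2
//           + alpha^2 * sum over 4-neighbor pairs ((du)^2 + (dv)^2)
// by Gauss-Seidel sweeps that solve each pixel's 2x2 system exactly given its
// neighbors, so E is non-increasing by construction. Returns the flow and the
// energy after each sweep.
// [[Rcpp::export]]
List hs_flow(NumericMatrix Ix, NumericMatrix Iy, NumericMatrix It,
             double alpha, int n_iterations) {
  const int H = Ix.nrow(), W = Ix.ncol();
  const double a2 = alpha * alpha;
  arma::mat u(H, W, arma::fill::zeros), v(H, W, arma::fill::zeros);
  arma::mat ix(Ix.begin(), H, W, true), iy(Iy.begin(), H, W, true),
            it(It.begin(), H, W, true);
  NumericVector energy(n_iterations);

  auto total_energy = [&]() {
    double e = 0.0;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const double r = ix(y, x) * u(y, x) + iy(y, x) * v(y, x) + it(y, x);
        e += r * r;
        if (y + 1 < H) {
          const double du = u(y + 1, x) - u(y, x), dv = v(y + 1, x) - v(y, x);
          e += a2 * (du * du + dv * dv);
        }
        if (x + 1 < W) {
          const double du = u(y, x + 1) - u(y, x), dv = v(y, x + 1) - v(y, x);
          e += a2 * (du * du + dv * dv);
        }
      }
    return e;
  };

  for (int iter = 0; iter < n_iterations; ++iter) {
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        double su = 0.0, sv = 0.0;
        int nn = 0;
        if (y > 0)     { su += u(y - 1, x); sv += v(y - 1, x); ++nn; }
        if (y + 1 < H) { su += u(y + 1, x); sv += v(y + 1, x); ++nn; }
        if (x > 0)     { su += u(y, x - 1); sv += v(y, x - 1); ++nn; }
        if (x + 1 < W) { su += u(y, x + 1); sv += v(y, x + 1); ++nn; }
        const double gx = ix(y, x), gy = iy(y, x), gt = it(y, x);
        // 2x2 normal equations of the per-pixel energy slice
        const double a11 = gx * gx + a2 * nn;
        const double a22 = gy * gy + a2 * nn;
        const double a12 = gx * gy;
        const double b1 = -gx * gt + a2 * su;
        const double b2 = -gy * gt + a2 * sv;
        const double det = a11 * a22 - a12 * a12;
        if (det > 0) {
          u(y, x) = (b1 * a22 - a12 * b2) / det;
          v(y, x) = (a11 * b2 - a12 * b1) / det;
        }
      }
    }
    energy[iter] = total_energy();
  }
  return List::create(_["u"] = wrap(u), _["v"] = wrap(v),
                      _["energy"] = energy);
}
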