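// Low-level layer kernels for the segmentation network.
//
// Array layout convention (matching R's column-major array order):
//   feature maps  x : dim (H, W, C, N)
//   conv weights  w : dim (k, k, Cin, Cout)
// so a (H, W, C) sample slice is contiguous and maps directly onto
// Armadillo matrices without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dim4(const NumericVector& x, int& d1, int& d2, int& d3,
                            int& d4) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

// im2col for one (H, W, Cin) sample: returns (k*k*Cin, H*W) matrix,
// column p = h + H*w, row r = kh + k*(kw + k*ci), zero padding.
static void im2col(const double* x, int H, int W, int Cin, int k, int pad,
                   arma::mat& M) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * ci);
        double* Mr = M.memptr() + r;  // stride M.n_rows between columns
        const size_t nr = M.n_rows;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - pad;
          if (iw < 0 || iw >= W) {
            for (int h = 0; h < H; ++h) Mr[(size_t)(h + H * w) * nr] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)iw * H;
          for (int h = 0; h < H; ++h) {
            const int ih = h + kh - pad;
            Mr[(size_t)(h + H * w) * nr] =
                (ih < 0 || ih >= H) ? 0.0 : xcol[ih];
          }
        }
      }
    }
  }
}

// scatter-add counterpart of im2col
static void col2im_add(const arma::mat& M, int H, int W, int Cin, int k,
                       int pad, double* gx) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* gc = gx + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * ci);
        const double* Mr = M.memptr() + r;
        const size_t nr = M.n_rows;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          double* gcol = gc + (size_t)iw * H;
          for (int h = 0; h < H; ++h) {
            const int ih = h + kh - pad;
            if (ih >= 0 && ih < H) gcol[ih] += Mr[(size_t)(h + H * w) * nr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector b) {
  int H, W, Cin, N;
  get_dim4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight/input channel mismatch");
  const int pad = (k - 1) / 2;

  NumericVector out = alloc4(H, W, Cout, N);
  arma::mat Wmat(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec bias(b.begin(), Cout);
  arma::mat M((size_t)k * k * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, pad, M);
    arma::mat O(out.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                false, true);
    O = M.t() * Wmat;
    O.each_row() += bias;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gout) {
  int H, W, Cin, N;
  get_dim4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;

  NumericVector gx = alloc4(H, W, Cin, N);
  NumericVector gw = alloc4(k, k, Cin, Cout);
  NumericVector gb(Cout);

  arma::mat Wmat(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat gW(gw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec gB(gb.begin(), Cout, false, true);
  arma::mat M((size_t)k * k * Cin, (size_t)H * W);
  arma::mat dM((size_t)k * k * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * Cin;
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)n * H * W * Cout,
                (size_t)H * W, Cout, false, true);
    im2col(xn, H, W, Cin, k, pad, M);
    gW += M * G;
    gB += arma::sum(G, 0);
    dM = Wmat * G.t();
    col2im_add(dM, H, W, Cin, k, pad, gx.begin() + (size_t)n * H * W * Cin);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int f) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  if (H % f != 0 || W % f != 0) stop("spatial dims not divisible by pool factor");
  const int Ho = H / f, Wo = W / f;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);  // 0-based index into x

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          size_t bi = 0;
          for (int dw = 0; dw < f; ++dw) {
            const size_t coloff = (size_t)(wo * f + dw) * H;
            for (int dh = 0; dh < f; ++dh) {
              const size_t i = coloff + ho * f + dh;
              if (xp[i] > best) { best = xp[i]; bi = i; }
            }
          }
          // out is (Ho, Wo, C, N): column-major over (ho, wo) then c, n —
          // but loop order here is wo outer, ho inner per (c, n); compute
          // the linear offset explicitly to stay layout-correct.
          const size_t oo = ((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho;
          out[oo] = best;
          idx[oo] = (int)(base + bi);

        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gout, IntegerVector idx,
                             IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const R_xlen_t m = gout.size();
  for (R_xlen_t i = 0; i < m; ++i) gx[idx[i]] += gout[i];
  return gx;
}

// Per-axis interpolation tables for bilinear resize by an integer factor
// (half-pixel-center convention, edges clamped).
static void interp_axis(int n_in, int f, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& w1) {
  const int n_out = n_in * f;
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int j = 0; j < n_out; ++j) {
    double s = (j + 0.5) / f - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int a = (int)std::floor(s);
    int b = std::min(a + 1, n_in - 1);
    i0[j] = a; i1[j] = b; w1[j] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, int f) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  const int Ho = H * f, Wo = W * f;
  NumericVector out = alloc4(Ho, Wo, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hw, ww;
  interp_axis(H, f, h0, h1, hw);
  interp_axis(W, f, w0, w1, ww);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* op = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* xa = xp + (size_t)w0[wo] * H;
        const double* xb = xp + (size_t)w1[wo] * H;
        const double bw = ww[wo];
        double* oc = op + (size_t)wo * Ho;
        for (int ho = 0; ho < Ho; ++ho) {
          const double ah = hw[ho];
          const double va = xa[h0[ho]] * (1 - ah) + xa[h1[ho]] * ah;
          const double vb = xb[h0[ho]] * (1 - ah) + xb[h1[ho]] * ah;
          oc[ho] = va * (1 - bw) + vb * bw;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector gout, int f, int H, int W) {
  int Ho, Wo, C, N;
  get_dim4(gout, Ho, Wo, C, N);
  if (Ho != H * f || Wo != W * f) stop("gradient shape mismatch in upsample");
  NumericVector gx = alloc4(H, W, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hw, ww;
  interp_axis(H, f, h0, h1, hw);
  interp_axis(W, f, w0, w1, ww);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gp = gout.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xp = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        double* xa = xp + (size_t)w0[wo] * H;
        double* xb = xp + (size_t)w1[wo] * H;
        const double bw = ww[wo];
        const double* oc = gp + (size_t)wo * Ho;
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = oc[ho];
          const double ah = hw[ho];
          xa[h0[ho]] += g * (1 - ah) * (1 - bw);
          xa[h1[ho]] += g * ah * (1 - bw);
          xb[h0[ho]] += g * (1 - ah) * bw;
          xb[h1[ho]] += g * ah * bw;
        }
      }
    }
  }
  return gx;
}
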