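// Hot kernels for the CNN engine: 3x3 same-padding patch extraction
// (im2col) and its adjoint, plus 2x2 max-pooling. Everything else (GEMMs,
// activations, optimizer) lives in R; these loops are the only places where
// elementwise R indexing was the bottleneck.
//
// Feature-map layout is (h, w, batch, channels), column-major. With that
// ordering the GEMM result (rows = output pixel fastest, then image) can be
// reshaped straight into the next layer's input without any transpose.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// X: array (h, w, n, cin). Returns P: (h*w*n) x (9*cin) with
// row = oi + h*oj + h*w*img and column = q + 9*c, q = di + 3*dj,
// di/dj in {0,1,2}. Taps outside the image are zero (same padding).
// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector X, int h, int w, int n, int cin) {
  const R_xlen_t p = (R_xlen_t)h * w;
  const R_xlen_t pn = p * n;
  NumericMatrix P(pn, 9 * cin);
  const double* x = X.begin();
  double* out = P.begin();
  for (int c = 0; c < cin; ++c) {
    const double* xc0 = x + (R_xlen_t)c * pn;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int q = di + 3 * dj;
        double* colbase = out + (R_xlen_t)(q + 9 * c) * pn;
        const int lo = (di == 0) ? 1 : 0;       // first valid output row
        const int hi = (di == 2) ? h - 1 : h;   // one past last valid
        for (int img = 0; img < n; ++img) {
          const double* xc = xc0 + (R_xlen_t)img * p;
          double* dst = colbase + (R_xlen_t)img * p;
          for (int oj = 0; oj < w; ++oj) {
            const int jj = oj + dj - 1;
            double* d = dst + (R_xlen_t)oj * h;
            if (jj < 0 || jj >= w) {
              std::memset(d, 0, sizeof(double) * h);
            } else {
              const double* s = xc + (R_xlen_t)jj * h + (di - 1);
              if (lo > 0) d[0] = 0.0;
              std::memcpy(d + lo, s + lo, sizeof(double) * (hi - lo));
              if (hi < h) d[h - 1] = 0.0;
            }
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the input.
// dP: (h*w*n) x (9*cin); returns array (h, w, n, cin).
// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix dP, int h, int w, int n, int cin) {
  const R_xlen_t p = (R_xlen_t)h * w;
  const R_xlen_t pn = p * n;
  NumericVector dX(pn * cin);
  const double* src = dP.begin();
  double* x = dX.begin();
  for (int c = 0; c < cin; ++c) {
    double* xc0 = x + (R_xlen_t)c * pn;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int q = di + 3 * dj;
        const double* colbase = src + (R_xlen_t)(q + 9 * c) * pn;
        const int lo = (di == 0) ? 1 : 0;
        const int hi = (di == 2) ? h - 1 : h;
        for (int img = 0; img < n; ++img) {
          double* xc = xc0 + (R_xlen_t)img * p;
          const double* s = colbase + (R_xlen_t)img * p;
          for (int oj = 0; oj < w; ++oj) {
            const int jj = oj + dj - 1;
            if (jj < 0 || jj >= w) continue;
            double* d = xc + (R_xlen_t)jj * h + (di - 1);
            const double* sc = s + (R_xlen_t)oj * h;
            for (int oi = lo; oi < hi; ++oi) d[oi] += sc[oi];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(h, w, n, cin);
  return dX;
}

// 2x2 max pool, stride 2, over `planes` independent (h, w) planes (the
// trailing batch x channel dimensions). Returns the pooled values plus the
// within-cell argmax (0 = (0,0), 1 = (1,0), 2 = (0,1), 3 = (1,1); ties go
// to the first maximal tap) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector X, int h, int w, R_xlen_t planes) {
  const int ho = h / 2, wo = w / 2;
  const R_xlen_t po = (R_xlen_t)ho * wo;
  NumericVector M(po * planes);
  IntegerVector A(po * planes);
  const double* x = X.begin();
  double* m = M.begin();
  int* a = A.begin();
  for (R_xlen_t pl = 0; pl < planes; ++pl) {
    const double* xp = x + pl * h * w;
    double* mp = m + pl * po;
    int* ap = a + pl * po;
    for (int oj = 0; oj < wo; ++oj) {
      const double* c0 = xp + (R_xlen_t)(2 * oj) * h;
      const double* c1 = c0 + h;
      double* mcol = mp + (R_xlen_t)oj * ho;
      int* acol = ap + (R_xlen_t)oj * ho;
      for (int oi = 0; oi < ho; ++oi) {
        const int i0 = 2 * oi;
        double best = c0[i0];
        int arg = 0;
        if (c0[i0 + 1] > best) { best = c0[i0 + 1]; arg = 1; }
        if (c1[i0] > best) { best = c1[i0]; arg = 2; }
        if (c1[i0 + 1] > best) { best = c1[i0 + 1]; arg = 3; }
        mcol[oi] = best;
        acol[oi] = arg;
      }
    }
  }
  return List::create(_["out"] = M, _["argmax"] = A);
}

// Route pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dM, IntegerVector A,
                           int h, int w, R_xlen_t planes) {
  const int ho = h / 2, wo = w / 2;
  const R_xlen_t po = (R_xlen_t)ho * wo;
  NumericVector dX((R_xlen_t)h * w * planes);
  const double* dm = dM.begin();
  const int* a = A.begin();
  double* dx = dX.begin();
  for (R_xlen_t pl = 0; pl < planes; ++pl) {
    const double* dmp = dm + pl * po;
    const int* ap = a + pl * po;
    double* dxp = dx + pl * h * w;
    for (int oj = 0; oj < wo; ++oj) {
      const double* mcol = dmp + (R_xlen_t)oj * ho;
      const int* acol = ap + (R_xlen_t)oj * ho;
      double* c0 = dxp + (R_xlen_t)(2 * oj) * h;
      double* c1 = c0 + h;
      for (int oi = 0; oi < ho; ++oi) {
        const int arg = acol[oi];
        double* col = (arg & 2) ? c1 : c0;
        col[2 * oi + (arg & 1)] += mcol[oi];
      }
    }
  }
  return dX;
}
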