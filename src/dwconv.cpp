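// Depthwise 3x3 convolution (same padding) on (B, H, W, C) arrays.
// The hot loop of every FeatureBlock/BioBlock; everything else in the
// network is BLAS-bound matrix algebra and stays in R.
#include <Rcpp.h>
using namespace Rcpp;

// flat index for column-major (B, H, W, C)
static inline R_xlen_t idx4(R_xlen_t b, R_xlen_t h, R_xlen_t w, R_xlen_t c,
                            R_xlen_t B, R_xlen_t H, R_xlen_t W) {
  return b + B * (h + H * (w + W * c));
}

// [[Rcpp::export]]
NumericVector dwconv3_fwd_cpp(NumericVector x, IntegerVector dims,
                              NumericVector kern, NumericVector bias) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  const double* pk = kern.begin();  // (3, 3, C) column-major
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* k = pk + 9 * c;
    const double bc = bias[c];
    for (R_xlen_t w = 0; w < W; ++w) {
      for (R_xlen_t h = 0; h < H; ++h) {
        for (R_xlen_t b = 0; b < B; ++b) {
          double acc = bc;
          for (int dj = -1; dj <= 1; ++dj) {
            const R_xlen_t ww = w + dj;
            if (ww < 0 || ww >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const R_xlen_t hh = h + di;
              if (hh < 0 || hh >= H) continue;
              acc += px[idx4(b, hh, ww, c, B, H, W)] * k[(di + 1) + 3 * (dj + 1)];
            }
          }
          py[idx4(b, h, w, c, B, H, W)] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv3_bwd_cpp(NumericVector x, IntegerVector dims,
                     NumericVector kern, NumericVector dy) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector dx(x.size());
  NumericVector dw(9 * C);
  NumericVector db(C);
  const double* px = x.begin();
  const double* pdy = dy.begin();
  const double* pk = kern.begin();
  double* pdx = dx.begin();
  double* pdw = dw.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* k = pk + 9 * c;
    double* dwc = pdw + 9 * c;
    double dbc = 0.0;
    for (R_xlen_t w = 0; w < W; ++w) {
      for (R_xlen_t h = 0; h < H; ++h) {
        for (R_xlen_t b = 0; b < B; ++b) {
          const double g = pdy[idx4(b, h, w, c, B, H, W)];
          dbc += g;
          for (int dj = -1; dj <= 1; ++dj) {
            const R_xlen_t ww = w + dj;
            if (ww < 0 || ww >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const R_xlen_t hh = h + di;
              if (hh < 0 || hh >= H) continue;
              const R_xlen_t src = idx4(b, hh, ww, c, B, H, W);
              const int kk = (di + 1) + 3 * (dj + 1);
              pdx[src] += g * k[kk];   // scatter: dx gets dy * w at offset
              dwc[kk] += g * px[src];
            }
          }
        }
      }
    }
    db[c] = dbc;
  }
  dw.attr("dim") = IntegerVector::create(3, 3, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
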