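#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable 2-D correlation with replicate (clamped) borders.
// ky runs along rows (y), kx along columns (x); both must have odd length.
// [[Rcpp::export]]
NumericMatrix sep_conv2(NumericMatrix x, NumericVector ky, NumericVector kx) {
  int h = x.nrow(), w = x.ncol();
  int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // columns pass (kx)
  for (int j = 0; j < w; ++j) {
    for (int b = -rx; b <= rx; ++b) {
      double kv = kx[b + rx];
      if (kv == 0.0) continue;
      int jj = clampi(j + b, 0, w - 1);
      for (int i = 0; i < h; ++i) tmp(i, j) += kv * x(i, jj);
    }
  }
  // rows pass (ky)
  for (int j = 0; j < w; ++j) {
    for (int a = -ry; a <= ry; ++a) {
      double kv = ky[a + ry];
      if (kv == 0.0) continue;
      for (int i = 0; i < h; ++i) {
        int ii = clampi(i + a, 0, h - 1);
        out(i, j) += kv * tmp(ii, j);
      }
    }
  }
  return out;
}
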