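#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

// 3 x 3 median filter over the first two dimensions of a [H, W, S] stack,
// reflecting edges (index -1 -> 1, H -> H-2 in 0-based terms). The hot path
// of the blank-tile rule; the R selection-network implementation serves as
// its oracle in the test suite.
// [[Rcpp::export(name = ".median3StackCpp")]]
NumericVector median3_stack(NumericVector x, int H, int W, int S) {
  NumericVector out(x.size());
  double win[9];
  for (int s = 0; s < S; ++s) {
    const double *p = &x[(R_xlen_t)s * H * W];
    double *q = &out[(R_xlen_t)s * H * W];
    for (int j = 0; j < W; ++j) {
      int jm = j == 0 ? 1 : j - 1;
      int jp = j == W - 1 ? W - 2 : j + 1;
      const double *c0 = p + (R_xlen_t)jm * H;
      const double *c1 = p + (R_xlen_t)j * H;
      const double *c2 = p + (R_xlen_t)jp * H;
      for (int i = 0; i < H; ++i) {
        int im = i == 0 ? 1 : i - 1;
        int ip = i == H - 1 ? H - 2 : i + 1;
        win[0] = c0[im]; win[1] = c0[i]; win[2] = c0[ip];
        win[3] = c1[im]; win[4] = c1[i]; win[5] = c1[ip];
        win[6] = c2[im]; win[7] = c2[i]; win[8] = c2[ip];
        std::nth_element(win, win + 4, win + 9);
        q[(R_xlen_t)j * H + i] = win[4];
      }
    }
  }
  return out;
}
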