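#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 2D median filter applied independently to every frame of an nx x ny x nf
// stack. Square window of odd side `kernel`, replicate-edge padding. Exact:
// no intensity quantization, so binary masks stay binary and constants are
// fixed points.
// [[Rcpp::export(name = ".medianFilter3d")]]
NumericVector median_filter3d(NumericVector x, int nx, int ny, int nf,
                              int kernel) {
  if (kernel < 1 || kernel % 2 == 0)
    stop("kernel must be an odd positive integer");
  if ((R_xlen_t)nx * ny * nf != x.size())
    stop("dimensions do not match data length");
  if (kernel == 1)
    return clone(x);

  int h = kernel / 2;
  NumericVector out(x.size());
  std::vector<double> win;
  win.reserve((size_t)kernel * kernel);

  for (int f = 0; f < nf; ++f) {
    R_xlen_t off = (R_xlen_t)f * nx * ny;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        win.clear();
        for (int dj = -h; dj <= h; ++dj) {
          int jj = j + dj;
          if (jj < 0) jj = 0;
          if (jj >= ny) jj = ny - 1;
          for (int di = -h; di <= h; ++di) {
            int ii = i + di;
            if (ii < 0) ii = 0;
            if (ii >= nx) ii = nx - 1;
            win.push_back(x[off + (R_xlen_t)jj * nx + ii]);
          }
        }
        size_t mid = win.size() / 2;
        std::nth_element(win.begin(), win.begin() + mid, win.end());
        out[off + (R_xlen_t)j * nx + i] = win[mid];
      }
    }
  }
  return out;
}
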