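#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Edge-preserving 2D bilateral filter of one slice. sigma_s is the spatial
// Gaussian sigma in pixels (window radius 2*sigma_s), sigma_r the range
// sigma in gray levels. Replicate boundary handling.
// [[Rcpp::export(name = ".cpp_bilateral2d")]]
NumericMatrix cpp_bilateral2d(NumericMatrix img, double sigma_s,
                              double sigma_r) {
  const int ny = img.nrow(), nx = img.ncol();
  const int r = std::max(1, (int)std::ceil(2.0 * sigma_s));
  std::vector<double> sw((2 * r + 1) * (2 * r + 1));
  for (int dx = -r; dx <= r; ++dx)
    for (int dy = -r; dy <= r; ++dy)
      sw[(dx + r) * (2 * r + 1) + (dy + r)] =
          std::exp(-(dx * dx + dy * dy) / (2.0 * sigma_s * sigma_s));
  const double inv2sr2 = 1.0 / (2.0 * sigma_r * sigma_r);
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double c = img(y, x), acc = 0.0, wsum = 0.0;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = x + dx;
        if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
        for (int dy = -r; dy <= r; ++dy) {
          int yy = y + dy;
          if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
          double v = img(yy, xx);
          double dv = v - c;
          double w = sw[(dx + r) * (2 * r + 1) + (dy + r)] *
                     std::exp(-dv * dv * inv2sr2);
          acc += w * v;
          wsum += w;
        }
      }
      out(y, x) = acc / wsum;
    }
  return out;
}
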