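#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Canny edge detector on a single grayscale frame in [0,1].
// Gaussian smoothing (separable, replicate borders), Sobel gradients,
// non-maximum suppression along the quantized gradient direction, and
// two-level hysteresis linking (8-connected flood fill from strong pixels).
// Thresholds apply to the gradient magnitude normalized to a unit maximum,
// so a fixed high threshold is scale-free across exposures.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
LogicalMatrix canny_cpp(const NumericMatrix& img, double sigma,
                        double low, double high) {
  const int nr = img.nrow(), nc = img.ncol();

  // separable Gaussian blur
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += ker[t + rad];
  }
  for (double& v : ker) v /= ksum;

  NumericMatrix tmp(nr, nc), sm(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t)
        acc += ker[t + rad] * img(clampi(i + t, 0, nr - 1), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t)
        acc += ker[t + rad] * tmp(i, clampi(j + t, 0, nc - 1));
      sm(i, j) = acc;
    }

  // Sobel gradients: gy along rows (m, downward), gx along columns (n)
  NumericMatrix mag(nr, nc), dir(nr, nc);
  double magmax = 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      const int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
      const double gx = (sm(im, jp) + 2.0 * sm(i, jp) + sm(ip, jp))
                      - (sm(im, jm) + 2.0 * sm(i, jm) + sm(ip, jm));
      const double gy = (sm(ip, jm) + 2.0 * sm(ip, j) + sm(ip, jp))
                      - (sm(im, jm) + 2.0 * sm(im, j) + sm(im, jp));
      const double m = std::sqrt(gx * gx + gy * gy);
      mag(i, j) = m;
      if (m > magmax) magmax = m;
      double a = std::atan2(gy, gx) * 180.0 / M_PI;
      if (a < 0) a += 180.0;
      dir(i, j) = a;
    }
  }
  if (magmax > 0)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) mag(i, j) /= magmax;

  // non-maximum suppression
  NumericMatrix nms(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double a = dir(i, j), m = mag(i, j);
      int di1, dj1, di2, dj2;
      if (a < 22.5 || a >= 157.5)      { di1 = 0;  dj1 = 1;  di2 = 0;  dj2 = -1; }
      else if (a < 67.5)               { di1 = 1;  dj1 = 1;  di2 = -1; dj2 = -1; }
      else if (a < 112.5)              { di1 = 1;  dj1 = 0;  di2 = -1; dj2 = 0; }
      else                             { di1 = -1; dj1 = 1;  di2 = 1;  dj2 = -1; }
      const double m1 = mag(clampi(i + di1, 0, nr - 1), clampi(j + dj1, 0, nc - 1));
      const double m2 = mag(clampi(i + di2, 0, nr - 1), clampi(j + dj2, 0, nc - 1));
      nms(i, j) = (m >= m1 && m >= m2) ? m : 0.0;
    }
  }

  // hysteresis: seed at strong pixels, grow through weak ones (8-connected)
  LogicalMatrix out(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (nms(i, j) >= high && !out(i, j)) {
        out(i, j) = true;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              const int qi = pi + di, qj = pj + dj;
              if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
              if (!out(qi, qj) && nms(qi, qj) >= low) {
                out(qi, qj) = true;
                stack.push_back(qi + qj * nr);
              }
            }
        }
      }
  return out;
}
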