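#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Flat rectangular grayscale morphology and median filters.
// All operators use clipped windows at the borders, which for flat
// min/max/median filters is identical to edge replication.

// [[Rcpp::export]]
NumericMatrix erode_rect_cpp(const NumericMatrix& x, int kr, int kc) {
  const int nr = x.nrow(), nc = x.ncol();
  const int rr = kr / 2, rc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - rc), j1 = std::min(nc - 1, j + rc);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - rr), i1 = std::min(nr - 1, i + rr);
      double v = R_PosInf;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (x(ii, jj) < v) v = x(ii, jj);
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dilate_rect_cpp(const NumericMatrix& x, int kr, int kc) {
  const int nr = x.nrow(), nc = x.ncol();
  const int rr = kr / 2, rc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - rc), j1 = std::min(nc - 1, j + rc);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - rr), i1 = std::min(nr - 1, i + rr);
      double v = R_NegInf;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (x(ii, jj) > v) v = x(ii, jj);
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix median2d_cpp(const NumericMatrix& x, int kr, int kc) {
  const int nr = x.nrow(), nc = x.ncol();
  const int rr = kr / 2, rc = kc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)kr * kc);
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - rc), j1 = std::min(nc - 1, j + rc);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - rr), i1 = std::min(nr - 1, i + rr);
      buf.clear();
      // replicate border: clipped cells re-enter with the edge value so the
      // window always holds kr*kc samples, matching an edge-padded filter
      for (int jj = j - rc; jj <= j + rc; ++jj) {
        const int jc = std::min(std::max(jj, j0), j1);
        for (int ii = i - rr; ii <= i + rr; ++ii) {
          const int ic = std::min(std::max(ii, i0), i1);
          buf.push_back(x(ic, jc));
        }
      }
      const size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// 3-D median over an M x N x I array (column-major, dims attribute on vec).
// [[Rcpp::export]]
NumericVector median3d_cpp(const NumericVector& vec, int M, int N, int I,
                           int km, int kn, int ki) {
  const int rm = km / 2, rn = kn / 2, ri = ki / 2;
  NumericVector out(vec.size());
  const double* x = vec.begin();
  double* o = out.begin();
  const size_t frame = (size_t)M * N;
  std::vector<double> buf;
  buf.reserve((size_t)km * kn * ki);
  for (int k = 0; k < I; ++k) {
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < M; ++i) {
        buf.clear();
        for (int kk = k - ri; kk <= k + ri; ++kk) {
          const int kc = std::min(std::max(kk, 0), I - 1);
          for (int jj = j - rn; jj <= j + rn; ++jj) {
            const int jc = std::min(std::max(jj, 0), N - 1);
            const double* base = x + frame * kc + (size_t)M * jc;
            for (int ii = i - rm; ii <= i + rm; ++ii) {
              const int ic = std::min(std::max(ii, 0), M - 1);
              buf.push_back(base[ic]);
            }
          }
        }
        const size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        o[frame * k + (size_t)M * j + i] = buf[mid];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(M, N, I);
  return out;
}
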