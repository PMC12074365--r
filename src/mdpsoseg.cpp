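#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Nearest-centroid assignment under the transformed, weighted distance
//   delta_c(p) = sum_m w[m] * ( exp( (|p_m - c_m| * alpha[m])^2 ) - 1 ).
// E: A x P element matrix, C: n_c x P centroid matrix, sizes: per-element
// multiplicity (1 for voxels, superpixel size in aggregated mode).
// Ties go to the lowest centroid index. Returns 1-based labels, per-cluster
// counts A_i (sum of sizes) and cumulative transformed errors e_i.
// [[Rcpp::export]]
List cpp_assign_elements(const NumericMatrix& E, const NumericMatrix& C,
                         const NumericVector& alpha, const NumericVector& w,
                         const NumericVector& sizes) {
  const int A = E.nrow(), P = E.ncol(), nc = C.nrow();
  IntegerVector labels(A);
  NumericVector Ai(nc), ei(nc), delta(A);
  for (int a = 0; a < A; ++a) {
    double best = R_PosInf;
    int besti = 0;
    for (int c = 0; c < nc; ++c) {
      double d = 0.0;
      for (int m = 0; m < P; ++m) {
        double u = std::fabs(E(a, m) - C(c, m)) * alpha[m];
        d += w[m] * std::expm1(u * u);
        if (d >= best) break;  // partial sums are non-decreasing
      }
      if (d < best) { best = d; besti = c; }
    }
    labels[a] = besti + 1;
    delta[a] = best;
    Ai[besti] += sizes[a];
    ei[besti] += sizes[a] * best;
  }
  return List::create(_["labels"] = labels, _["A_i"] = Ai, _["e_i"] = ei,
                      _["delta"] = delta);
}

// Direct 2D convolution with replicate (nearest-edge) padding.
// [[Rcpp::export]]
NumericMatrix cpp_convolve2d(const NumericMatrix& img, const NumericMatrix& ker) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = ker.nrow(), kc = ker.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int kj = 0; kj < kc; ++kj) {
        int jj = std::min(std::max(j + kj - hc, 0), nc - 1);
        for (int ki = 0; ki < kr; ++ki) {
          int ii = std::min(std::max(i + ki - hr, 0), nr - 1);
          s += img(ii, jj) * ker(ki, kj);
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Direct 3D convolution with replicate padding; img and ker are flat arrays
// with dims attached.
// [[Rcpp::export]]
NumericVector cpp_convolve3d(const NumericVector& img, const IntegerVector& idim,
                             const NumericVector& ker, const IntegerVector& kdim) {
  const int n1 = idim[0], n2 = idim[1], n3 = idim[2];
  const int k1 = kdim[0], k2 = kdim[1], k3 = kdim[2];
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  NumericVector out(n1 * n2 * n3);
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        double s = 0.0;
        for (int kz = 0; kz < k3; ++kz) {
          int zz = std::min(std::max(z + kz - h3, 0), n3 - 1);
          for (int ky = 0; ky < k2; ++ky) {
            int yy = std::min(std::max(y + ky - h2, 0), n2 - 1);
            for (int kx = 0; kx < k1; ++kx) {
              int xx = std::min(std::max(x + kx - h1, 0), n1 - 1);
              s += img[xx + n1 * (yy + n2 * (size_t)zz)] *
                   ker[kx + k1 * (ky + k2 * (size_t)kz)];
            }
          }
        }
        out[x + n1 * (y + n2 * (size_t)z)] = s;
      }
  out.attr("dim") = idim;
  return out;
}

// Square-window median filter, 2D, replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_median2d(const NumericMatrix& img, const int win) {
  const int nr = img.nrow(), nc = img.ncol(), h = win / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)win * win);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int kj = -h; kj <= h; ++kj) {
        int jj = std::min(std::max(j + kj, 0), nc - 1);
        for (int ki = -h; ki <= h; ++ki) {
          int ii = std::min(std::max(i + ki, 0), nr - 1);
          buf.push_back(img(ii, jj));
        }
      }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        m = 0.5 * (m + buf[mid - 1]);
      }
      out(i, j) = m;
    }
  return out;
}

// Cube-window median filter, 3D, replicate padding.
// [[Rcpp::export]]
NumericVector cpp_median3d(const NumericVector& img, const IntegerVector& idim,
                           const int win) {
  const int n1 = idim[0], n2 = idim[1], n3 = idim[2], h = win / 2;
  NumericVector out(n1 * n2 * n3);
  std::vector<double> buf;
  buf.reserve((size_t)win * win * win);
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        buf.clear();
        for (int kz = -h; kz <= h; ++kz) {
          int zz = std::min(std::max(z + kz, 0), n3 - 1);
          for (int ky = -h; ky <= h; ++ky) {
            int yy = std::min(std::max(y + ky, 0), n2 - 1);
            for (int kx = -h; kx <= h; ++kx) {
              int xx = std::min(std::max(x + kx, 0), n1 - 1);
              buf.push_back(img[xx + n1 * (yy + n2 * (size_t)zz)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[x + n1 * (y + n2 * (size_t)z)] = buf[mid];
      }
  out.attr("dim") = idim;
  return out;
}
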