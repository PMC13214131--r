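#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Feature maps are N x C matrices, N = d1*d2*d3 voxels in column-major
// voxel order: row = i + d1*j + d1*d2*k (0-based).

// [[Rcpp::export]]
NumericMatrix im2col3d(const NumericMatrix& x, const IntegerVector& dims,
                       const IntegerVector& ksize, const IntegerVector& stride,
                       const IntegerVector& pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int C = x.ncol();
  const int o1 = (d1 + 2 * p1 - k1) / s1 + 1;
  const int o2 = (d2 + 2 * p2 - k2) / s2 + 1;
  const int o3 = (d3 + 2 * p3 - k3) / s3 + 1;
  const int Nout = o1 * o2 * o3;
  const int K = k1 * k2 * k3;
  NumericMatrix out(Nout, K * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * d1 * d2 * d3;
    for (int kc = 0; kc < k3; ++kc) {
      for (int kb = 0; kb < k2; ++kb) {
        for (int ka = 0; ka < k1; ++ka) {
          const int col = ka + k1 * (kb + k2 * kc) + K * c;
          double* oc = op + (size_t)col * Nout;
          for (int z = 0; z < o3; ++z) {
            const int iz = z * s3 - p3 + kc;
            const bool zin = iz >= 0 && iz < d3;
            for (int y = 0; y < o2; ++y) {
              const int iy = y * s2 - p2 + kb;
              const bool yin = iy >= 0 && iy < d2;
              double* orow = oc + (size_t)(z * o2 + y) * o1;
              if (!zin || !yin) {
                for (int xo = 0; xo < o1; ++xo) orow[xo] = 0.0;
                continue;
              }
              const double* xrow = xc + ((size_t)iz * d2 + iy) * d1;
              for (int xo = 0; xo < o1; ++xo) {
                const int ix = xo * s1 - p1 + ka;
                orow[xo] = (ix >= 0 && ix < d1) ? xrow[ix] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col3d: cols is Nout x (K*C); returns Nin x C.
// [[Rcpp::export]]
NumericMatrix col2im3d(const NumericMatrix& cols, const IntegerVector& dims,
                       const IntegerVector& ksize, const IntegerVector& stride,
                       const IntegerVector& pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = (d1 + 2 * p1 - k1) / s1 + 1;
  const int o2 = (d2 + 2 * p2 - k2) / s2 + 1;
  const int o3 = (d3 + 2 * p3 - k3) / s3 + 1;
  const int Nout = o1 * o2 * o3;
  const int K = k1 * k2 * k3;
  const int C = cols.ncol() / K;
  NumericMatrix out(d1 * d2 * d3, C);
  const double* cp = cols.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    double* oc = op + (size_t)c * d1 * d2 * d3;
    for (int kc = 0; kc < k3; ++kc) {
      for (int kb = 0; kb < k2; ++kb) {
        for (int ka = 0; ka < k1; ++ka) {
          const int col = ka + k1 * (kb + k2 * kc) + K * c;
          const double* cc = cp + (size_t)col * Nout;
          for (int z = 0; z < o3; ++z) {
            const int iz = z * s3 - p3 + kc;
            if (iz < 0 || iz >= d3) continue;
            for (int y = 0; y < o2; ++y) {
              const int iy = y * s2 - p2 + kb;
              if (iy < 0 || iy >= d2) continue;
              const double* crow = cc + (size_t)(z * o2 + y) * o1;
              double* orow = oc + ((size_t)iz * d2 + iy) * d1;
              for (int xo = 0; xo < o1; ++xo) {
                const int ix = xo * s1 - p1 + ka;
                if (ix >= 0 && ix < d1) orow[ix] += crow[xo];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List maxpool3d_fwd(const NumericMatrix& x, const IntegerVector& dims, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = d1 / k, o2 = d2 / k, o3 = d3 / k;
  const int C = x.ncol();
  const int Nout = o1 * o2 * o3;
  NumericMatrix y(Nout, C);
  IntegerMatrix idx(Nout, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * d1 * d2 * d3;
    for (int z = 0; z < o3; ++z)
      for (int yy = 0; yy < o2; ++yy)
        for (int xx = 0; xx < o1; ++xx) {
          double best = -1e300; int bi = -1;
          for (int kc = 0; kc < k; ++kc)
            for (int kb = 0; kb < k; ++kb)
              for (int ka = 0; ka < k; ++ka) {
                const int ii = (xx * k + ka) + d1 * ((yy * k + kb) + (size_t)d2 * (z * k + kc));
                if (xc[ii] > best) { best = xc[ii]; bi = ii; }
              }
          const int orow = xx + o1 * (yy + (size_t)o2 * z);
          y(orow, c) = best;
          idx(orow, c) = bi;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool3d_bwd(const NumericMatrix& dy, const IntegerMatrix& idx,
                            int n_in) {
  const int C = dy.ncol();
  NumericMatrix dx(n_in, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < dy.nrow(); ++r)
      dx(idx(r, c), c) += dy(r, c);
  return dx;
}

// 6-connected component labeling of the nonzero voxels of a binary grid.
// [[Rcpp::export]]
IntegerVector labelComponents6(const IntegerVector& mask, const IntegerVector& dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int x = v % d1, y = (v / d1) % d2, z = v / (d1 * d2);
      const int nb[6][3] = {{x-1,y,z},{x+1,y,z},{x,y-1,z},{x,y+1,z},{x,y,z-1},{x,y,z+1}};
      for (int t = 0; t < 6; ++t) {
        const int nx = nb[t][0], ny = nb[t][1], nz = nb[t][2];
        if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 || nz < 0 || nz >= d3) continue;
        const int w = nx + d1 * (ny + d2 * nz);
        if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// For each row of a (voxel indices, 0-based, n x 3) return the minimum
// Euclidean distance in mm to any row of b, given per-axis spacing.
// [[Rcpp::export]]
NumericVector minSurfaceDists(const IntegerMatrix& a, const IntegerMatrix& b,
                              const NumericVector& spacing) {
  const int n = a.nrow(), m = b.nrow();
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = a(i, 0) * s1, y = a(i, 1) * s2, z = a(i, 2) * s3;
    for (int j = 0; j < m; ++j) {
      const double dx = x - b(j, 0) * s1;
      const double dy = y - b(j, 1) * s2;
      const double dz = z - b(j, 2) * s3;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
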