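#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 1D correlation along one axis of a 3D array with edge-replicate borders.
// axis: 0 = x (fastest-varying), 1 = y, 2 = z.  Kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv1d_axis_cpp(const NumericVector& x, const IntegerVector& dim,
                              const NumericVector& kernel, const int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = (kernel.size() - 1) / 2;
  const long sy = nx, sz = (long)nx * ny;
  const long stride = axis == 0 ? 1L : (axis == 1 ? sy : sz);
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  NumericVector out(no_init(x.size()));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const long base = i + sy * (long)j + sz * (long)k;
        const int c = axis == 0 ? i : (axis == 1 ? j : k);
        double s = 0.0;
        for (int t = -h; t <= h; ++t) {
          const int cc = clampi(c + t, 0, len - 1);
          s += kernel[t + h] * x[base + stride * (long)(cc - c)];
        }
        out[base] = s;
      }
  return out;
}

// 3D median filter with cubic window of half-length h (edge-replicate borders).
// [[Rcpp::export]]
NumericVector median3d_cpp(const NumericVector& x, const IntegerVector& dim,
                           const int h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sy = nx, sz = (long)nx * ny;
  const int w = 2 * h + 1;
  const int nwin = w * w * w;
  const int mid = nwin / 2;  // nwin is odd
  NumericVector out(no_init(x.size()));
  std::vector<double> buf(nwin);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = 0;
        for (int dk = -h; dk <= h; ++dk) {
          const long zz = clampi(k + dk, 0, nz - 1) * sz;
          for (int dj = -h; dj <= h; ++dj) {
            const long yy = clampi(j + dj, 0, ny - 1) * sy;
            for (int di = -h; di <= h; ++di)
              buf[p++] = x[clampi(i + di, 0, nx - 1) + yy + zz];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[i + sy * (long)j + sz * (long)k] = buf[mid];
      }
  return out;
}

// Characteristic ratio at every voxel with intensity > 0: the fraction of
// in-bounds voxels of the (2h+1)^3 neighbourhood (centre included) whose
// intensity is <= the centre intensity.  Neighbourhoods are clipped at the
// volume boundary (no padding).  Voxels with intensity <= 0 get NA.
// [[Rcpp::export]]
NumericVector ratio_map_cpp(const NumericVector& x, const IntegerVector& dim,
                            const int h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sy = nx, sz = (long)nx * ny;
  NumericVector out(no_init(x.size()));
  for (int k = 0; k < nz; ++k) {
    const int k0 = std::max(0, k - h), k1 = std::min(nz - 1, k + h);
    for (int j = 0; j < ny; ++j) {
      const int j0 = std::max(0, j - h), j1 = std::min(ny - 1, j + h);
      for (int i = 0; i < nx; ++i) {
        const long base = i + sy * (long)j + sz * (long)k;
        const double c = x[base];
        if (!(c > 0.0)) { out[base] = NA_REAL; continue; }
        const int i0 = std::max(0, i - h), i1 = std::min(nx - 1, i + h);
        int tot = 0, le = 0;
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj) {
            const long off = sy * (long)jj + sz * (long)kk;
            for (int ii = i0; ii <= i1; ++ii) {
              ++tot;
              if (x[ii + off] <= c) ++le;
            }
          }
        out[base] = (double)le / (double)tot;
      }
    }
  }
  return out;
}

// 26-connected component labelling of a binary volume (non-zero = foreground).
// Returns integer labels, 0 for background, components numbered from 1 in
// first-encounter (column-major) order.
// [[Rcpp::export]]
IntegerVector label3d_cpp(const IntegerVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sy = nx, sz = (long)nx * ny, n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int next = 0;
  for (long seed = 0; seed < n; ++seed) {
    if (mask[seed] == 0 || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int i = (int)(v % nx);
      const int j = (int)((v / nx) % ny);
      const int k = (int)(v / sz);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const long u = ii + sy * (long)jj + sz * (long)kk;
            if (mask[u] != 0 && lab[u] == 0) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Exposed-face count per labelled component: a face is exposed when the
// 6-neighbour across it carries a different label (or lies outside the
// volume).  Used for digital surface area in the sphericity test.
// [[Rcpp::export]]
IntegerVector face_counts_cpp(const IntegerVector& lab, const IntegerVector& dim,
                              const int nlab) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sy = nx, sz = (long)nx * ny;
  IntegerVector faces(nlab, 0);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int l = lab[i + sy * (long)j + sz * (long)k];
        if (l == 0) continue;
        for (int d = 0; d < 6; ++d) {
          const int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
          int nb = 0;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            nb = lab[ii + sy * (long)jj + sz * (long)kk];
          if (nb != l) ++faces[l - 1];
        }
      }
  return faces;
}
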