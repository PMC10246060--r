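#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multi-component volume sampling at continuous 0-based voxel coordinates.
// vol is laid out (nx, ny, nz, nc) column-major; out-of-bounds samples are
// zero records (fields vanish away from the head).

static inline double voxval(const double* v, int nx, int ny, int nz,
                            int i, int j, int k, int c) {
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * ((size_t)k + (size_t)nz * (size_t)c))];
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_volume(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nc = dim[3];
  const int n = pts.nrow();
  const double* v = REAL(vol);
  NumericMatrix out(n, nc);

  for (int p = 0; p < n; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) {
      for (int c = 0; c < nc; ++c) out(p, c) = 0.0;
      continue;
    }
    if (nearest) {
      const int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        for (int c = 0; c < nc; ++c) out(p, c) = 0.0;
      } else {
        for (int c = 0; c < nc; ++c) out(p, c) = voxval(v, nx, ny, nz, i, j, k, c);
      }
    } else {
      const double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
      const int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
      const double wx = x - fx, wy = y - fy, wz = z - fz;
      for (int c = 0; c < nc; ++c) out(p, c) = 0.0;
      for (int di = 0; di <= 1; ++di) {
        const int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        const double wi = di ? wx : 1.0 - wx;
        if (wi == 0.0) continue;
        for (int dj = 0; dj <= 1; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= ny) continue;
          const double wj = dj ? wy : 1.0 - wy;
          if (wj == 0.0) continue;
          for (int dk = 0; dk <= 1; ++dk) {
            const int k = k0 + dk;
            if (k < 0 || k >= nz) continue;
            const double wk = dk ? wz : 1.0 - wz;
            if (wk == 0.0) continue;
            const double w = wi * wj * wk;
            for (int c = 0; c < nc; ++c)
              out(p, c) += w * voxval(v, nx, ny, nz, i, j, k, c);
          }
        }
      }
    }
  }
  return out;
}
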