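// 3D binary-morphology primitives shared by segmentation, interruption
// detection and void extension: separable squared Euclidean distance
// transform (Felzenszwalb & Huttenlocher), 26/6-connected component
// labelling, local-thickness sphere painting, and a separable Gaussian
// blur.  All grids are R arrays in column-major order; distances are in
// voxel units.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double INF = 1e20;

// 1D lower-envelope squared distance transform (in place across a strided
// line).  f holds squared distances on input and output.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// FALSE voxel of `mask`.  Zero on FALSE voxels.  If no FALSE voxel exists
// the result is INF everywhere.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * s3];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * s3] = d[k];
    }
  return out;
}

// Connected-component labelling of TRUE voxels.  connectivity: 6 or 26.
// Labels are consecutive from 1 in scan (column-major) order of each
// component's first voxel.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);

  std::vector<int> off1, off2, off3;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        off1.push_back(dx); off2.push_back(dy); off3.push_back(dz);
      }
  const int noff = (int)off1.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % n1);
      int j = (int)((cur / n1) % n2);
      int k = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < noff; ++t) {
        int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t q = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Local thickness (Hildebrand-Rueegsegger): per foreground voxel, the
// diameter (voxel units) of the largest sphere that contains the voxel and
// fits inside the structure.  Sphere radii are EDT - 0.5 (distance to the
// half-voxel boundary), so an n-voxel slab gets thickness n.  Painting in
// descending radius order.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector edt2 = edt_sq_cpp(mask, dims);
  NumericVector out(n, 0.0);

  std::vector<R_xlen_t> idx;
  idx.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return edt2[a] > edt2[b];
  });

  for (size_t t = 0; t < idx.size(); ++t) {
    R_xlen_t c = idx[t];
    double r = std::sqrt(edt2[c]) - 0.5;
    if (r < 0) r = 0;
    double th = 2.0 * r;
    if (th <= 0) continue;
    int i = (int)(c % n1);
    int j = (int)((c / n1) % n2);
    int k = (int)(c / ((R_xlen_t)n1 * n2));
    int ri = (int)std::floor(r);
    double r2 = r * r;
    for (int dz = -ri; dz <= ri; ++dz) {
      int kk = k + dz;
      if (kk < 0 || kk >= n3) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int jj = j + dy;
        if (jj < 0 || jj >= n2) continue;
        double rem = r2 - dz * (double)dz - dy * (double)dy;
        if (rem < 0) continue;
        int rx = (int)std::floor(std::sqrt(rem));
        int lo = std::max(0, i - rx), hi = std::min(n1 - 1, i + rx);
        R_xlen_t base = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1;
        for (int ii = lo; ii <= hi; ++ii) {
          R_xlen_t q = base + ii;
          if (out[q] < th) out[q] = th;
        }
      }
    }
  }
  return out;
}

// Separable Gaussian blur, sigma in voxels, kernel truncated at 4 sigma,
// reflecting boundary.
// [[Rcpp::export(name = ".gauss_blur3_cpp")]]
NumericVector gauss_blur3_cpp(NumericVector vol, IntegerVector dims,
                              double sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (sigma <= 0) return clone(vol);

  int hw = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * hw + 1);
  double s = 0;
  for (int t = -hw; t <= hw; ++t) {
    ker[t + hw] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + hw];
  }
  for (auto& x : ker) x /= s;

  NumericVector a = clone(vol), b(n);
  auto reflect = [](int i, int len) {
    while (i < 0 || i >= len) {
      if (i < 0) i = -i - 1;
      if (i >= len) i = 2 * len - i - 1;
    }
    return i;
  };

  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) {
        double acc = 0;
        for (int t = -hw; t <= hw; ++t)
          acc += ker[t + hw] * a[base + reflect(i + t, n1)];
        b[base + i] = acc;
      }
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) {
        double acc = 0;
        for (int t = -hw; t <= hw; ++t)
          acc += ker[t + hw] * b[base + (R_xlen_t)reflect(j + t, n2) * n1];
        a[base + (R_xlen_t)j * n1] = acc;
      }
    }
  // axis 3
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) {
        double acc = 0;
        for (int t = -hw; t <= hw; ++t)
          acc += ker[t + hw] * a[base + (R_xlen_t)reflect(k + t, n3) * s3];
        b[base + (R_xlen_t)k * s3] = acc;
      }
    }
  return b;
}
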