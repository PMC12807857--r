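// Low-level 3D volume primitives. All arrays are R arrays with
// dim = c(nz, ny, nx) (z fastest), addressed as z + nz*(y + ny*x).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

struct Offsets {
  std::vector<int> dz, dy, dx;
};

static Offsets conn_offsets(int connectivity) {
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int l1 = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && l1 != 1) continue;
        o.dz.push_back(dz); o.dy.push_back(dy); o.dx.push_back(dx);
      }
  return o;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  Offsets off = conn_offsets(connectivity);
  int nextlab = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++nextlab;
        lab[i] = nextlab;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (size_t k = 0; k < off.dz.size(); ++k) {
            int zz = cz + off.dz[k], yy = cy + off.dy[k], xx = cx + off.dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = nextlab;
              stack.push_back(j);
            }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// Fill interior background cavities: background voxels not reachable from
// the array border by 6-connected background paths become foreground.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  Offsets off = conn_offsets(6);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 &&
            x != 0 && x != nx - 1) continue;
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int cz = (int)(cur % nz);
    int cy = (int)((cur / nz) % ny);
    int cx = (int)(cur / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < off.dz.size(); ++k) {
      int zz = cz + off.dz[k], yy = cy + off.dy[k], xx = cx + off.dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] && !outside[j]) { outside[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Binary erosion/dilation with an arbitrary structuring element given as an
// integer matrix of voxel offsets (rows: dz, dy, dx). Outside the array is
// treated as background.
// [[Rcpp::export(name = ".cpp_morph")]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets, bool erode) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, false);
  int m = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (erode) {
          if (!mask[i]) continue;
          bool keep = true;
          for (int k = 0; k < m && keep; ++k) {
            int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
                xx = x + offsets(k, 2);
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                xx >= nx || !mask[idx3(zz, yy, xx, nz, ny)])
              keep = false;
          }
          out[i] = keep;
        } else {
          if (!mask[i]) continue;
          for (int k = 0; k < m; ++k) {
            int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
                xx = x + offsets(k, 2);
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                xx >= nx) continue;
            out[idx3(zz, yy, xx, nz, ny)] = true;
          }
        }
      }
  out.attr("dim") = dim;
  return out;
}

static void conv_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double> &kernel) {
  int r = ((int)kernel.size() - 1) / 2;
  int nAxis = axis == 0 ? nz : (axis == 1 ? ny : nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz += k; else if (axis == 1) yy += k; else xx += k;
          int p = axis == 0 ? zz : (axis == 1 ? yy : xx);
          if (p < 0 || p >= nAxis) continue;  // zero padding
          acc += kernel[k + r] * v[idx3(zz, yy, xx, nz, ny)];
        }
        tmp[idx3(z, y, x, nz, ny)] = acc;
      }
  v.swap(tmp);
}

// Separable Gaussian blur, sigma in voxels per axis (z, y, x); zero padding.
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> v(vol.begin(), vol.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> kernel(2 * r + 1);
    double sum = 0.0;
    for (int k = -r; k <= r; ++k) {
      kernel[k + r] = std::exp(-0.5 * k * k / (s * s));
      sum += kernel[k + r];
    }
    for (double &w : kernel) w /= sum;
    conv_axis(v, tmp, nz, ny, nx, axis, kernel);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear resampling onto a new grid. Voxel centers are aligned in
// physical space: position of output voxel i is (i + 0.5) * out_spacing,
// mapped into input voxel coordinates and clamped to the valid range.
// [[Rcpp::export(name = ".cpp_resample_trilinear")]]
NumericVector cpp_resample_trilinear(NumericVector vol, IntegerVector dim,
                                     IntegerVector outDim,
                                     NumericVector spacingIn,
                                     NumericVector spacingOut) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int oz = outDim[0], oy = outDim[1], ox = outDim[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  std::vector<double> zc(oz), yc(oy), xc(ox);
  std::vector<int> z0(oz), y0(oy), x0(ox);
  std::vector<double> zf(oz), yf(oy), xf(ox);
  auto prep = [](std::vector<double> &c, std::vector<int> &i0,
                 std::vector<double> &f, int nOut, int nIn,
                 double spIn, double spOut) {
    for (int i = 0; i < nOut; ++i) {
      double p = ((i + 0.5) * spOut) / spIn - 0.5;
      if (p < 0) p = 0;
      if (p > nIn - 1) p = nIn - 1;
      int lo = (int)std::floor(p);
      if (lo > nIn - 2) lo = std::max(0, nIn - 2);
      c[i] = p; i0[i] = lo; f[i] = p - lo;
    }
  };
  prep(zc, z0, zf, oz, nz, spacingIn[0], spacingOut[0]);
  prep(yc, y0, yf, oy, ny, spacingIn[1], spacingOut[1]);
  prep(xc, x0, xf, ox, nx, spacingIn[2], spacingOut[2]);
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z) {
        int zi = z0[z], yi = y0[y], xi = x0[x];
        double fz = zf[z], fy = yf[y], fx = xf[x];
        int z1 = std::min(zi + 1, nz - 1), y1 = std::min(yi + 1, ny - 1),
            x1 = std::min(xi + 1, nx - 1);
        double c000 = vol[idx3(zi, yi, xi, nz, ny)];
        double c100 = vol[idx3(z1, yi, xi, nz, ny)];
        double c010 = vol[idx3(zi, y1, xi, nz, ny)];
        double c110 = vol[idx3(z1, y1, xi, nz, ny)];
        double c001 = vol[idx3(zi, yi, x1, nz, ny)];
        double c101 = vol[idx3(z1, yi, x1, nz, ny)];
        double c011 = vol[idx3(zi, y1, x1, nz, ny)];
        double c111 = vol[idx3(z1, y1, x1, nz, ny)];
        double c00 = c000 * (1 - fz) + c100 * fz;
        double c01 = c001 * (1 - fz) + c101 * fz;
        double c10 = c010 * (1 - fz) + c110 * fz;
        double c11 = c011 * (1 - fz) + c111 * fz;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        double val = c0 * (1 - fx) + c1 * fx;
        out[idx3(z, y, x, oz, oy)] = val < 0 ? 0.0 : val;
      }
  out.attr("dim") = outDim;
  return out;
}

// Voxel counts per label id (ignoring 0); returns named integer vector.
// [[Rcpp::export(name = ".cpp_label_sizes")]]
IntegerVector cpp_label_sizes(IntegerVector lab, int maxLabel) {
  std::vector<int> cnt(maxLabel + 1, 0);
  for (R_xlen_t i = 0; i < lab.size(); ++i) {
    int v = lab[i];
    if (v > 0 && v <= maxLabel) cnt[v]++;
  }
  IntegerVector out(maxLabel);
  for (int i = 1; i <= maxLabel; ++i) out[i - 1] = cnt[i];
  return out;
}
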