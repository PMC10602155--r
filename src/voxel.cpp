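#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Deposit one unit of mass per bead as the product of 1-D Gaussian
// integrals over each voxel (difference of normal CDFs per axis),
// truncated at +/- trunc_sd standard deviations.
// [[Rcpp::export(name = ".voxelize_cpp")]]
NumericVector voxelize_cpp(NumericMatrix coords, NumericVector origin,
                           IntegerVector dims, double edge, double sigma,
                           double trunc_sd) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector stack((R_xlen_t) nx * ny * nz);
  int n = coords.nrow();
  double half = trunc_sd * sigma;
  std::vector<double> wx, wy, wz;

  for (int b = 0; b < n; ++b) {
    double cx = coords(b, 0), cy = coords(b, 1), cz = coords(b, 2);
    int ix0 = std::max(0, (int) std::floor((cx - half - origin[0]) / edge));
    int ix1 = std::min(nx - 1, (int) std::floor((cx + half - origin[0]) / edge));
    int iy0 = std::max(0, (int) std::floor((cy - half - origin[1]) / edge));
    int iy1 = std::min(ny - 1, (int) std::floor((cy + half - origin[1]) / edge));
    int iz0 = std::max(0, (int) std::floor((cz - half - origin[2]) / edge));
    int iz1 = std::min(nz - 1, (int) std::floor((cz + half - origin[2]) / edge));
    if (ix1 < ix0 || iy1 < iy0 || iz1 < iz0) continue;
    wx.resize(ix1 - ix0 + 1); wy.resize(iy1 - iy0 + 1); wz.resize(iz1 - iz0 + 1);
    for (int i = ix0; i <= ix1; ++i) {
      double lo = origin[0] + i * edge, hi = lo + edge;
      wx[i - ix0] = R::pnorm(hi, cx, sigma, 1, 0) - R::pnorm(lo, cx, sigma, 1, 0);
    }
    for (int i = iy0; i <= iy1; ++i) {
      double lo = origin[1] + i * edge, hi = lo + edge;
      wy[i - iy0] = R::pnorm(hi, cy, sigma, 1, 0) - R::pnorm(lo, cy, sigma, 1, 0);
    }
    for (int i = iz0; i <= iz1; ++i) {
      double lo = origin[2] + i * edge, hi = lo + edge;
      wz[i - iz0] = R::pnorm(hi, cz, sigma, 1, 0) - R::pnorm(lo, cz, sigma, 1, 0);
    }
    for (int k = iz0; k <= iz1; ++k)
      for (int j = iy0; j <= iy1; ++j) {
        double wyz = wy[j - iy0] * wz[k - iz0];
        R_xlen_t base = (R_xlen_t) nx * (j + (R_xlen_t) ny * k);
        for (int i = ix0; i <= ix1; ++i)
          stack[base + i] += wx[i - ix0] * wyz;
      }
  }
  return stack;
}

// Separable Gaussian smoothing of a 3-D array, reflecting boundaries.
// [[Rcpp::export(name = ".smooth3d_cpp")]]
NumericVector smooth3d_cpp(NumericVector stack, IntegerVector dims,
                           double sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int half = std::max(1, (int) std::ceil(3.0 * sigma_vox));
  std::vector<double> kern(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    kern[i + half] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += kern[i + half];
  }
  for (double &k : kern) k /= s;

  NumericVector a = clone(stack), b((R_xlen_t) nx * ny * nz);
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k);
  };
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int o = -half; o <= half; ++o)
          acc += kern[o + half] * a[idx(reflect(i + o, nx), j, k)];
        b[idx(i, j, k)] = acc;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int o = -half; o <= half; ++o)
          acc += kern[o + half] * b[idx(i, reflect(j + o, ny), k)];
        a[idx(i, j, k)] = acc;
      }
  if (nz == 1) return a;
  // z pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int o = -half; o <= half; ++o)
          acc += kern[o + half] * a[idx(i, j, reflect(k + o, nz))];
        b[idx(i, j, k)] = acc;
      }
  return b;
}

// Strict local maxima over the 26-neighbourhood (8 in 2-D stacks) above an
// intensity threshold.  Returns 1-based voxel indices (i, j, k) by column.
// [[Rcpp::export(name = ".local_maxima_cpp")]]
IntegerMatrix local_maxima_cpp(NumericVector stack, IntegerVector dims,
                               double threshold) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k);
  };
  std::vector<int> vi, vj, vk;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = stack[idx(i, j, k)];
        if (v < threshold) continue;
        bool is_max = true;
        for (int dk = -1; dk <= 1 && is_max; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1 && is_max; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di; if (ii < 0 || ii >= nx) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (stack[idx(ii, jj, kk)] >= v) { is_max = false; break; }
            }
          }
        }
        if (is_max) { vi.push_back(i + 1); vj.push_back(j + 1); vk.push_back(k + 1); }
      }
  IntegerMatrix out((int) vi.size(), 3);
  for (size_t r = 0; r < vi.size(); ++r) {
    out(r, 0) = vi[r]; out(r, 1) = vj[r]; out(r, 2) = vk[r];
  }
  return out;
}

// Mass-scaling curves: for every seed voxel in a cubic window about
// `center` (1-based voxel indices), M(r) = total intensity within radius r
// of the seed voxel centre; curves averaged weighted by seed intensity.
// Distances are Euclidean in voxel units times `edge`; in 2-D stacks
// (nz == 1) they are in-plane.  r_breaks are in physical units (nm).
// [[Rcpp::export(name = ".mass_scaling_cpp")]]
NumericVector mass_scaling_cpp(NumericVector stack, IntegerVector dims,
                               double edge, IntegerVector center, int window,
                               NumericVector r_breaks) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nb = r_breaks.size();
  double r_max = r_breaks[nb - 1];
  int rv = (int) std::ceil(r_max / edge);
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k);
  };

  // precompute voxel offsets within r_max with their radial bin
  std::vector<int> oi, oj, ok, ob;
  int rz = (nz == 1) ? 0 : rv;
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -rv; dj <= rv; ++dj)
      for (int di = -rv; di <= rv; ++di) {
        double d = edge * std::sqrt((double) di * di + dj * dj + dk * dk);
        if (d >= r_max) continue;
        int b = 0;
        // half-open bins [r_breaks[b], r_breaks[b+1])
        if (d < r_breaks[0]) continue;
        while (b < nb - 2 && d >= r_breaks[b + 1]) ++b;
        oi.push_back(di); oj.push_back(dj); ok.push_back(dk); ob.push_back(b);
      }

  int hw = window / 2;
  NumericVector acc(nb - 1), curve(nb - 1);
  double wsum = 0.0;
  int hz = (nz == 1) ? 0 : hw;
  for (int sk = center[2] - 1 - hz; sk <= center[2] - 1 + hz; ++sk)
    for (int sj = center[1] - 1 - hw; sj <= center[1] - 1 + hw; ++sj)
      for (int si = center[0] - 1 - hw; si <= center[0] - 1 + hw; ++si) {
        if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
          continue;
        double w = stack[idx(si, sj, sk)];
        if (w <= 0.0) continue;
        std::fill(curve.begin(), curve.end(), 0.0);
        for (size_t o = 0; o < oi.size(); ++o) {
          int ii = si + oi[o], jj = sj + oj[o], kk = sk + ok[o];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          curve[ob[o]] += stack[idx(ii, jj, kk)];
        }
        double run = 0.0;
        for (int b = 0; b < nb - 1; ++b) {
          run += curve[b];
          acc[b] += w * run;
        }
        wsum += w;
      }
  if (wsum <= 0.0) stop("empty mass-scaling window");
  for (int b = 0; b < nb - 1; ++b) acc[b] /= wsum;
  return acc;
}
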