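#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Shared spatial hash for fixed-radius neighbour queries.
namespace {

struct Grid {
  double x0, y0, z0, edge;
  int nx, ny, nz;
  std::vector<int> head, nxt;

  void build(const NumericMatrix &c, double cell_edge) {
    int n = c.nrow();
    x0 = c(0, 0); y0 = c(0, 1); z0 = c(0, 2);
    double x1 = x0, y1 = y0, z1 = z0;
    for (int i = 1; i < n; ++i) {
      x0 = std::min(x0, c(i, 0)); x1 = std::max(x1, c(i, 0));
      y0 = std::min(y0, c(i, 1)); y1 = std::max(y1, c(i, 1));
      z0 = std::min(z0, c(i, 2)); z1 = std::max(z1, c(i, 2));
    }
    edge = cell_edge;
    nx = std::max(1, (int) std::floor((x1 - x0) / edge) + 1);
    ny = std::max(1, (int) std::floor((y1 - y0) / edge) + 1);
    nz = std::max(1, (int) std::floor((z1 - z0) / edge) + 1);
    head.assign((size_t) nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int ix = (int) std::floor((c(i, 0) - x0) / edge);
      int iy = (int) std::floor((c(i, 1) - y0) / edge);
      int iz = (int) std::floor((c(i, 2) - z0) / edge);
      int cell = ix + nx * (iy + ny * iz);
      nxt[i] = head[cell];
      head[cell] = i;
    }
  }
};

inline int bin_of(double v, const NumericVector &breaks) {
  // index of half-open bin [breaks[k], breaks[k+1]); -1 if outside
  int nb = breaks.size();
  if (v < breaks[0] || v >= breaks[nb - 1]) return -1;
  int lo = 0, hi = nb - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (v < breaks[mid]) hi = mid; else lo = mid;
  }
  return lo;
}

} // namespace

// Histogram of genomic separations |cum_bp[j] - cum_bp[i]| over all pairs
// with spatial distance < cutoff, binned by `breaks` (half-open).
// [[Rcpp::export(name = ".contact_hist_cpp")]]
NumericVector contact_hist_cpp(NumericMatrix coords, NumericVector cum_bp,
                               double cutoff, NumericVector breaks) {
  int n = coords.nrow();
  NumericVector counts(breaks.size() - 1);
  Grid g;
  g.build(coords, cutoff);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int cix = (int) std::floor((coords(i, 0) - g.x0) / g.edge);
    int ciy = (int) std::floor((coords(i, 1) - g.y0) / g.edge);
    int ciz = (int) std::floor((coords(i, 2) - g.z0) / g.edge);
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = ciz + dz; if (iz < 0 || iz >= g.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = ciy + dy; if (iy < 0 || iy >= g.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = cix + dx; if (ix < 0 || ix >= g.nx) continue;
          for (int j = g.head[ix + g.nx * (iy + g.ny * iz)]; j >= 0;
               j = g.nxt[j]) {
            if (j <= i) continue;
            double ddx = coords(i, 0) - coords(j, 0);
            double ddy = coords(i, 1) - coords(j, 1);
            double ddz = coords(i, 2) - coords(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz >= c2) continue;
            int b = bin_of(std::abs(cum_bp[j] - cum_bp[i]), breaks);
            if (b >= 0) counts[b] += 1.0;
          }
        }
      }
    }
  }
  return counts;
}

// O(N^2) oracle for the contact histogram.
// [[Rcpp::export(name = ".contact_hist_brute_cpp")]]
NumericVector contact_hist_brute_cpp(NumericMatrix coords, NumericVector cum_bp,
                                     double cutoff, NumericVector breaks) {
  int n = coords.nrow();
  NumericVector counts(breaks.size() - 1);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ddx = coords(i, 0) - coords(j, 0);
      double ddy = coords(i, 1) - coords(j, 1);
      double ddz = coords(i, 2) - coords(j, 2);
      if (ddx * ddx + ddy * ddy + ddz * ddz >= c2) continue;
      int b = bin_of(std::abs(cum_bp[j] - cum_bp[i]), breaks);
      if (b >= 0) counts[b] += 1.0;
    }
  }
  return counts;
}

// Cumulative pair correlation: for each reference bead (given by 1-based
// `ref_idx`), histogram distances to ALL other beads up to r_max =
// max(r_breaks), then cumulative-sum and average over reference beads.
// Returns mean cumulative neighbour count G at each break point > 0.
// [[Rcpp::export(name = ".gofr_cpp")]]
NumericVector gofr_cpp(NumericMatrix coords, IntegerVector ref_idx,
                       NumericVector r_breaks) {
  int nb = r_breaks.size();
  double r_max = r_breaks[nb - 1];
  NumericVector hist(nb - 1);
  Grid g;
  g.build(coords, r_max);
  double r2 = r_max * r_max;
  int nref = ref_idx.size();
  for (int k = 0; k < nref; ++k) {
    int i = ref_idx[k] - 1;
    int cix = (int) std::floor((coords(i, 0) - g.x0) / g.edge);
    int ciy = (int) std::floor((coords(i, 1) - g.y0) / g.edge);
    int ciz = (int) std::floor((coords(i, 2) - g.z0) / g.edge);
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = ciz + dz; if (iz < 0 || iz >= g.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = ciy + dy; if (iy < 0 || iy >= g.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = cix + dx; if (ix < 0 || ix >= g.nx) continue;
          for (int j = g.head[ix + g.nx * (iy + g.ny * iz)]; j >= 0;
               j = g.nxt[j]) {
            if (j == i) continue;
            double ddx = coords(i, 0) - coords(j, 0);
            double ddy = coords(i, 1) - coords(j, 1);
            double ddz = coords(i, 2) - coords(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 >= r2) continue;
            int b = bin_of(std::sqrt(d2), r_breaks);
            if (b >= 0) hist[b] += 1.0;
          }
        }
      }
    }
  }
  NumericVector G(nb - 1);
  double acc = 0.0;
  for (int b = 0; b < nb - 1; ++b) {
    acc += hist[b];
    G[b] = acc / nref;
  }
  return G;
}

// O(N_ref * N) oracle for G(r).
// [[Rcpp::export(name = ".gofr_brute_cpp")]]
NumericVector gofr_brute_cpp(NumericMatrix coords, IntegerVector ref_idx,
                             NumericVector r_breaks) {
  int nb = r_breaks.size();
  int n = coords.nrow();
  NumericVector hist(nb - 1);
  int nref = ref_idx.size();
  for (int k = 0; k < nref; ++k) {
    int i = ref_idx[k] - 1;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double ddx = coords(i, 0) - coords(j, 0);
      double ddy = coords(i, 1) - coords(j, 1);
      double ddz = coords(i, 2) - coords(j, 2);
      int b = bin_of(std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz), r_breaks);
      if (b >= 0) hist[b] += 1.0;
    }
  }
  NumericVector G(nb - 1);
  double acc = 0.0;
  for (int b = 0; b < nb - 1; ++b) {
    acc += hist[b];
    G[b] = acc / nref;
  }
  return G;
}

// Mean squared spatial distance per genomic-separation bin from explicit
// pair samples (i, j are 1-based bead indices).
// [[Rcpp::export(name = ".pair_sqdist_cpp")]]
NumericVector pair_sqdist_cpp(NumericMatrix coords, IntegerVector i,
                              IntegerVector j) {
  int m = i.size();
  NumericVector d2(m);
  for (int k = 0; k < m; ++k) {
    double ddx = coords(i[k] - 1, 0) - coords(j[k] - 1, 0);
    double ddy = coords(i[k] - 1, 1) - coords(j[k] - 1, 1);
    double ddz = coords(i[k] - 1, 2) - coords(j[k] - 1, 2);
    d2[k] = ddx * ddx + ddy * ddy + ddz * ddz;
  }
  return d2;
}
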