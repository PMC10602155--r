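#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Cell list over the bounding box of the coordinates.  Cell edge must be
// >= the interaction range so that all interacting pairs sit in the same
// or adjacent cells.
struct CellList {
  double x0, y0, z0, edge;
  int nx, ny, nz;
  std::vector<int> head;   // first bead index per cell, -1 if empty
  std::vector<int> next;   // linked list over beads

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, double cell_edge) {
    int n = (int) x.size();
    double x1, y1, z1;
    x0 = x1 = x[0]; y0 = y1 = y[0]; z0 = z1 = z[0];
    for (int i = 1; i < n; ++i) {
      x0 = std::min(x0, x[i]); x1 = std::max(x1, x[i]);
      y0 = std::min(y0, y[i]); y1 = std::max(y1, y[i]);
      z0 = std::min(z0, z[i]); z1 = std::max(z1, z[i]);
    }
    edge = cell_edge;
    nx = std::max(1, (int) std::floor((x1 - x0) / edge) + 1);
    ny = std::max(1, (int) std::floor((y1 - y0) / edge) + 1);
    nz = std::max(1, (int) std::floor((z1 - z0) / edge) + 1);
    head.assign((size_t) nx * ny * nz, -1);
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      next[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline int cell_of(double xx, double yy, double zz) const {
    int ix = clampi((int) std::floor((xx - x0) / edge), 0, nx - 1);
    int iy = clampi((int) std::floor((yy - y0) / edge), 0, ny - 1);
    int iz = clampi((int) std::floor((zz - z0) / edge), 0, nz - 1);
    return ix + nx * (iy + ny * iz);
  }
  inline int index(int ix, int iy, int iz) const {
    return ix + nx * (iy + ny * iz);
  }
};

// Minimum non-bonded pair distance (beads i, i+1 are bonded and skipped).
// Returns {min_dist, i, j}.
static void min_nonbonded(const std::vector<double> &x,
                          const std::vector<double> &y,
                          const std::vector<double> &z,
                          const CellList &cl, double &dmin,
                          int &imin, int &jmin) {
  int n = (int) x.size();
  dmin = R_PosInf; imin = jmin = -1;
  for (int i = 0; i < n; ++i) {
    int cix = (int) std::floor((x[i] - cl.x0) / cl.edge);
    int ciy = (int) std::floor((y[i] - cl.y0) / cl.edge);
    int ciz = (int) std::floor((z[i] - cl.z0) / cl.edge);
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = ciz + dz; if (iz < 0 || iz >= cl.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = ciy + dy; if (iy < 0 || iy >= cl.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = cix + dx; if (ix < 0 || ix >= cl.nx) continue;
          for (int j = cl.head[cl.index(ix, iy, iz)]; j >= 0; j = cl.next[j]) {
            if (j <= i + 1 && j >= i - 1) continue; // self and bonded
            if (j < i) continue;                    // count each pair once
            double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < dmin * dmin) {
              dmin = std::sqrt(d2); imin = i; jmin = j;
            }
          }
        }
      }
    }
  }
}

// Overdamped relaxation under soft pairwise repulsion
// E = k_rep * (2 r0 - r)^2 for non-bonded r < 2 r0, plus harmonic bonds
// E = k_bond * (r - L0)^2.  Beads move by step * force each sweep.  When
// the minimum non-bonded distance stalls between checks while overlaps
// remain, overlapping beads get small zero-mean uniform kicks and the
// repulsion stiffness is boosted by stall_boost (with the step shrunk by
// the same factor, keeping the explicit update stable): residual overlaps
// held in place by stretched bonds are squeezed out penalty-style as the
// repulsion-to-bond stiffness ratio grows.
// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix coords, NumericVector bond_l0, double r0,
               double k_rep, double k_bond, double step, double noise_amp,
               double tol, int check_interval, int max_sweeps,
               double stall_boost, bool record_energy) {
  RNGScope scope;
  int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  double dcut = 2.0 * r0;
  double target = dcut * (1.0 - tol);
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<char> overlapped(n);
  std::vector<double> energy_trace;
  CellList cl;

  double last_min = -1.0;
  int sweeps = 0;
  bool converged = false;
  double dmin = R_PosInf;
  int imin = -1, jmin = -1;

  if (n == 1) {
    converged = true;
  }

  while (!converged && sweeps < max_sweeps) {
    ++sweeps;
    cl.build(x, y, z, dcut);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(overlapped.begin(), overlapped.end(), 0);
    double e_rep = 0.0;

    // pairwise repulsion via cell list (each pair visited once)
    for (int i = 0; i < n; ++i) {
      int cix = (int) std::floor((x[i] - cl.x0) / cl.edge);
      int ciy = (int) std::floor((y[i] - cl.y0) / cl.edge);
      int ciz = (int) std::floor((z[i] - cl.z0) / cl.edge);
      for (int dz = -1; dz <= 1; ++dz) {
        int izc = ciz + dz; if (izc < 0 || izc >= cl.nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int iyc = ciy + dy; if (iyc < 0 || iyc >= cl.ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int ixc = cix + dx; if (ixc < 0 || ixc >= cl.nx) continue;
            for (int j = cl.head[cl.index(ixc, iyc, izc)]; j >= 0;
                 j = cl.next[j]) {
              if (j <= i) continue;
              if (j == i + 1) continue; // bonded neighbours handled below
              double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 >= dcut * dcut) continue;
              double d = std::sqrt(d2);
              double overlap = dcut - d;
              double fmag;
              double ux, uy, uz;
              if (d > 1e-12) {
                ux = ddx / d; uy = ddy / d; uz = ddz / d;
              } else {
                // coincident centres: deterministic split along x
                ux = 1.0; uy = 0.0; uz = 0.0;
              }
              fmag = 2.0 * k_rep * overlap;
              fx[i] += fmag * ux; fy[i] += fmag * uy; fz[i] += fmag * uz;
              fx[j] -= fmag * ux; fy[j] -= fmag * uy; fz[j] -= fmag * uz;
              overlapped[i] = overlapped[j] = 1;
              if (record_energy) e_rep += k_rep * overlap * overlap;
            }
          }
        }
      }
    }

    // harmonic bonds
    for (int i = 0; i < n - 1; ++i) {
      double ddx = x[i + 1] - x[i], ddy = y[i + 1] - y[i],
             ddz = z[i + 1] - z[i];
      double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d < 1e-12) continue;
      double fmag = 2.0 * k_bond * (d - bond_l0[i]) / d;
      fx[i] += fmag * ddx; fy[i] += fmag * ddy; fz[i] += fmag * ddz;
      fx[i + 1] -= fmag * ddx; fy[i + 1] -= fmag * ddy; fz[i + 1] -= fmag * ddz;
    }

    for (int i = 0; i < n; ++i) {
      x[i] += step * fx[i];
      y[i] += step * fy[i];
      z[i] += step * fz[i];
    }
    if (record_energy) energy_trace.push_back(e_rep);

    if (sweeps % check_interval == 0) {
      cl.build(x, y, z, dcut);
      min_nonbonded(x, y, z, cl, dmin, imin, jmin);
      if (dmin >= target) {
        converged = true;
        break;
      }
      bool stalled = last_min >= 0.0 && dmin - last_min < 1e-3 * dcut;
      if (stalled && stall_boost > 1.0) {
        k_rep *= stall_boost;
        step /= stall_boost;
      }
      if (noise_amp > 0.0 && stalled) {
        // stalled: kick overlapping beads, zero-mean per coordinate
        double mx = 0.0, my = 0.0, mz = 0.0;
        int nk = 0;
        std::vector<double> kx(n, 0.0), ky(n, 0.0), kz(n, 0.0);
        for (int i = 0; i < n; ++i) {
          if (!overlapped[i]) continue;
          kx[i] = noise_amp * (2.0 * unif_rand() - 1.0);
          ky[i] = noise_amp * (2.0 * unif_rand() - 1.0);
          kz[i] = noise_amp * (2.0 * unif_rand() - 1.0);
          mx += kx[i]; my += ky[i]; mz += kz[i];
          ++nk;
        }
        if (nk > 0) {
          mx /= nk; my /= nk; mz /= nk;
          for (int i = 0; i < n; ++i) {
            if (!overlapped[i]) continue;
            x[i] += kx[i] - mx; y[i] += ky[i] - my; z[i] += kz[i] - mz;
          }
        }
      }
      last_min = dmin;
    }
  }

  if (!converged && n > 1) {
    cl.build(x, y, z, dcut);
    min_nonbonded(x, y, z, cl, dmin, imin, jmin);
    converged = dmin >= target;
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return List::create(_["coords"] = out,
                      _["sweeps"] = sweeps,
                      _["converged"] = converged,
                      _["min_dist"] = dmin,
                      _["worst_pair"] = IntegerVector::create(imin + 1, jmin + 1),
                      _["energy_trace"] = wrap(energy_trace));
}

// Minimum non-bonded distance through the cell list (used by reports).
// [[Rcpp::export(name = ".min_nonbonded_cpp")]]
List min_nonbonded_cpp(NumericMatrix coords, double cell_edge) {
  int n = coords.nrow();
  if (n < 3)
    return List::create(_["min_dist"] = R_PosInf,
                        _["pair"] = IntegerVector::create(NA_INTEGER, NA_INTEGER));
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  CellList cl;
  cl.build(x, y, z, cell_edge);
  double dmin; int imin, jmin;
  min_nonbonded(x, y, z, cl, dmin, imin, jmin);
  // cell-list min is exact only if dmin <= cell_edge; enlarge otherwise
  while (dmin > cl.edge && n > 2) {
    cl.build(x, y, z, cl.edge * 2.0);
    min_nonbonded(x, y, z, cl, dmin, imin, jmin);
    if (cl.edge > 4.0 * dmin) break;
  }
  return List::create(_["min_dist"] = dmin,
                      _["pair"] = IntegerVector::create(imin + 1, jmin + 1));
}
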