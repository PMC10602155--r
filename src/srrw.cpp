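#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Self-returning random walk generator.
//
// At every step, if the backbone stack is non-empty, a return is attempted
// with probability U0^(-alpha)/alpha where U0 is the length of the step on
// top of the stack; a return retraces that step exactly and pops it.
// Otherwise (or when the stack is empty) an isotropic forward jump is drawn
// with length from the pdf (alpha+1) * U^-(alpha+2) on U > 1, truncated at
// u_max by resampling.  The proposed vertex must fall within rc_units of the
// centre of mass of all vertices generated so far, else the whole jump
// (direction and length) is redrawn.  All lengths are in units of the
// minimum jump b.  Uses R's RNG so set.seed() gives bit-identical output.

static inline double jump_length(double alpha) {
  // inverse CDF of (alpha+1) U^-(alpha+2) on (1, Inf)
  double u = unif_rand();
  return std::pow(1.0 - u, -1.0 / (alpha + 1.0));
}

static inline void iso_dir(double &dx, double &dy, double &dz) {
  // Marsaglia sphere picking
  double a, b, s;
  do {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0);
  double root = 2.0 * std::sqrt(1.0 - s);
  dx = a * root;
  dy = b * root;
  dz = 1.0 - 2.0 * s;
}

// [[Rcpp::export(name = ".srrw_generate_cpp")]]
List srrw_generate_cpp(int n_steps, double alpha, double u_max,
                       double rc_units, int attempt_cap) {
  RNGScope scope;

  std::vector<double> x(n_steps + 1), y(n_steps + 1), z(n_steps + 1);
  IntegerVector kind(n_steps);       // 0 = jump, 1 = return
  IntegerVector depth(n_steps);      // stack depth after the step

  // backbone stack of step vectors and their lengths
  std::vector<double> sx, sy, sz, slen;
  sx.reserve(n_steps); sy.reserve(n_steps); sz.reserve(n_steps);
  slen.reserve(n_steps);

  x[0] = y[0] = z[0] = 0.0;
  // running centre of mass of generated vertices
  double cx = 0.0, cy = 0.0, cz = 0.0;
  int nv = 1;
  int n_return = 0;

  for (int i = 0; i < n_steps; ++i) {
    bool did_return = false;
    if (!slen.empty()) {
      double u0 = slen.back();
      double p_ret = std::pow(u0, -alpha) / alpha;
      if (unif_rand() < p_ret) {
        // retrace the top-of-stack step
        x[i + 1] = x[i] - sx.back();
        y[i + 1] = y[i] - sy.back();
        z[i + 1] = z[i] - sz.back();
        sx.pop_back(); sy.pop_back(); sz.pop_back(); slen.pop_back();
        kind[i] = 1;
        ++n_return;
        did_return = true;
      }
    }
    if (!did_return) {
      int attempt = 0;
      for (;;) {
        if (++attempt > attempt_cap)
          stop("confinement unsatisfiable at step %d (attempt cap %d)",
               i + 1, attempt_cap);
        double u;
        do {
          u = jump_length(alpha);
        } while (u > u_max);
        double dx, dy, dz;
        iso_dir(dx, dy, dz);
        double px = x[i] + u * dx;
        double py = y[i] + u * dy;
        double pz = z[i] + u * dz;
        double ex = px - cx, ey = py - cy, ez = pz - cz;
        if (ex * ex + ey * ey + ez * ez <= rc_units * rc_units) {
          x[i + 1] = px; y[i + 1] = py; z[i + 1] = pz;
          sx.push_back(u * dx); sy.push_back(u * dy); sz.push_back(u * dz);
          slen.push_back(u);
          kind[i] = 0;
          break;
        }
      }
    }
    depth[i] = (int) slen.size();
    // update running centre of mass with the new vertex
    cx += (x[i + 1] - cx) / (nv + 1);
    cy += (y[i + 1] - cy) / (nv + 1);
    cz += (z[i + 1] - cz) / (nv + 1);
    ++nv;
  }

  NumericMatrix verts(n_steps + 1, 3);
  for (int i = 0; i <= n_steps; ++i) {
    verts(i, 0) = x[i]; verts(i, 1) = y[i]; verts(i, 2) = z[i];
  }
  return List::create(_["vertices"] = verts,
                      _["step_kind"] = kind,
                      _["stack_depth"] = depth,
                      _["n_return"] = n_return);
}
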