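#include <Rcpp.h>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// ---- elementary samplers (Eq. 3-5 of the transport model) ----------------
// Exported individually so the R wrappers and the unit tests exercise the
// exact code paths the tracer uses.

// [[Rcpp::export]]
NumericVector cpp_sample_step(NumericVector xi, double mutot) {
  if (mutot <= 0) stop("mutot must be > 0");
  int n = xi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = -std::log(xi[i]) / mutot;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_azimuth(NumericVector xi) {
  return 2.0 * M_PI * xi;
}

static inline double hg_cos(double xi, double g) {
  if (g == 0.0) return 2.0 * xi - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_sample_deflection(NumericVector xi, double g) {
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)");
  int n = xi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(xi[i], g);
  return out;
}

// Scattering rotation. Near-vertical propagation uses the degenerate
// branch; otherwise the standard direction-cosine rotation, which preserves
// |dir| = 1 (the literal printed form of the general branch does not).
static inline void spin(double* u, double costh, double psi) {
  double sinth = std::sqrt(std::max(0.0, 1.0 - costh * costh));
  double cosp = std::cos(psi), sinp = std::sin(psi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999) {
    u[0] = sinth * cosp;
    u[1] = sinth * sinp;
    u[2] = (uz >= 0 ? costh : -costh);
  } else {
    double s = std::sqrt(1.0 - uz * uz);
    u[0] = sinth * (ux * uz * cosp - uy * sinp) / s + ux * costh;
    u[1] = sinth * (uy * uz * cosp + ux * sinp) / s + uy * costh;
    u[2] = -sinth * cosp * s + uz * costh;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_update_direction(NumericMatrix dir, NumericVector costheta,
                                   NumericVector psi) {
  int n = dir.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double u[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (std::fabs(nrm - 1.0) > 1e-10) stop("direction must be a unit vector");
    spin(u, costheta[i], psi[i]);
    out(i, 0) = u[0];
    out(i, 1) = u[1];
    out(i, 2) = u[2];
  }
  return out;
}

// Deterministic uniform draws from the tracer's own generator, for
// distributional tests that must see the same stream the tracer consumes.
// [[Rcpp::export]]
NumericVector cpp_draw_uniforms(int n, double seed) {
  Xoshiro256 rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.next_unif();
  return out;
}

// ---- full tracer ---------------------------------------------------------
//
// Voxelized hop-drop-spin transport: optical depth is sampled once per hop
// (Eq. 3) and consumed voxel-by-voxel at the local mu_tot, the interaction
// deposits W * mu_a / mu_tot (Eq. 12), and the survivor is deflected by the
// Henyey-Greenstein draw (Eqs. 4-11). Matched boundaries: photons crossing
// the top surface, the lateral/bottom limits, or entering an inactive voxel
// escape and are tallied. Russian roulette below `w_threshold` keeps the
// tracking unbiased; the realized roulette imbalance is tallied so that
// absorbed + escaped + roulette_net == 1 exactly.
//
// [[Rcpp::export]]
List cpp_trace(IntegerVector dims, double d,
               NumericVector mua, NumericVector mus, NumericVector g,
               LogicalVector active,
               double beam_radius, int n_photons, double seed,
               double w_threshold, double p_survival, double specular) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double lx = nx * d, ly = ny * d, lz = nz * d;
  const double x0 = -lx / 2.0, y0 = -ly / 2.0;  // z runs 0..lz downward
  const size_t nvox = (size_t)nx * ny * nz;
  if ((size_t)mua.size() != nvox) stop("property arrays do not match dims");

  std::vector<double> absorbed(nvox, 0.0);
  double refl = 0.0, trans = 0.0, lateral = 0.0;
  double roulette_killed = 0.0, roulette_gain = 0.0;
  const double eps = 1e-9;  // mm push across voxel faces

  Xoshiro256 rng((uint64_t)seed);

  for (int ph = 0; ph < n_photons; ++ph) {
    // top-hat launch: uniform over the beam disk, normal incidence
    double r = beam_radius * std::sqrt(rng.next_unif());
    double phi = 2.0 * M_PI * rng.next_unif();
    double px = r * std::cos(phi), py = r * std::sin(phi), pz = eps;
    double u[3] = {0.0, 0.0, 1.0};
    double W = 1.0;
    if (specular > 0) { refl += W * specular; W *= 1.0 - specular; }

    bool alive = true;
    while (alive) {
      double sleft = -std::log(rng.next_unif());  // dimensionless depth
      bool interacted = false;
      int ivox = -1;
      while (sleft > 0) {
        int ix = (int)std::floor((px - x0) / d);
        int iy = (int)std::floor((py - y0) / d);
        int iz = (int)std::floor(pz / d);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz ||
            !active[ix + (size_t)nx * (iy + (size_t)ny * iz)]) {
          if (pz < 0) refl += W;
          else if (pz >= lz) trans += W;
          else lateral += W;
          alive = false;
          break;
        }
        ivox = ix + (int)((size_t)nx * (iy + (size_t)ny * iz));
        double mt = mua[ivox] + mus[ivox];
        // distance to the voxel boundary along the current direction
        double db = 1e30;
        if (u[0] > 0) db = std::min(db, ((ix + 1) * d + x0 - px) / u[0]);
        else if (u[0] < 0) db = std::min(db, (ix * d + x0 - px) / u[0]);
        if (u[1] > 0) db = std::min(db, ((iy + 1) * d + y0 - py) / u[1]);
        else if (u[1] < 0) db = std::min(db, (iy * d + y0 - py) / u[1]);
        if (u[2] > 0) db = std::min(db, ((iz + 1) * d - pz) / u[2]);
        else if (u[2] < 0) db = std::min(db, (iz * d - pz) / u[2]);
        if (db < 0) db = 0;

        if (mt <= 0.0) {  // transparent voxel: traverse without interaction
          px += u[0] * (db + eps); py += u[1] * (db + eps); pz += u[2] * (db + eps);
          continue;
        }
        double svox = mt * db;
        if (svox >= sleft) {  // interaction inside this voxel
          double step = sleft / mt;
          px += u[0] * step; py += u[1] * step; pz += u[2] * step;
          double dw = W * mua[ivox] / mt;  // Eq. 12
          absorbed[ivox] += dw;
          W -= dw;
          sleft = 0;
          interacted = true;
        } else {  // cross into the neighboring voxel
          px += u[0] * (db + eps); py += u[1] * (db + eps); pz += u[2] * (db + eps);
          sleft -= svox;
        }
      }
      if (!alive || !interacted) break;

      if (W <= 0.0) break;  // fully absorbed (pure absorber)
      if (W < w_threshold) {  // Russian roulette, unbiased termination
        if (rng.next_unif() < p_survival) {
          roulette_gain += W * (1.0 / p_survival - 1.0);
          W /= p_survival;
        } else {
          roulette_killed += W;
          break;
        }
      }
      double psi = 2.0 * M_PI * rng.next_unif();           // Eq. 4
      double costh = hg_cos(rng.next_unif(), g[ivox]);     // Eq. 5
      spin(u, costh, psi);                                 // Eqs. 6-11
    }
    if (ph % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  const double inv_n = 1.0 / (double)n_photons;
  NumericVector amap(nvox);
  for (size_t i = 0; i < nvox; ++i) amap[i] = absorbed[i] * inv_n;
  amap.attr("dim") = dims;
  return List::create(
    _["absorbed"] = amap,
    _["reflected"] = refl * inv_n,
    _["transmitted"] = trans * inv_n,
    _["lateral"] = lateral * inv_n,
    _["roulette_net"] = (roulette_killed - roulette_gain) * inv_n);
}
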