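#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Explicit finite-difference heat diffusion on the voxel grid.
// Face conduction uses the harmonic-mean conductivity 2*k*k_nb/(k + k_nb).
// Boundary modes: 0 = adiabatic top surface + fixed far-field (lateral and
// bottom Dirichlet at T_far), 1 = all faces adiabatic (closed system, used
// for energy-budget verification). Faces onto inactive voxels never conduct.

struct HeatModel {
  int nx, ny, nz;
  size_t nvox;
  double dm;                    // voxel edge, meters
  std::vector<double> gx, gy, gz;   // conductance to +x/+y/+z neighbor, W/K
  std::vector<double> gfar;         // Dirichlet conductance to far field
  std::vector<double> inv_cap;      // 1 / (rho * c_v * V), K/J
  std::vector<char> act;

  HeatModel(IntegerVector dims, double d_mm, NumericVector kcond,
            NumericVector rho, NumericVector cv, LogicalVector active,
            int mode) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    nvox = (size_t)nx * ny * nz;
    dm = d_mm * 1e-3;
    gx.assign(nvox, 0.0); gy.assign(nvox, 0.0); gz.assign(nvox, 0.0);
    gfar.assign(nvox, 0.0); inv_cap.assign(nvox, 0.0); act.assign(nvox, 0);
    const double vol = dm * dm * dm;
    for (size_t i = 0; i < nvox; ++i) {
      act[i] = active[i] ? 1 : 0;
      if (act[i]) inv_cap[i] = 1.0 / (rho[i] * cv[i] * vol);
    }
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          size_t i = ix + (size_t)nx * (iy + (size_t)ny * iz);
          if (!act[i]) continue;
          double ki = kcond[i];
          // internal faces (conductance = harmonic k * area / dist = .. * dm)
          if (ix + 1 < nx) {
            size_t j = i + 1;
            if (act[j]) gx[i] = 2.0 * ki * kcond[j] / (ki + kcond[j]) * dm;
          }
          if (iy + 1 < ny) {
            size_t j = i + nx;
            if (act[j]) gy[i] = 2.0 * ki * kcond[j] / (ki + kcond[j]) * dm;
          }
          if (iz + 1 < nz) {
            size_t j = i + (size_t)nx * ny;
            if (act[j]) gz[i] = 2.0 * ki * kcond[j] / (ki + kcond[j]) * dm;
          }
          if (mode == 0) {
            // fixed far-field at lateral and bottom domain limits; the
            // ghost voxel carries the voxel's own k (harmonic mean = k)
            int nfar = (ix == 0) + (ix == nx - 1) + (iy == 0) + (iy == ny - 1)
                     + (iz == nz - 1);
            gfar[i] = nfar * ki * dm;
          }
        }
  }

  // one explicit update; returns index of first non-finite voxel or -1
  long step(const double* T, double* Tn, const double* src,
            double src_scale, double dt, double t_far) const {
    const size_t sxy = (size_t)nx * ny;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          size_t i = ix + (size_t)nx * iy + sxy * iz;
          if (!act[i]) { Tn[i] = T[i]; continue; }
          double Ti = T[i];
          double flux = 0.0;
          if (ix + 1 < nx) flux += gx[i] * (T[i + 1] - Ti);
          if (ix > 0)      flux += gx[i - 1] * (T[i - 1] - Ti);
          if (iy + 1 < ny) flux += gy[i] * (T[i + nx] - Ti);
          if (iy > 0)      flux += gy[i - nx] * (T[i - nx] - Ti);
          if (iz + 1 < nz) flux += gz[i] * (T[i + sxy] - Ti);
          if (iz > 0)      flux += gz[i - sxy] * (T[i - sxy] - Ti);
          flux += gfar[i] * (t_far - Ti);
          double Tnew = Ti + dt * inv_cap[i] * (flux + src_scale * src[i]);
          if (!std::isfinite(Tnew)) return (long)i;
          Tn[i] = Tnew;
        }
    return -1;
  }
};

static inline bool laser_is_on(double t, double tau_h, double phic) {
  if (phic <= 0) return true;
  double cycle = tau_h * (1.0 + phic);
  double rem = t - std::floor(t / cycle) * cycle;  // t mod cycle
  return rem < tau_h;
}

static void stop_diverged(long bad, int nx, int ny) {
  int iz = (int)(bad / ((size_t)nx * ny));
  long rem = bad % ((long)nx * ny);
  stop("heat solver diverged: non-finite temperature at voxel (%d, %d, %d); "
       "reduce the time step (smaller stability safety factor)",
       (int)(rem % nx) + 1, (int)(rem / nx) + 1, iz + 1);
}

// [[Rcpp::export]]
NumericVector cpp_heat_step(NumericVector temp, IntegerVector dims, double d_mm,
                            NumericVector kcond, NumericVector rho,
                            NumericVector cv, LogicalVector active,
                            NumericVector absorbed, double p_mw, double dt,
                            bool laser_on, int mode, double t_far) {
  HeatModel m(dims, d_mm, kcond, rho, cv, active, mode);
  NumericVector out(temp.size());
  long bad = m.step(REAL(temp), REAL(out), REAL(absorbed),
                    laser_on ? p_mw * 1e-3 : 0.0, dt, t_far);
  if (bad >= 0) stop_diverged(bad, m.nx, m.ny);
  out.attr("dim") = dims;
  return out;
}

// Full treatment run at one power. Snapshots every `steps_per_snap` steps
// (dt is chosen by the caller to divide the snapshot interval exactly).
// [[Rcpp::export]]
List cpp_heat_run(IntegerVector dims, double d_mm, NumericVector kcond,
                  NumericVector rho, NumericVector cv, LogicalVector active,
                  NumericVector absorbed, double p_mw,
                  double tau_h, double phic, double dt, int n_steps,
                  int steps_per_snap, int mode, double t_far,
                  NumericVector t0, IntegerVector monitor_idx,
                  bool keep_fields) {
  HeatModel m(dims, d_mm, kcond, rho, cv, active, mode);
  const size_t nvox = m.nvox;
  std::vector<double> Ta(REAL(t0), REAL(t0) + nvox), Tb(nvox);
  double* T = Ta.data();
  double* Tn = Tb.data();
  const double p_watt = p_mw * 1e-3;

  int n_snap = n_steps / steps_per_snap + 1;
  NumericVector times(n_snap);
  NumericMatrix monitors(n_snap, monitor_idx.size());
  List fields(keep_fields ? n_snap : 0);
  double on_time = 0.0;

  int isnap = 0;
  auto record = [&](double t) {
    times[isnap] = t;
    for (int j = 0; j < monitor_idx.size(); ++j)
      monitors(isnap, j) = T[monitor_idx[j] - 1];
    if (keep_fields) {
      NumericVector f(T, T + nvox);
      f.attr("dim") = dims;
      fields[isnap] = f;
    }
    ++isnap;
  };
  record(0.0);

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    bool on = laser_is_on(t, tau_h, phic);
    if (on) on_time += dt;
    long bad = m.step(T, Tn, REAL(absorbed), on ? p_watt : 0.0, dt, t_far);
    if (bad >= 0) stop_diverged(bad, m.nx, m.ny);
    std::swap(T, Tn);
    if ((s + 1) % steps_per_snap == 0) record((s + 1) * dt);
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector final_field(T, T + nvox);
  final_field.attr("dim") = dims;
  return List::create(_["times"] = times, _["monitors"] = monitors,
                      _["fields"] = fields, _["final"] = final_field,
                      _["on_time"] = on_time, _["dt"] = dt);
}

// One sweep condition: a single unit-power (1 mW) solve whose snapshots are
// rescaled by superposition to every laser power in `powers`, accumulating
// time-averaged apoptosis-band retention over the tumor and band-weighted
// thermal hazard over normal tissue by trapezoidal integration.
// [[Rcpp::export]]
List cpp_heat_sweep(IntegerVector dims, double d_mm, NumericVector kcond,
                    NumericVector rho, NumericVector cv, LogicalVector active,
                    NumericVector absorbed,
                    double tau_h, double phic, double dt, int n_steps,
                    int steps_per_snap, int mode, double t_far, double t_init,
                    NumericVector powers,
                    double band_lo, double band_hi,
                    NumericVector hazard_breaks, NumericVector hazard_weights,
                    IntegerVector tumor_idx, IntegerVector normal_idx,
                    IntegerVector monitor_idx) {
  HeatModel m(dims, d_mm, kcond, rho, cv, active, mode);
  const size_t nvox = m.nvox;
  std::vector<double> Ta(nvox, t_init), Tb(nvox, t_init);
  double* T = Ta.data();
  double* Tn = Tb.data();
  const int np = powers.size();
  const int nb = hazard_breaks.size();

  // thresholds on the unit-power excess u = T - t_init:
  // tumor band membership at power P needs u in [(lo-Ti)/P, (hi-Ti)/P);
  // hazard band k at power P needs u >= (break_k - Ti)/P.
  std::vector<double> thr;
  for (int p = 0; p < np; ++p) {
    if (powers[p] <= 0) continue;
    thr.push_back((band_lo - t_init) / powers[p]);
    thr.push_back((band_hi - t_init) / powers[p]);
    for (int b = 0; b < nb; ++b)
      thr.push_back((hazard_breaks[b] - t_init) / powers[p]);
  }
  std::sort(thr.begin(), thr.end());
  thr.erase(std::unique(thr.begin(), thr.end()), thr.end());
  const int mth = (int)thr.size();
  auto thr_index = [&](double v) {
    return (int)(std::lower_bound(thr.begin(), thr.end(), v) - thr.begin());
  };
  std::vector<int> i_lo(np, 0), i_hi(np, 0);
  std::vector<std::vector<int>> i_brk(np, std::vector<int>(nb, 0));
  for (int p = 0; p < np; ++p) {
    if (powers[p] <= 0) continue;
    i_lo[p] = thr_index((band_lo - t_init) / powers[p]);
    i_hi[p] = thr_index((band_hi - t_init) / powers[p]);
    for (int b = 0; b < nb; ++b)
      i_brk[p][b] = thr_index((hazard_breaks[b] - t_init) / powers[p]);
  }

  const double n_tum = (double)tumor_idx.size();
  const double n_nrm = (double)normal_idx.size();
  std::vector<double> ge_t(mth + 1), ge_n(mth + 1);
  std::vector<double> cnt(mth + 1);

  // counts of voxels with u >= thr[j], via bucketed suffix sums
  auto tally = [&](const IntegerVector& idx, std::vector<double>& ge) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int k = 0; k < idx.size(); ++k) {
      double u = T[idx[k] - 1] - t_init;
      int b = (int)(std::upper_bound(thr.begin(), thr.end(), u) - thr.begin());
      cnt[b] += 1.0;
    }
    ge[mth] = 0.0;
    for (int j = mth - 1; j >= 0; --j) ge[j] = ge[j + 1] + cnt[j + 1];
  };

  NumericVector thetaA(np), thetaH(np);
  std::vector<double> prevA(np, 0.0), prevH(np, 0.0);
  int n_snap = n_steps / steps_per_snap + 1;
  NumericVector times(n_snap);
  NumericMatrix monitors(n_snap, monitor_idx.size());
  double t_prev = 0.0;
  int isnap = 0;

  auto snapshot = [&](double t) {
    tally(tumor_idx, ge_t);
    tally(normal_idx, ge_n);
    for (int p = 0; p < np; ++p) {
      double a = 0.0, h = 0.0;
      if (powers[p] > 0) {
        a = (ge_t[i_lo[p]] - ge_t[i_hi[p]]) / n_tum;
        for (int b = 0; b < nb; ++b) {
          double upper = (b + 1 < nb) ? ge_n[i_brk[p][b + 1]] : 0.0;
          h += hazard_weights[b] * (ge_n[i_brk[p][b]] - upper);
        }
        h /= n_nrm;
      }
      if (t > 0) {
        thetaA[p] += 0.5 * (prevA[p] + a) * (t - t_prev);
        thetaH[p] += 0.5 * (prevH[p] + h) * (t - t_prev);
      }
      prevA[p] = a;
      prevH[p] = h;
    }
    times[isnap] = t;
    for (int j = 0; j < monitor_idx.size(); ++j)
      monitors(isnap, j) = T[monitor_idx[j] - 1];
    ++isnap;
    t_prev = t;
  };
  snapshot(0.0);

  for (int s = 0; s < n_steps; ++s) {
    bool on = laser_is_on(s * dt, tau_h, phic);
    long bad = m.step(T, Tn, REAL(absorbed), on ? 1e-3 : 0.0, dt, t_far);
    if (bad >= 0) stop_diverged(bad, m.nx, m.ny);
    std::swap(T, Tn);
    if ((s + 1) % steps_per_snap == 0) snapshot((s + 1) * dt);
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }

  double span = t_prev;  // == tau_tot
  for (int p = 0; p < np; ++p) { thetaA[p] /= span; thetaH[p] /= span; }
  return List::create(_["thetaA_star"] = thetaA, _["thetaH_star"] = thetaH,
                      _["times"] = times, _["unit_monitors"] = monitors,
                      _["dt"] = dt);
}
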