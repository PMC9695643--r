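#' Parameter grid for the treatment sweep
#'
#' Default grid of the full parametric study: 51 laser powers (0-1000 mW in
#' 20 mW steps), four nanoparticle volume fractions and six cooling-time
#' ratios — 1224 conditions. Reduced grids must be explicit subsets.
#'
#' @param powers_mw laser powers, mW.
#' @param f_v nanoparticle volume fractions.
#' @param phi_c cooling-time ratios.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(powers_mw = seq(0, 1000, by = 20),
                       f_v = c(1e-3, 1e-4, 1e-5, 1e-6),
                       phi_c = c(0, 0.5, 1, 1.5, 2, 2.33)) {
  stopifnot(length(powers_mw) >= 1, length(f_v) >= 1, length(phi_c) >= 1,
            all(powers_mw >= 0), all(f_v > 0), all(f_v < 1), all(phi_c >= 0),
            !anyDuplicated(powers_mw), !anyDuplicated(f_v),
            !anyDuplicated(phi_c))
  structure(list(powers_mw = powers_mw, f_v = f_v, phi_c = phi_c),
            class = "sweep_grid")
}

#' Fraction of treatment time spent cooling
#'
#' For cooling-time ratio `phi_c` the duty cycle spends
#' `phi_c / (1 + phi_c)` of each period with the laser off.
#'
#' @param phi_c cooling-time ratio(s), >= 0.
#' @return cooling fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' cooling_fraction(c(0, 1, 2.33))
cooling_fraction <- function(phi_c) {
  if (any(phi_c < 0)) stop("phi_c must be >= 0", call. = FALSE)
  phi_c / (1 + phi_c)
}

#' Fidelity presets for the sweep
#'
#' Named problem-size presets: `"test"` (1.0 mm voxels, 2e4 photons) keeps
#' unit tests fast; `"acceptance"` (0.5 mm voxels, 2e5 photons) is the
#' scaled-down study fidelity used by the reproduction script.
#'
#' @param name preset name.
#' @return list with `voxel_size` (mm) and `n_photons`.
#' @export
fidelity_preset <- function(name = c("test", "acceptance")) {
  switch(match.arg(name),
         test = list(voxel_size = 1.0, n_photons = 2e4),
         acceptance = list(voxel_size = 0.5, n_photons = 2e5))
}

#' Run the full treatment-condition sweep
#'
#' Drives the whole parametric study: one Monte Carlo absorption map per
#' volume fraction, one unit-power heat solve per (volume fraction,
#' cooling-time ratio), and — because the temperature rise is linear in
#' laser power — metric evaluation for every power by superposition scaling
#' of the unit-power response. Snapshot-level metrics are accumulated by
#' trapezoidal time averaging inside the solver.
#'
#' @param grid a [sweep_grid()].
#' @param voxel_size phantom voxel edge, mm.
#' @param n_photons photon packets per Monte Carlo trace.
#' @param seed base seed; the trace for the i-th volume fraction uses
#'   `seed + i - 1`.
#' @param schedule_total,schedule_heat treatment and heating times, s.
#' @param config a [solver_config()].
#' @param band an [apoptosis_band()].
#' @param weighting a [hazard_weighting()].
#' @param eps hazard floor for the effective ratio.
#' @param blend_surface passed to [build_phantom()].
#' @param verbose print per-stage progress.
#' @return A tibble of class `sweep_result` with one row per condition:
#'   `p_mw`, `f_v`, `phi_c`, `theta_A_star`, `theta_H_star`,
#'   `theta_eff_star`, plus provenance columns (`seed`, `n_photons`,
#'   `voxel_size`, `dt`).
#' @export
run_sweep <- function(grid = sweep_grid(),
                      voxel_size = fidelity_preset("acceptance")$voxel_size,
                      n_photons = fidelity_preset("acceptance")$n_photons,
                      seed = 1,
                      schedule_total = 900, schedule_heat = 30,
                      config = solver_config(),
                      band = apoptosis_band(),
                      weighting = hazard_weighting(),
                      eps = 1e-3,
                      blend_surface = FALSE,
                      verbose = interactive()) {
  stopifnot(inherits(grid, "sweep_grid"))
  say <- function(...) if (verbose) message(...)
  rows <- list()
  for (i in seq_along(grid$f_v)) {
    fv <- grid$f_v[i]
    phantom <- suppressWarnings(
      build_phantom(voxel_size = voxel_size, f_v = fv,
                    blend_surface = blend_surface))
    fv_seed <- seed + i - 1
    say("tracing f_v = ", format(fv), " (", format(n_photons, big.mark = ","),
        " photons, seed ", fv_seed, ")")
    amap <- trace_photons(phantom, n_photons = n_photons, seed = fv_seed)
    st <- resolve_dt(phantom, config)
    n_snaps <- round(schedule_total / config$snapshot_every)
    monitors <- default_monitors(phantom)
    for (pc in grid$phi_c) {
      say("  solving phi_c = ", pc)
      res <- cpp_heat_sweep(
        as.integer(phantom$dims), phantom$voxel_size,
        as.numeric(phantom$k), as.numeric(phantom$rho),
        as.numeric(phantom$c_v), as.logical(phantom$active),
        as.numeric(amap$absorbed),
        schedule_heat, pc, st$dt, n_snaps * st$steps_per_snap,
        st$steps_per_snap, boundary_mode(config), config$t_init,
        config$t_init, as.numeric(grid$powers_mw),
        band$lower, band$upper,
        as.numeric(weighting$breaks), as.numeric(weighting$weights),
        which(phantom$tumor_mask), which(phantom$normal_mask),
        as.integer(monitors))
      rows[[length(rows) + 1]] <- tibble::tibble(
        p_mw = grid$powers_mw, f_v = fv, phi_c = pc,
        theta_A_star = res$thetaA_star,
        theta_H_star = res$thetaH_star,
        theta_eff_star = effective_ratio(res$thetaA_star, res$thetaH_star,
                                         eps),
        seed = fv_seed, n_photons = n_photons,
        voxel_size = voxel_size, dt = res$dt)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sweep_result", class(out)),
            weighting = weighting$name, eps = eps)
}

#' Locate the optimal treatment condition
#'
#' Argmax of the chosen scalar metric over the sweep records. Ties are
#' broken toward lower power, then lower volume fraction, then lower
#' cooling-time ratio (and reported via a message).
#'
#' @param result a [run_sweep()] result (or any data frame with the metric
#'   and condition columns).
#' @param metric `"theta_A_star"` or `"theta_eff_star"`.
#' @return One-row tibble: the optimal condition and its metric values.
#' @export
find_optimum <- function(result, metric = c("theta_A_star",
                                            "theta_eff_star")) {
  metric <- match.arg(metric)
  if (nrow(result) == 0) stop("empty sweep result", call. = FALSE)
  best <- max(result[[metric]])
  top <- result[result[[metric]] == best, , drop = FALSE]
  if (nrow(top) > 1)
    message(nrow(top), " conditions tie at the optimum; ",
            "breaking toward lower p_mw, f_v, phi_c")
  dplyr::arrange(tibble::as_tibble(top), .data$p_mw, .data$f_v, .data$phi_c) |>
    dplyr::slice(1)
}

#' Time a monitored-point trace leaves the apoptosis band upward
#'
#' First time the trace crosses the given threshold from below, located by
#' linear interpolation between snapshots. `NA` if the trace never reaches
#' the threshold.
#'
#' @param times snapshot times, s.
#' @param temps monitored temperatures, degC.
#' @param threshold crossing temperature, degC (default: apoptosis band
#'   upper limit, 50).
#' @return crossing time, s (or `NA`).
#' @export
band_crossing_time <- function(times, temps, threshold = 50) {
  stopifnot(length(times) == length(temps), length(times) >= 2)
  above <- temps >= threshold
  i <- which(!above[-length(above)] & above[-1])
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  times[i] + (threshold - temps[i]) * (times[i + 1] - times[i]) /
    (temps[i + 1] - temps[i])
}
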