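#' Pulsed-laser treatment schedule
#'
#' The laser alternates heating intervals of length `tau_heat` with cooling
#' intervals of length `phi_c * tau_heat` over a total treatment time
#' `tau_total`. `phi_c = 0` is continuous heating.
#'
#' @param phi_c cooling-time ratio (>= 0): cooling interval / heating
#'   interval.
#' @param tau_total total treatment time, s (default 900).
#' @param tau_heat heating interval, s (default 30).
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(phi_c, tau_total = 900, tau_heat = 30) {
  stopifnot(is.numeric(phi_c), length(phi_c) == 1, phi_c >= 0,
            tau_total > 0, tau_heat > 0)
  structure(list(tau_total = tau_total, tau_heat = tau_heat, phi_c = phi_c),
            class = "treatment_schedule")
}

#' Is the laser on at time t?
#'
#' The duty cycle has period `tau_heat * (1 + phi_c)`; the laser is on
#' during the first `tau_heat` seconds of each cycle.
#'
#' @param t time(s) since treatment start, s (>= 0).
#' @param schedule a [treatment_schedule()].
#' @return logical vector.
#' @export
#' @examples
#' laser_on(45, treatment_schedule(phi_c = 1))  # off: cycle is on 0-30, off 30-60
laser_on <- function(t, schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (schedule$phi_c == 0) return(rep(TRUE, length(t)))
  t %% (schedule$tau_heat * (1 + schedule$phi_c)) < schedule$tau_heat
}

#' Stability bound for the explicit heat step
#'
#' The explicit scheme is stable for
#' `dt <= min over voxels of rho * c_v / (2 k (1/dx^2 + 1/dy^2 + 1/dz^2))`
#' (SI units); for the cubic grid this is `rho * c_v * d^2 / (6 k)` per
#' material. Returns `safety` times the minimum over active voxels.
#'
#' @param phantom a [build_phantom()] result.
#' @param safety multiplier in (0, 1].
#' @return time step, s.
#' @export
stable_dt <- function(phantom, safety = 0.5) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            safety > 0, safety <= 1)
  act <- phantom$active
  if (any(phantom$k[act] <= 0) || any(phantom$rho[act] <= 0) ||
      any(phantom$c_v[act] <= 0))
    stop("degenerate thermal properties", call. = FALSE)
  d_m <- phantom$voxel_size * 1e-3
  safety * min((phantom$rho[act] * phantom$c_v[act] * d_m^2) /
                 (6 * phantom$k[act]))
}

#' Heat-solver configuration
#'
#' @param dt time step, s, or `"auto"` (the stability bound times
#'   `safety`, then rounded down so it divides `snapshot_every` exactly).
#' @param snapshot_every snapshot (and metric-sampling) interval, s.
#' @param t_init initial and far-field temperature, degC.
#' @param boundary `"semi-infinite"` (adiabatic top surface, fixed far-field
#'   at the lateral/bottom limits) or `"adiabatic"` (closed system).
#' @param safety stability safety factor in (0, 1].
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = "auto", snapshot_every = 1, t_init = 37,
                          boundary = c("semi-infinite", "adiabatic"),
                          safety = 0.5) {
  boundary <- match.arg(boundary)
  stopifnot(snapshot_every > 0, safety > 0, safety <= 1)
  structure(list(dt = dt, snapshot_every = snapshot_every, t_init = t_init,
                 boundary = boundary, safety = safety),
            class = "solver_config")
}

resolve_dt <- function(phantom, config) {
  dt <- config$dt
  if (identical(dt, "auto")) dt <- stable_dt(phantom, config$safety)
  if (dt > stable_dt(phantom, 1))
    warning("dt exceeds the explicit stability bound", call. = FALSE)
  # align so snapshots fall exactly on step boundaries
  n_sub <- max(1L, as.integer(ceiling(config$snapshot_every / dt - 1e-12)))
  list(dt = config$snapshot_every / n_sub, steps_per_snap = n_sub)
}

boundary_mode <- function(config) {
  if (config$boundary == "semi-infinite") 0L else 1L
}

#' Single explicit heat-diffusion step
#'
#' One explicit finite-difference update of the temperature field: the
#' laser source deposits `A * P / (rho c_v V)` per voxel when on, and face
#' conduction uses the harmonic-mean conductivity
#' `2 k k_nb / (k + k_nb)`. Exposed for verification; [run_treatment()]
#' drives the full integration in compiled code.
#'
#' @param temp temperature array (degC) matching the phantom grid.
#' @param phantom a [build_phantom()] result.
#' @param absorption an [trace_photons()] result (or `NULL` for no source).
#' @param power_mw laser power, mW.
#' @param dt time step, s.
#' @param on logical: laser on during this step.
#' @param config a [solver_config()] (boundary mode and far-field).
#' @return updated temperature array.
#' @export
heat_step <- function(temp, phantom, absorption = NULL, power_mw = 0,
                      dt, on = TRUE, config = solver_config()) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            length(temp) == prod(phantom$dims))
  a <- if (is.null(absorption)) array(0, phantom$dims) else absorption$absorbed
  cpp_heat_step(as.numeric(temp), as.integer(phantom$dims),
                phantom$voxel_size,
                as.numeric(phantom$k), as.numeric(phantom$rho),
                as.numeric(phantom$c_v), as.logical(phantom$active),
                as.numeric(a), power_mw, dt, isTRUE(on),
                boundary_mode(config), config$t_init)
}

new_temperature_series <- function(times, fields, monitors, dims, dt,
                                   power_mw, boundary, on_time) {
  structure(list(times = times, fields = fields, monitors = monitors,
                 dims = dims, dt = dt, power_mw = power_mw,
                 boundary = boundary, on_time = on_time),
            class = "temperature_series")
}

#' Run a full heat-diffusion treatment simulation
#'
#' Integrates the heat-diffusion equation with the Monte Carlo absorption
#' map as source term over the full treatment time, toggling the laser by
#' the duty-cycle schedule. Pure conduction (no perfusion term); properties
#' are temperature-independent, so the temperature rise above the initial
#' field is exactly linear in laser power.
#'
#' @param phantom a [build_phantom()] result.
#' @param absorption an [trace_photons()] result on the same grid.
#' @param schedule a [treatment_schedule()].
#' @param power_mw laser power, mW.
#' @param config a [solver_config()].
#' @param keep_fields store every snapshot field (`TRUE`, needed for the
#'   dose metrics) or only the monitored-point traces (`FALSE`).
#' @param initial optional initial temperature array (default: uniform
#'   `config$t_init`).
#' @param monitors named integer vector of monitored voxel indices
#'   (default: tumor axis at 0.1 mm depth, normal axis at 2.5 mm).
#' @return A `temperature_series`: snapshot times, optional fields,
#'   monitored-point traces, and solver metadata.
#' @export
run_treatment <- function(phantom, absorption, schedule, power_mw,
                          config = solver_config(), keep_fields = TRUE,
                          initial = NULL,
                          monitors = default_monitors(phantom)) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(schedule, "treatment_schedule"))
  if (!is.null(absorption) &&
      !all(absorption$dims == phantom$dims))
    stop("absorption map does not match the phantom grid", call. = FALSE)
  a <- if (is.null(absorption)) array(0, phantom$dims) else absorption$absorbed
  st <- resolve_dt(phantom, config)
  n_snaps <- round(schedule$tau_total / config$snapshot_every)
  n_steps <- n_snaps * st$steps_per_snap
  t0 <- if (is.null(initial)) rep(config$t_init, prod(phantom$dims))
        else as.numeric(initial)
  res <- cpp_heat_run(as.integer(phantom$dims), phantom$voxel_size,
                      as.numeric(phantom$k), as.numeric(phantom$rho),
                      as.numeric(phantom$c_v), as.logical(phantom$active),
                      as.numeric(a), power_mw,
                      schedule$tau_heat, schedule$phi_c,
                      st$dt, n_steps, st$steps_per_snap,
                      boundary_mode(config), config$t_init,
                      t0, as.integer(monitors), isTRUE(keep_fields))
  mon <- tibble::tibble(time_s = res$times)
  labels <- names(monitors)
  if (is.null(labels)) labels <- paste0("point", seq_along(monitors))
  for (j in seq_along(monitors))
    mon[[paste0("T_", labels[j], "_C")]] <- res$monitors[, j]
  new_temperature_series(times = res$times,
                         fields = if (keep_fields) res$fields else NULL,
                         monitors = mon, dims = phantom$dims, dt = res$dt,
                         power_mw = power_mw, boundary = config$boundary,
                         on_time = res$on_time)
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("<temperature_series> ", length(x$times), " snapshots over ",
      max(x$times), " s (dt = ", signif(x$dt, 4), " s, ",
      if (is.null(x$fields)) "monitors only" else "fields kept", ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.temperature_series <- function(x, ...) {
  tidyr::pivot_longer(x$monitors, -"time_s",
                      names_to = "point", values_to = "temperature_C") |>
    dplyr::mutate(point = gsub("^T_|_C$", "", .data$point))
}

#' Export monitored-point traces as CSV
#'
#' Writes the monitored-point temperature traces (`time_s`, `T_tumor_C`,
#' `T_normal_C`, ...) to a CSV file.
#'
#' @param series a `temperature_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_monitor_csv <- function(series, path) {
  stopifnot(inherits(series, "temperature_series"))
  utils::write.csv(series$monitors, path, row.names = FALSE)
  invisible(path)
}
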