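#' Laser source description
#'
#' Top-hat beam at normal incidence: uniform irradiance inside a disk of
#' `beam_radius` centered on the axis, zero outside.
#'
#' @param power_mw laser power, mW (>= 0).
#' @param beam_radius beam radius, mm (> 0).
#' @param wavelength_nm operating wavelength, nm (metadata).
#' @return An object of class `laser_source`.
#' @export
laser_source <- function(power_mw, beam_radius = 5, wavelength_nm = 1064) {
  stopifnot(is.numeric(power_mw), power_mw >= 0, beam_radius > 0)
  structure(list(power_mw = power_mw, beam_radius = beam_radius,
                 wavelength_nm = wavelength_nm, profile = "top-hat"),
            class = "laser_source")
}

#' Sample a photon step length
#'
#' Inverse-transform sample of the free path in a medium of total
#' attenuation `mu_tot`: `S = -log(xi) / mu_tot` (mm), exponentially
#' distributed with mean `1 / mu_tot`.
#'
#' @param xi uniform draws on (0, 1].
#' @param mu_tot total attenuation coefficient, 1/mm (> 0).
#' @return step lengths, mm.
#' @export
sample_step <- function(xi, mu_tot) {
  stopifnot(all(xi > 0), all(xi <= 1))
  if (!is.numeric(mu_tot) || mu_tot <= 0)
    stop("mu_tot must be > 0", call. = FALSE)
  cpp_sample_step(as.numeric(xi), mu_tot)
}

#' Sample a scattering azimuth
#'
#' `psi = 2 * pi * xi`, uniform on `[0, 2 * pi)`.
#'
#' @param xi uniform draws on \[0, 1).
#' @return azimuth angles, radians.
#' @export
sample_azimuth <- function(xi) {
  stopifnot(all(xi >= 0), all(xi <= 1))
  cpp_sample_azimuth(as.numeric(xi))
}

#' Sample a scattering deflection cosine
#'
#' Henyey-Greenstein inverse transform for anisotropy `g > 0`; the
#' isotropic limit `g = 0` gives `cos(theta) = 2 * xi - 1`. The mean of the
#' sampled cosine equals `g`. Results are clamped to `[-1, 1]`.
#'
#' @param xi uniform draws on \[0, 1).
#' @param g anisotropy factor in `[0, 1)`.
#' @return deflection cosines.
#' @export
sample_deflection <- function(xi, g) {
  if (!is.numeric(g) || length(g) != 1 || g < 0 || g >= 1)
    stop("anisotropy g must lie in [0, 1)", call. = FALSE)
  cpp_sample_deflection(as.numeric(xi), g)
}

#' Rotate photon directions by a sampled deflection
#'
#' Applies the scattering rotation to unit direction-cosine vectors: the
#' standard rotation for general directions, and the degenerate
#' near-vertical branch when `|mu_z| > 0.99999`. Preserves unit norm.
#'
#' @param dir numeric matrix (n x 3) of unit direction cosines, or a
#'   length-3 vector.
#' @param cos_theta deflection cosines.
#' @param psi azimuth angles, radians.
#' @return matrix (n x 3) of rotated unit directions.
#' @export
update_direction <- function(dir, cos_theta, psi) {
  if (is.null(dim(dir))) dir <- matrix(dir, ncol = 3)
  n <- nrow(dir)
  cpp_update_direction(dir, rep_len(as.numeric(cos_theta), n),
                       rep_len(as.numeric(psi), n))
}

#' Deposit photon weight at an interaction
#'
#' At each interaction the packet leaves `dW = W * mu_a / mu_tot` in the
#' current voxel and continues with the remainder.
#'
#' @param w packet weight(s) (>= 0).
#' @param mu_a,mu_tot absorption and total attenuation, 1/mm (`mu_tot > 0`).
#' @return list with `deposited` and `weight` (the updated packet weight).
#' @export
deposit_weight <- function(w, mu_a, mu_tot) {
  stopifnot(all(w >= 0))
  if (mu_tot <= 0) stop("mu_tot must be > 0", call. = FALSE)
  dw <- w * mu_a / mu_tot
  list(deposited = dw, weight = w - dw)
}

#' Monte Carlo photon transport through the phantom
#'
#' Traces photon packets launched uniformly over the top-hat beam disk at
#' normal incidence through the voxelized phantom: exponential free paths
#' consumed voxel-by-voxel at the local attenuation, partial absorption at
#' each interaction, Henyey-Greenstein deflection, matched (non-reflecting)
#' boundaries, Russian-roulette termination. The result is the per-voxel
#' fraction of emitted laser energy absorbed, per unit power, plus escape
#' tallies; absorbed + escaped + roulette imbalance sums to 1 exactly.
#'
#' Bit-reproducible for a fixed seed (own deterministic stream; R's RNG
#' state is untouched).
#'
#' @param phantom a [build_phantom()] result.
#' @param n_photons number of photon packets (>= 1).
#' @param seed non-negative integer seed.
#' @param beam_radius beam radius, mm.
#' @param w_threshold roulette trigger weight.
#' @param p_survival roulette survival probability (survivor weight is
#'   divided by it).
#' @param specular optional specular reflection fraction removed at launch
#'   (default 0: matched surface).
#' @return An object of class `absorption_map`: the absorbed-fraction
#'   array and escape/roulette tallies with provenance metadata.
#' @export
trace_photons <- function(phantom, n_photons = 1e5, seed = 1,
                          beam_radius = 5, w_threshold = 1e-4,
                          p_survival = 0.1, specular = 0) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (!is.numeric(n_photons) || n_photons < 1)
    stop("n_photons must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0)
    stop("seed must be a single non-negative number", call. = FALSE)
  res <- cpp_trace(as.integer(phantom$dims), phantom$voxel_size,
                   as.numeric(phantom$mu_a), as.numeric(phantom$mu_s),
                   as.numeric(phantom$g), as.logical(phantom$active),
                   beam_radius, as.integer(n_photons), as.numeric(seed),
                   w_threshold, p_survival, specular)
  structure(list(
    absorbed = res$absorbed,
    reflected = res$reflected, transmitted = res$transmitted,
    lateral = res$lateral, roulette_net = res$roulette_net,
    n_photons = as.integer(n_photons), seed = seed,
    beam_radius = beam_radius, f_v = phantom$f_v,
    voxel_size = phantom$voxel_size, dims = phantom$dims
  ), class = "absorption_map")
}

#' @export
print.absorption_map <- function(x, ...) {
  cat("<absorption_map> ", paste(x$dims, collapse = " x "),
      " voxels, ", format(x$n_photons, big.mark = ","), " photons (seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  absorbed %.4f | reflected %.4f | transmitted %.4f | lateral %.4f\n",
              sum(x$absorbed), x$reflected, x$transmitted, x$lateral))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.absorption_map <- function(x, ...) {
  tibble::tibble(
    absorbed_total = sum(x$absorbed),
    reflected = x$reflected,
    transmitted = x$transmitted,
    lateral = x$lateral,
    roulette_net = x$roulette_net,
    n_photons = x$n_photons,
    seed = x$seed
  )
}
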