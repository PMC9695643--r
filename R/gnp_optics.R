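#' Gold-nanorod specification
#'
#' Describes the nanorod population injected into the tumor. The effective
#' radius is the light-interaction radius enhanced by the localized surface
#' plasmon resonance; the absorption/scattering efficiencies `q_abs`/`q_sca`
#' are dimensionless efficiency factors at the 1064 nm operating wavelength.
#' Defaults are back-derived from the published loaded-tumor optical table
#' (see [derive_efficiencies()]); an electromagnetic solver is out of scope.
#'
#' @param f_v nanoparticle volume fraction in the host medium, in `[0, 1)`.
#' @param q_abs,q_sca absorption and scattering efficiency factors (>= 0).
#' @param r_eff_mm effective radius in mm (default 20 nm = 2e-5 mm).
#' @param aspect_ratio nanorod aspect ratio (metadata; default 6.67).
#' @return An object of class `nanoparticle_spec`.
#' @export
nanoparticle_spec <- function(f_v,
                              q_abs = derive_efficiencies()$q_abs,
                              q_sca = derive_efficiencies()$q_sca,
                              r_eff_mm = 2e-5,
                              aspect_ratio = 6.67) {
  stopifnot(is.numeric(f_v), all(f_v >= 0), all(f_v < 1))
  if (r_eff_mm <= 0) stop("r_eff_mm must be > 0", call. = FALSE)
  if (q_abs < 0 || q_sca < 0) stop("efficiencies must be >= 0", call. = FALSE)
  structure(
    list(f_v = f_v, q_abs = q_abs, q_sca = q_sca,
         r_eff_mm = r_eff_mm, aspect_ratio = aspect_ratio),
    class = "nanoparticle_spec"
  )
}

#' Nanoparticle contribution to the medium's optical coefficients
#'
#' Volume-fraction mixing rule for spherical-equivalent scatterers:
#' `mu_np = 0.75 * f_v * Q / r_eff`, applied to the absorption and
#' scattering efficiencies separately. Linear in `f_v`.
#'
#' @param spec a [nanoparticle_spec()].
#' @return A tibble with columns `f_v`, `mu_a_np`, `mu_s_np` (1/mm).
#' @export
#' @examples
#' nanoparticle_coefficients(nanoparticle_spec(f_v = 1e-4))
nanoparticle_coefficients <- function(spec) {
  stopifnot(inherits(spec, "nanoparticle_spec"))
  tibble::tibble(
    f_v = spec$f_v,
    mu_a_np = 0.75 * spec$f_v * spec$q_abs / spec$r_eff_mm,
    mu_s_np = 0.75 * spec$f_v * spec$q_sca / spec$r_eff_mm
  )
}

#' Optical properties of a medium loaded with nanoparticles
#'
#' The loaded medium's absorption and scattering coefficients are the sums
#' of the host coefficients and the nanoparticle contributions. The
#' anisotropy factor is that of the host medium: the mixing rule addresses
#' only `mu_a` and `mu_s`.
#'
#' @param base a data frame (or one-row tibble) with columns `mu_a`, `mu_s`
#'   and optionally `g` — the host medium.
#' @param np_coeffs output of [nanoparticle_coefficients()] (columns
#'   `mu_a_np`, `mu_s_np`), or a list with those elements.
#' @return A tibble with columns `mu_a`, `mu_s` (and `g` if present in
#'   `base`), one row per row of `np_coeffs`.
#' @export
composite_medium <- function(base, np_coeffs) {
  stopifnot(all(c("mu_a", "mu_s") %in% names(base)),
            all(c("mu_a_np", "mu_s_np") %in% names(np_coeffs)))
  out <- tibble::tibble(
    mu_a = base$mu_a + np_coeffs$mu_a_np,
    mu_s = base$mu_s + np_coeffs$mu_s_np
  )
  if ("f_v" %in% names(np_coeffs)) out <- dplyr::bind_cols(
    tibble::tibble(f_v = np_coeffs$f_v), out)
  if ("g" %in% names(base)) out$g <- base$g
  out
}

#' Back-derive nanorod efficiency factors from the loaded-tumor table
#'
#' The published loaded-tumor coefficients are linear in the volume
#' fraction: `mu(f_v) = mu_host + 0.75 * f_v * Q / r_eff`. `Q` is recovered
#' either by a least-squares slope through the origin over all table
#' columns (default) or from a single named column.
#'
#' @param table a tibble like [tumor_optics_table()].
#' @param base_mu_a,base_mu_s host-tumor coefficients (1/mm).
#' @param r_eff_mm effective radius, mm.
#' @param method `"least_squares"` over all columns or `"single_column"`.
#' @param column which `f_v` column to use for `"single_column"`.
#' @return list with `q_abs`, `q_sca`.
#' @export
#' @examples
#' derive_efficiencies()
#' derive_efficiencies(method = "single_column", column = 1e-3)
derive_efficiencies <- function(table = tumor_optics_table(),
                                base_mu_a = 0.047, base_mu_s = 0.883,
                                r_eff_mm = 2e-5,
                                method = c("least_squares", "single_column"),
                                column = 1e-3) {
  method <- match.arg(method)
  x <- 0.75 * table$f_v / r_eff_mm
  ya <- table$mu_a - base_mu_a
  ys <- table$mu_s - base_mu_s
  if (method == "least_squares") {
    list(q_abs = sum(x * ya) / sum(x * x), q_sca = sum(x * ys) / sum(x * x))
  } else {
    i <- which(table$f_v == column)
    if (length(i) != 1) stop("column not found in table", call. = FALSE)
    list(q_abs = ya[i] / x[i], q_sca = ys[i] / x[i])
  }
}

#' Loaded-tumor optical table for arbitrary volume fractions
#'
#' Applies the mixing model to reconstruct (or extend) the loaded-tumor
#' optical coefficient table.
#'
#' @param f_v volume fractions to tabulate.
#' @param q_abs,q_sca efficiency factors (defaults back-derived).
#' @param base host-tumor row with `mu_a`, `mu_s`, `g`.
#' @inheritParams nanoparticle_spec
#' @return A tibble with columns `f_v`, `mu_a`, `mu_s`, `g`.
#' @export
#' @examples
#' gnp_optical_table(c(1e-3, 1e-4, 1e-5, 1e-6))
gnp_optical_table <- function(f_v,
                              q_abs = derive_efficiencies()$q_abs,
                              q_sca = derive_efficiencies()$q_sca,
                              r_eff_mm = 2e-5,
                              base = skin_layers()[skin_layers()$layer == "tumor", ]) {
  spec <- nanoparticle_spec(f_v = f_v, q_abs = q_abs, q_sca = q_sca,
                            r_eff_mm = r_eff_mm)
  composite_medium(base, nanoparticle_coefficients(spec))
}
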