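#' Thermal and optical properties of the skin layers and tumor
#'
#' Reference property table for the four-layer skin model (epidermis,
#' papillary dermis, reticular dermis, subcutaneous fat) plus the squamous
#' cell carcinoma row. Layer thicknesses stack from the surface downward;
#' the tumor row's thickness is the tumor depth (it is embedded, not
#' stacked). Optical coefficients are for 1064 nm.
#'
#' @param include_tumor include the tumor row (default `TRUE`).
#' @return A tibble with columns `layer`, `thickness_mm`, `c_v` (specific
#'   heat, J/kg/K), `rho` (density, kg/m^3), `k` (thermal conductivity,
#'   W/m/K), `g` (scattering anisotropy), `mu_a` and `mu_s` (absorption and
#'   scattering coefficients, 1/mm).
#' @export
#' @examples
#' skin_layers()
skin_layers <- function(include_tumor = TRUE) {
  tbl <- tibble::tribble(
    ~layer,              ~thickness_mm, ~c_v, ~rho, ~k,    ~g,   ~mu_a, ~mu_s,
    "epidermis",          0.08,  3589, 1200, 0.235, 0.8,  0.4,   45,
    "papillary_dermis",   0.5,   3300, 1200, 0.445, 0.9,  0.38,  30,
    "reticular_dermis",   0.6,   3300, 1200, 0.445, 0.8,  0.48,  25,
    "subcutaneous_fat",  18.82,  2500, 1000, 0.19,  0.75, 0.43,   5,
    "tumor",              2,     3421, 1070, 0.495, 0.8,  0.047,  0.883
  )
  if (!include_tumor) tbl <- tbl[tbl$layer != "tumor", ]
  tbl
}

#' Optical coefficients of the GNP-loaded tumor
#'
#' Published absorption and scattering coefficients of the tumor tissue
#' after gold-nanorod loading, by nanoparticle volume fraction. These are
#' the values used directly by [build_phantom()]; [gnp_optical_table()]
#' reconstructs them from the mixing model as a closure check.
#'
#' @return A tibble with columns `f_v` (volume fraction), `mu_a`, `mu_s`
#'   (1/mm).
#' @export
#' @examples
#' tumor_optics_table()
tumor_optics_table <- function() {
  tibble::tibble(
    f_v  = c(1e-3, 1e-4, 1e-5, 1e-6),
    mu_a = c(557.41, 55.78, 5.62, 0.60),
    mu_s = c(118.58, 12.65, 2.06, 1.00)
  )
}
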