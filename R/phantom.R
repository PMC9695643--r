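#' Build the voxelized skin + tumor phantom
#'
#' Voxelizes the treatment geometry on a Cartesian grid: a cylindrical
#' tissue domain of radius 15 mm and depth 20 mm containing four stacked
#' skin layers (cumulative depth boundaries at 0.08, 0.58, 1.18 and
#' 20.0 mm) and a tumor cylinder of radius 5 mm and depth 2 mm whose top
#' face sits 0.1 mm below the surface on the beam axis. `z` increases
#' downward from the surface; voxel `i` along an axis owns the half-open
#' interval `[i*d, (i+1)*d)` and takes the region containing its center.
#' Voxels whose centers fall outside the domain radius are inactive: no
#' photon transport into them and no conduction across them.
#'
#' Tumor voxels carry the loaded-tumor optical coefficients selected by
#' `f_v` (published table values) and always the unloaded tumor thermal
#' properties. `f_v = "none"` (or `0`) keeps the unloaded tumor optics.
#'
#' The epidermis (0.08 mm) is thinner than practical voxel sizes; by
#' default a sub-voxel epidermis triggers a warning and the surface voxel
#' takes the properties of the layer containing its center.
#' `blend_surface = TRUE` instead assigns the non-tumor surface voxels
#' thickness-weighted averages of every layer slice inside them.
#'
#' @param voxel_size cubic voxel edge, mm (> 0).
#' @param f_v tumor nanoparticle volume fraction: one of 1e-3, 1e-4, 1e-5,
#'   1e-6, or `"none"`/`0` for the unloaded tumor.
#' @param layers layer property table, see [skin_layers()].
#' @param tumor_optics loaded-tumor optical table, see
#'   [tumor_optics_table()].
#' @param blend_surface blend sub-voxel surface layers (default `FALSE`).
#' @param domain_shape `"cylinder"` (voxels with centers outside
#'   `domain_radius` are inactive) or `"box"` (all voxels active; useful
#'   for slab verification problems).
#' @param domain_radius,domain_depth domain cylinder, mm.
#' @param tumor_radius,tumor_depth,tumor_top tumor cylinder, mm.
#' @return An object of class `tissue_phantom`: voxel arrays of region id,
#'   optical (`mu_a`, `mu_s`, `g`) and thermal (`k`, `rho`, `c_v`)
#'   properties, the active/tumor/normal masks, and grid metadata.
#' @export
#' @examples
#' ph <- build_phantom(voxel_size = 1, f_v = 1e-6)
#' ph
build_phantom <- function(voxel_size = 0.5, f_v = 1e-6,
                          layers = skin_layers(),
                          tumor_optics = tumor_optics_table(),
                          blend_surface = FALSE,
                          domain_shape = c("cylinder", "box"),
                          domain_radius = 15, domain_depth = 20,
                          tumor_radius = 5, tumor_depth = 2,
                          tumor_top = 0.1) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive scalar (mm)", call. = FALSE)
  domain_shape <- match.arg(domain_shape)

  skin <- layers[layers$layer != "tumor", ]
  tumor_row <- layers[layers$layer == "tumor", ]
  stopifnot(nrow(tumor_row) == 1, nrow(skin) >= 1)
  if (voxel_size > min(skin$thickness_mm) && !blend_surface)
    warning("voxel_size ", voxel_size, " mm exceeds the thinnest layer (",
            min(skin$thickness_mm), " mm): the epidermis is sub-voxel; ",
            "surface voxels take the layer at their center ",
            "(set blend_surface = TRUE to thickness-average)", call. = FALSE)

  # tumor optics by volume fraction
  if (identical(f_v, "none") || identical(f_v, 0)) {
    f_v <- 0
    t_opt <- tumor_row[, c("mu_a", "mu_s")]
  } else {
    i <- which(abs(tumor_optics$f_v - f_v) < 1e-12 * f_v)
    if (length(i) != 1)
      stop("f_v must be one of ", paste(format(tumor_optics$f_v), collapse = ", "),
           " or \"none\"", call. = FALSE)
    t_opt <- tumor_optics[i, c("mu_a", "mu_s")]
  }

  d <- voxel_size
  nx <- ny <- as.integer(round(2 * domain_radius / d))
  nz <- as.integer(round(domain_depth / d))
  if (abs(nx * d - 2 * domain_radius) > d || abs(nz * d - domain_depth) > d)
    stop("voxel_size must divide the domain extents to within one voxel",
         call. = FALSE)
  xc <- -domain_radius + (seq_len(nx) - 0.5) * d
  zc <- (seq_len(nz) - 0.5) * d

  # region ids: 1..n_layers skin (top down), n_layers + 1 = tumor
  zb <- cumsum(skin$thickness_mm)
  layer_of_z <- findInterval(zc, c(0, zb[-length(zb)]))
  region <- array(rep(layer_of_z, each = nx * ny), dim = c(nx, ny, nz))
  r2 <- outer(xc^2, xc^2, "+")                    # center radius^2 in x-y
  in_domain <- if (domain_shape == "box") r2 >= 0 else r2 <= domain_radius^2
  active <- array(rep(in_domain, nz), dim = c(nx, ny, nz))
  in_disk <- r2 <= tumor_radius^2
  tumor_id <- nrow(skin) + 1L
  tz <- zc >= tumor_top & zc < tumor_top + tumor_depth
  tumor_mask <- array(as.vector(outer(as.vector(in_disk), tz, "&")),
                      dim = c(nx, ny, nz)) & active
  region[tumor_mask] <- tumor_id

  look <- function(vals_skin, val_tumor) {
    lut <- c(vals_skin, val_tumor)
    array(lut[region], dim = dim(region))
  }
  mu_a <- look(skin$mu_a, t_opt$mu_a)
  mu_s <- look(skin$mu_s, t_opt$mu_s)
  g    <- look(skin$g, tumor_row$g)
  k    <- look(skin$k, tumor_row$k)
  rho  <- look(skin$rho, tumor_row$rho)
  c_v  <- look(skin$c_v, tumor_row$c_v)

  if (blend_surface) {
    # thickness-weighted properties for the non-tumor surface voxels
    seg <- pmax(0, pmin(zb, d) - pmin(c(0, zb[-length(zb)]), d))
    w <- seg / sum(seg)
    surf <- region[, , 1] != tumor_id & active[, , 1]
    blend <- function(arr, vals) {
      sl <- arr[, , 1]; sl[surf] <- sum(w * vals); arr[, , 1] <- sl; arr
    }
    mu_a <- blend(mu_a, skin$mu_a); mu_s <- blend(mu_s, skin$mu_s)
    g <- blend(g, skin$g); k <- blend(k, skin$k)
    rho <- blend(rho, skin$rho); c_v <- blend(c_v, skin$c_v)
  }

  structure(list(
    dims = c(nx, ny, nz), voxel_size = d,
    region = region,
    region_labels = c(skin$layer, "tumor"),
    mu_a = mu_a, mu_s = mu_s, g = g, k = k, rho = rho, c_v = c_v,
    active = active,
    tumor_mask = tumor_mask,
    normal_mask = active & !tumor_mask,
    f_v = f_v, blend_surface = blend_surface,
    domain_radius = domain_radius, domain_depth = domain_depth,
    tumor_radius = tumor_radius, tumor_depth = tumor_depth,
    tumor_top = tumor_top,
    layers = layers
  ), class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", paste(x$dims, collapse = " x "),
      " voxels @ ", x$voxel_size, " mm (f_v = ",
      if (x$f_v == 0) "none" else format(x$f_v), ")\n", sep = "")
  cat("  tumor voxels: ", sum(x$tumor_mask),
      "  normal voxels: ", sum(x$normal_mask),
      "  inactive: ", sum(!x$active), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.tissue_phantom <- function(x, ...) {
  vv <- x$voxel_size^3
  counts <- table(factor(x$region[x$active],
                         levels = seq_along(x$region_labels),
                         labels = x$region_labels))
  tibble::tibble(
    region = names(counts),
    n_voxels = as.integer(counts),
    volume_mm3 = as.numeric(counts) * vv
  )
}

#' Voxel index of a point
#'
#' Linear (1-based) index of the voxel owning the point `(x, y, z)` in mm,
#' with the origin on the beam axis at the skin surface and z downward.
#' Used to place monitoring points.
#'
#' @param phantom a [build_phantom()] result.
#' @param point numeric length-3, mm.
#' @return integer linear voxel index.
#' @export
voxel_index <- function(phantom, point) {
  d <- phantom$voxel_size
  nx <- phantom$dims[1]; ny <- phantom$dims[2]; nz <- phantom$dims[3]
  ix <- floor((point[1] + phantom$domain_radius) / d)
  iy <- floor((point[2] + phantom$domain_radius) / d)
  iz <- floor(point[3] / d)
  if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
    stop("point lies outside the phantom", call. = FALSE)
  as.integer(1 + ix + nx * (iy + ny * iz))
}

default_monitors <- function(phantom) {
  c(tumor = voxel_index(phantom, c(0, 0, 0.1)),
    normal = voxel_index(phantom, c(0, 0, 2.5)))
}

#' Synthetic temperature-field specification
#'
#' Describes a deterministic test field: a uniform baseline plus a
#' sharp-edged spherical hot spot whose amplitude follows a given temporal
#' profile. Used to unit-test the dose metrics against hand-computable
#' ground truth; it emulates no physics.
#'
#' @param peak hot-spot temperature at profile scale 1, degC.
#' @param baseline background temperature, degC (`baseline <= peak`).
#' @param center hot-spot center `(x, y, z)`, mm.
#' @param radius hot-spot radius, mm (> 0).
#' @param profile data frame with columns `time` (s) and `scale`
#'   (amplitude multipliers).
#' @return An object of class `synth_field_spec`.
#' @export
synth_field_spec <- function(peak = 45, baseline = 37,
                             center = c(0, 0, 1.1), radius = 5.2,
                             profile = tibble::tibble(time = c(0, 450, 900),
                                                      scale = c(1, 1, 1))) {
  if (baseline > peak) stop("baseline must not exceed peak", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  stopifnot(all(c("time", "scale") %in% names(profile)),
            !is.unsorted(profile$time, strictly = TRUE))
  structure(list(peak = peak, baseline = baseline, center = center,
                 radius = radius, profile = profile),
            class = "synth_field_spec")
}

#' Generate a synthetic temperature series
#'
#' Realizes a [synth_field_spec()] on a phantom grid: voxels whose centers
#' lie within the hot-spot sphere sit at
#' `baseline + scale(t) * (peak - baseline)`, all others at `baseline`.
#' Deterministic; returns the same `temperature_series` container the heat
#' solver produces, so every metric can be exercised with known ground
#' truth.
#'
#' @param spec a [synth_field_spec()].
#' @param phantom a [build_phantom()] result.
#' @return A `temperature_series` object.
#' @export
synth_temperature_series <- function(spec, phantom) {
  stopifnot(inherits(spec, "synth_field_spec"),
            inherits(phantom, "tissue_phantom"))
  d <- phantom$voxel_size
  nx <- phantom$dims[1]; ny <- phantom$dims[2]; nz <- phantom$dims[3]
  xc <- -phantom$domain_radius + (seq_len(nx) - 0.5) * d
  zc <- (seq_len(nz) - 0.5) * d
  dist2 <- outer(outer((xc - spec$center[1])^2, (xc - spec$center[2])^2, "+"),
                 (zc - spec$center[3])^2, "+")
  inside <- dist2 <= spec$radius^2
  fields <- lapply(spec$profile$scale, function(s) {
    f <- array(spec$baseline, dim = phantom$dims)
    f[inside] <- spec$baseline + s * (spec$peak - spec$baseline)
    f
  })
  midx <- default_monitors(phantom)
  monitors <- tibble::tibble(
    time_s = spec$profile$time,
    T_tumor_C = vapply(fields, function(f) f[midx["tumor"]], numeric(1)),
    T_normal_C = vapply(fields, function(f) f[midx["normal"]], numeric(1))
  )
  new_temperature_series(times = spec$profile$time, fields = fields,
                         monitors = monitors, dims = phantom$dims,
                         dt = NA_real_, power_mw = NA_real_,
                         boundary = "synthetic", on_time = NA_real_)
}
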