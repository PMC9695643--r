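# Shared fixtures. Everything is generated in code; coarse grids and small
# photon counts keep the default run fast.

tiny_phantom <- function(voxel_size = 1, f_v = 1e-6, ...) {
  suppressWarnings(build_phantom(voxel_size = voxel_size, f_v = f_v, ...))
}

# homogeneous box phantom: one material everywhere (the "tumor" rows carry
# identical properties so region labeling is irrelevant to the physics)
homogeneous_phantom <- function(voxel_size = 1, depth = 10, half_width = 5,
                                mu_a = 1, mu_s = 0, g = 0,
                                k = 0.5, rho = 1000, c_v = 4000) {
  lay <- tibble::tibble(
    layer = c("medium", "tumor"),
    thickness_mm = c(depth, 1),
    c_v = c_v, rho = rho, k = k, g = g, mu_a = mu_a, mu_s = mu_s
  )
  suppressWarnings(build_phantom(
    voxel_size = voxel_size, f_v = "none", layers = lay,
    domain_shape = "box", domain_radius = half_width, domain_depth = depth,
    tumor_radius = voxel_size / 2, tumor_depth = voxel_size,
    tumor_top = depth - voxel_size
  ))
}

# absorbed-energy totals for conservation checks
total_weight <- function(am) {
  sum(am$absorbed) + am$reflected + am$transmitted + am$lateral +
    am$roulette_net
}

# thermal energy of a field (J), active voxels only
thermal_energy <- function(field, phantom) {
  v <- (phantom$voxel_size * 1e-3)^3
  sum((phantom$rho * phantom$c_v * v * field)[phantom$active])
}
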