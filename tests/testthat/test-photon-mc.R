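test_that("step sampling inverts the exponential free-path law", {
  expect_equal(sample_step(1, 2.5), 0)
  # tumor at the lightest loading: mu_tot = 0.60 + 1.00
  expect_equal(sample_step(0.5, 1.6), log(2) / 1.6, tolerance = 1e-12)
  xi <- phototherm:::cpp_draw_uniforms(2e5, 42)
  s <- sample_step(xi, 1.6)
  expect_equal(mean(s), 1 / 1.6, tolerance = 0.01)
  expect_error(sample_step(0.5, 0), "mu_tot")
  expect_error(sample_step(0.5, -1), "mu_tot")
})

test_that("azimuth sampling is uniform on [0, 2*pi)", {
  expect_equal(sample_azimuth(0), 0)
  expect_equal(sample_azimuth(0.25), pi / 2)
  xi <- phototherm:::cpp_draw_uniforms(1e6, 7)
  ks <- suppressWarnings(stats::ks.test(sample_azimuth(xi), "punif",
                                        0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("deflection sampling matches the Henyey-Greenstein law", {
  # closed-form spot values
  expect_equal(sample_deflection(0.75, 0), 0.5)
  expect_equal(sample_deflection(0.5, 0.8),
               (1 / 1.6) * (1.64 - 0.36^2), tolerance = 1e-12)
  # first moment equals g at the anisotropies used by the tissue layers
  for (g in c(0.75, 0.8, 0.9)) {
    xi <- phototherm:::cpp_draw_uniforms(1e6, 100 + round(100 * g))
    ct <- sample_deflection(xi, g)
    expect_true(all(ct >= -1 & ct <= 1))
    se <- stats::sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
  # isotropic limit: cos(theta) uniform on [-1, 1]
  xi <- phototherm:::cpp_draw_uniforms(1e6, 11)
  ks <- suppressWarnings(stats::ks.test(sample_deflection(xi, 0), "punif",
                                        -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_deflection(0.5, 1), "g")
  expect_error(sample_deflection(0.5, -0.1), "g")
})

test_that("direction updates rotate correctly and preserve unit norm", {
  # vertical packet deflected by 90 degrees at psi = 0 -> x axis
  expect_equal(update_direction(c(0, 0, 1), 0, 0)[1, ], c(1, 0, 0))
  # zero deflection is the identity
  expect_equal(update_direction(c(1, 0, 0), 1, 2.3)[1, ], c(1, 0, 0),
               tolerance = 1e-12)
  # norm preservation under random rotations (this is the property the
  # literal printed general-branch formula fails)
  set.seed(1)
  n <- 2000
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  out <- update_direction(dir, stats::runif(n, -1, 1),
                          stats::runif(n, 0, 2 * pi))
  expect_lt(max(abs(sqrt(rowSums(out^2)) - 1)), 1e-12)
  expect_error(update_direction(c(1, 1, 0), 0.5, 0), "unit")
})

test_that("weight deposition follows the albedo split and is monotone", {
  # lightest-loading tumor: mu_a/mu_tot = 0.6/1.6
  d <- deposit_weight(1, 0.6, 1.6)
  expect_equal(d$deposited, 0.375)
  expect_equal(d$weight, 0.625)
  expect_equal(deposit_weight(0.7, 0, 2)$deposited, 0)
  w <- 1
  for (i in 1:50) {
    d <- deposit_weight(w, 0.6, 1.6)
    expect_lte(d$weight, w)
    expect_gte(d$weight, 0)
    w <- d$weight
  }
})

test_that("traced energy is conserved and runs are reproducible", {
  ph <- tiny_phantom(voxel_size = 1, f_v = 1e-5)
  a1 <- trace_photons(ph, n_photons = 5000, seed = 9)
  a2 <- trace_photons(ph, n_photons = 5000, seed = 9)
  expect_identical(a1$absorbed, a2$absorbed)
  expect_lt(abs(total_weight(a1) - 1), 1e-9)
  expect_true(all(a1$absorbed >= 0))
  # conservation holds for a different phantom and seed
  a3 <- trace_photons(tiny_phantom(voxel_size = 1, f_v = 1e-3),
                      n_photons = 5000, seed = 123)
  expect_lt(abs(total_weight(a3) - 1), 1e-9)
  expect_error(trace_photons(ph, n_photons = 0), "n_photons")
  expect_error(trace_photons(ph, seed = NA), "seed")
})

test_that("absorbing-only slab reproduces the Beer-Lambert depth profile", {
  ph <- homogeneous_phantom(voxel_size = 0.5, depth = 10, half_width = 6,
                            mu_a = 1, mu_s = 0, g = 0)
  am <- trace_photons(ph, n_photons = 1e5, seed = 1, beam_radius = 3)
  prof <- apply(am$absorbed, 3, sum)
  zedges <- seq(0, 10, by = 0.5)
  expected <- exp(-zedges[-length(zedges)]) - exp(-zedges[-1])
  over3mfp <- zedges[-length(zedges)] < 3
  # profile agreement within 2% (rms of per-bin relative deviations; the
  # per-bin Monte Carlo noise at 1e5 photons is ~1.7% in the deepest bin)
  rel <- prof[over3mfp] / expected[over3mfp] - 1
  expect_lt(sqrt(mean(rel^2)), 0.02)
  # and each bin individually within its own 3-sigma counting error
  n <- am$n_photons
  sigma <- sqrt((1 - expected) / (n * expected))[over3mfp]
  expect_true(all(abs(rel) < 3 * sigma))
})

test_that("two-voxel absorbing column matches the exact decay integral", {
  # quadrature-free closed form of the same integral the tracer estimates
  ph <- homogeneous_phantom(voxel_size = 1, depth = 2, half_width = 2,
                            mu_a = 1, mu_s = 0, g = 0)
  am <- trace_photons(ph, n_photons = 1e5, seed = 4, beam_radius = 1.5)
  a_z <- apply(am$absorbed, 3, sum)
  exact <- c(1 - exp(-1), exp(-1) - exp(-2))
  # within 3 standard errors of the binomial counting noise
  se <- sqrt(exact * (1 - exact) / am$n_photons)
  expect_true(all(abs(a_z - exact) < 3 * se))
  se_t <- sqrt(exp(-2) * (1 - exp(-2)) / am$n_photons)
  expect_lt(abs(am$transmitted - exp(-2)), 3 * se_t)
})

test_that("transparent regions pass photons through without interaction", {
  ph <- homogeneous_phantom(voxel_size = 1, depth = 4, half_width = 2,
                            mu_a = 0, mu_s = 0, g = 0)
  am <- trace_photons(ph, n_photons = 1000, seed = 5, beam_radius = 1)
  expect_equal(sum(am$absorbed), 0)
  expect_equal(am$transmitted, 1)
})
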