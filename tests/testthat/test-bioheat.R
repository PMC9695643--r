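test_that("laser duty cycle toggles by the cooling-time ratio", {
  expect_true(all(laser_on(seq(0, 900, by = 7), treatment_schedule(0))))
  s1 <- treatment_schedule(phi_c = 1)
  expect_true(laser_on(29.9, s1))
  expect_false(laser_on(45, s1))   # cycle 60 s: on 0-30, off 30-60
  expect_true(laser_on(60, s1))
  expect_error(laser_on(-1, s1), "non-negative")
  # cooling fraction of the cycle
  expect_equal(cooling_fraction(0), 0)
  expect_equal(cooling_fraction(1), 0.5)
  expect_equal(cooling_fraction(2.33), 2.33 / 3.33)
  sch <- treatment_schedule(phi_c = 2.33)
  tgrid <- seq(0, 99.9 * 100, by = 0.01); tgrid <- tgrid[-length(tgrid)]
  expect_equal(mean(!laser_on(tgrid, sch)), 2.33 / 3.33, tolerance = 1e-3)
})

test_that("stability bound follows the explicit-scheme closed form", {
  ph <- homogeneous_phantom(voxel_size = 1, k = 0.5, rho = 1000, c_v = 4000)
  expect_equal(stable_dt(ph, safety = 1), 1000 * 4000 * 1e-6 / (6 * 0.5),
               tolerance = 1e-12)
  ph2 <- homogeneous_phantom(voxel_size = 0.5, k = 0.5, rho = 1000,
                             c_v = 4000)
  expect_equal(stable_dt(ph2, safety = 1), stable_dt(ph, safety = 1) / 4)
  # multi-material phantom: the minimum over per-material bounds
  ph3 <- tiny_phantom(voxel_size = 1)
  lay <- skin_layers()
  per_mat <- lay$rho * lay$c_v * 1e-6 / (6 * lay$k)
  present <- unique(ph3$region[ph3$active])
  expect_equal(stable_dt(ph3, safety = 1), min(per_mat[present]))
  lay_bad <- lay; lay_bad$k[2] <- 0
  expect_error(stable_dt(tiny_phantom(layers = lay_bad)), "degenerate")
})

test_that("a single step conducts by the harmonic-mean flux and conserves energy", {
  # two-voxel closed system at 38/36 degC
  ph <- homogeneous_phantom(voxel_size = 1, depth = 2, half_width = 0.5,
                            k = 0.5, rho = 1000, c_v = 4000)
  expect_equal(ph$dims, c(1, 1, 2))
  cfg <- solver_config(boundary = "adiabatic")
  t1 <- heat_step(array(c(38, 36), ph$dims), ph, NULL, 0, dt = 0.1,
                  config = cfg)
  expect_equal(t1[1, 1, 1] - 38, -0.1 * 0.5 * 1e-3 * 2 / (1000 * 4000 * 1e-9))
  expect_equal(sum(t1), 74)  # symmetric exchange
  # uniform field with no source stays put
  tu <- heat_step(array(37, ph$dims), ph, NULL, 0, dt = 0.1, config = cfg)
  expect_true(all(tu == 37))
})

test_that("adiabatic runs bank exactly the absorbed power times on-time", {
  ph <- tiny_phantom(voxel_size = 1)
  am <- trace_photons(ph, n_photons = 2000, seed = 2)
  cfg <- solver_config(boundary = "adiabatic")
  sch <- treatment_schedule(phi_c = 1, tau_total = 60)
  ts <- run_treatment(ph, am, sch, power_mw = 500, config = cfg,
                      keep_fields = TRUE)
  gained <- thermal_energy(ts$fields[[length(ts$fields)]] - 37, ph)
  expected <- 500e-3 * sum(am$absorbed) * ts$on_time
  expect_equal(gained, expected, tolerance = 1e-6)
  expect_equal(ts$on_time, 30)
})

test_that("temperature rise is homogeneous of degree one in laser power", {
  ph <- tiny_phantom(voxel_size = 1)
  am <- trace_photons(ph, n_photons = 2000, seed = 3)
  sch <- treatment_schedule(phi_c = 0.5, tau_total = 30)
  t1 <- run_treatment(ph, am, sch, power_mw = 100, keep_fields = TRUE)
  t2 <- run_treatment(ph, am, sch, power_mw = 200, keep_fields = TRUE)
  f1 <- t1$fields[[length(t1$fields)]] - 37
  f2 <- t2$fields[[length(t2$fields)]] - 37
  expect_equal(f2, 2 * f1, tolerance = 1e-8)
  # zero power: every snapshot stays at the initial field
  t0 <- run_treatment(ph, am, sch, power_mw = 0, keep_fields = TRUE)
  expect_true(all(vapply(t0$fields, function(f) all(f[ph$active] == 37),
                         logical(1))))
})

test_that("an instantaneous point deposit spreads as the analytic heat kernel", {
  ph <- homogeneous_phantom(voxel_size = 0.5, depth = 15.5, half_width = 7.75,
                            k = 0.5, rho = 1000, c_v = 4000)
  cfg <- solver_config(boundary = "adiabatic", snapshot_every = 2)
  d_m <- 0.5e-3
  alpha <- 0.5 / (1000 * 4000)
  # delta: one central voxel raised by 1000 K
  init <- array(0, ph$dims)
  ctr <- c(16, 16, 16)
  init[ctr[1], ctr[2], ctr[3]] <- 1000
  sch <- treatment_schedule(phi_c = 0, tau_total = 10)
  ts <- run_treatment(ph, NULL, sch, power_mw = 0, config = cfg,
                      keep_fields = TRUE, initial = init)
  q <- 1000 * d_m^3  # K m^3 of the initial deposit
  for (tt in c(6, 10)) {
    f <- ts$fields[[which(ts$times == tt)]]
    idx <- as.matrix(expand.grid(i = 10:22, j = 10:22, k = 10:22))
    r2 <- colSums((t(idx) - ctr)^2) * d_m^2
    kernel <- q / (4 * pi * alpha * tt)^1.5 * exp(-r2 / (4 * alpha * tt))
    peak <- q / (4 * pi * alpha * tt)^1.5
    expect_lt(max(abs(f[idx] - kernel)) / peak, 0.03)
  }
})

test_that("without a source the extrema never exceed the initial extrema", {
  ph <- tiny_phantom(voxel_size = 1)
  set.seed(5)
  init <- array(37, ph$dims)
  init[ph$active] <- stats::runif(sum(ph$active), 36, 45)
  cfg <- solver_config(boundary = "adiabatic")
  ts <- run_treatment(ph, NULL, treatment_schedule(0, tau_total = 20), 0,
                      config = cfg, keep_fields = TRUE, initial = init)
  rng0 <- range(init[ph$active])
  for (f in ts$fields) {
    expect_gte(min(f[ph$active]), rng0[1] - 1e-12)
    expect_lte(max(f[ph$active]), rng0[2] + 1e-12)
  }
})

test_that("solver failure modes are reported", {
  ph <- tiny_phantom(voxel_size = 1)
  am <- trace_photons(ph, n_photons = 1000, seed = 1)
  ph2 <- tiny_phantom(voxel_size = 0.5)
  expect_error(run_treatment(ph2, am, treatment_schedule(0), 100),
               "does not match")
  # a wildly unstable step diverges with a located voxel
  cfg <- solver_config(dt = 50, snapshot_every = 50)
  expect_condition(run_treatment(ph, am, treatment_schedule(0, tau_total = 200),
                                 1000, config = cfg), class = "condition")
})
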