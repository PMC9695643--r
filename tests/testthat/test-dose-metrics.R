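test_that("apoptosis ratio counts the in-band tumor volume fraction", {
  ph <- tiny_phantom(voxel_size = 1)
  f <- array(37, ph$dims)
  expect_equal(apoptosis_ratio(f, ph$tumor_mask), 0)
  f[ph$tumor_mask] <- 45
  expect_equal(apoptosis_ratio(f, ph$tumor_mask), 1)
  # half the tumor voxels heated: ratio follows the direct count
  idx <- which(ph$tumor_mask)
  half <- idx[seq_len(floor(length(idx) / 2))]
  f2 <- array(37, ph$dims)
  f2[half] <- 45
  expect_equal(apoptosis_ratio(f2, ph$tumor_mask),
               length(half) / length(idx))
  # permuting labels inside the mask leaves the ratio unchanged
  set.seed(1)
  f3 <- f2
  f3[idx] <- f2[sample(idx)]
  expect_equal(apoptosis_ratio(f3, ph$tumor_mask),
               apoptosis_ratio(f2, ph$tumor_mask))
  # band is half-open: 50 degC is necrotic, not apoptotic
  f4 <- array(37, ph$dims); f4[ph$tumor_mask] <- 50
  expect_equal(apoptosis_ratio(f4, ph$tumor_mask), 0)
  f4[ph$tumor_mask] <- 43
  expect_equal(apoptosis_ratio(f4, ph$tumor_mask), 1)
  expect_error(apoptosis_ratio(f, array(FALSE, ph$dims)), "empty")
})

test_that("thermal hazard weights temperature bands over normal tissue", {
  ph <- tiny_phantom(voxel_size = 1)
  f <- array(37, ph$dims)
  expect_equal(thermal_hazard(f, ph$normal_mask), 0)
  f[ph$normal_mask] <- 45
  expect_equal(thermal_hazard(f, ph$normal_mask), 1)
  # half at 52 (weight 2), half at 37 (weight 0)
  idx <- which(ph$normal_mask)
  f2 <- array(37, ph$dims)
  f2[idx[seq_len(floor(length(idx) / 2))]] <- 52
  expect_equal(thermal_hazard(f2, ph$normal_mask),
               2 * floor(length(idx) / 2) / length(idx))
  # monotone under pointwise heating with non-decreasing weights
  set.seed(2)
  base <- array(37, ph$dims)
  base[idx] <- stats::runif(length(idx), 37, 55)
  hotter <- base; hotter[idx] <- base[idx] + stats::runif(length(idx), 0, 5)
  expect_gte(thermal_hazard(hotter, ph$normal_mask),
             thermal_hazard(base, ph$normal_mask))
  expect_error(hazard_weighting(breaks = c(50, 43)), "breaks")
})

test_that("retention averages are trapezoidal time means", {
  expect_equal(retention_average(c(0, 900), c(0.3, 0.3)), 0.3)
  # in-band for half the treatment
  expect_equal(retention_average(c(0, 449, 450, 451, 900),
                                 c(1, 1, 1, 0, 0)), 0.5, tolerance = 2e-3)
  # linear ramp integrates to its midpoint
  tt <- seq(0, 900, by = 1)
  expect_equal(retention_average(tt, tt / 900), 0.5)
  expect_error(retention_average(numeric(0), numeric(0)), "non-empty")
  expect_error(retention_average(c(0, 0), c(1, 1)), "increasing")
})

test_that("effective ratio divides with a hazard floor", {
  expect_equal(effective_ratio(0, 5), 0)
  expect_equal(effective_ratio(0.4, 0.2), 2)
  expect_equal(effective_ratio(0.1, 0), 100)
  expect_error(effective_ratio(-0.1, 1), "theta")
  expect_error(effective_ratio(0.5, -1), "theta")
})

test_that("metrics on synthetic series match hand computation exactly", {
  ph <- tiny_phantom(voxel_size = 1)
  # hot sphere centered on the tumor covering part of it, ramping 0 -> 1
  spec <- synth_field_spec(peak = 45, baseline = 37, center = c(0, 0, 0),
                           radius = 4,
                           profile = tibble::tibble(time = c(0, 450, 900),
                                                    scale = c(0, 1, 1)))
  ts <- synth_temperature_series(spec, ph)
  m <- treatment_metrics(ts, ph)
  # hand count: voxel centers inside the sphere and inside each mask
  d <- 1
  xc <- -15 + (seq_len(30) - 0.5) * d
  zc <- (seq_len(20) - 0.5) * d
  dist2 <- outer(outer(xc^2, xc^2, "+"), zc^2, "+")
  hot <- dist2 <= 16
  frac_tumor <- sum(hot & ph$tumor_mask) / sum(ph$tumor_mask)
  frac_normal <- sum(hot & ph$normal_mask) / sum(ph$normal_mask)
  expect_equal(m$theta_A, c(0, frac_tumor, frac_tumor))
  expect_equal(m$theta_H, c(0, frac_normal, frac_normal))
  # trapezoid: 0 over the ramp midpoint average, then constant
  expect_equal(attr(m, "theta_A_star"), frac_tumor * 0.75)
  expect_equal(attr(m, "theta_H_star"), frac_normal * 0.75)
  expect_equal(attr(m, "theta_eff_star"),
               frac_tumor * 0.75 / max(frac_normal * 0.75, 1e-3))
  g <- glance(m)
  expect_named(g, c("theta_A_star", "theta_H_star", "theta_eff_star",
                    "hazard_weighting"))
})

test_that("metric export writes CSV traces and a JSON summary", {
  ph <- tiny_phantom(voxel_size = 1)
  spec <- synth_field_spec(profile = tibble::tibble(time = c(0, 10),
                                                    scale = c(1, 1)))
  m <- treatment_metrics(synth_temperature_series(spec, ph), ph)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics(m, csv, js, condition = list(p_mw = 200))
  got <- utils::read.csv(csv)
  expect_named(got, c("time_s", "thetaA", "thetaH"))
  j <- jsonlite::read_json(js)
  expect_equal(j$thetaA_star, attr(m, "theta_A_star"))
  expect_equal(j$p_mw, 200)
  unlink(c(csv, js))
})
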