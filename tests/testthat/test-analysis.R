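# Field-set statistics, positional uncertainty, plane comparison.

test_that("diff_statistics: symmetric pair, constant set, spreadsheet oracle, permutation invariance", {
  d <- diff_statistics(c(1.01, 0.99), c(1.00, 1.00))
  expect_equal(d$mean, 0)
  expect_equal(d$max, 1)
  expect_equal(d$min, -1)

  dc <- diff_statistics(c(1.02, 1.02, 1.02), c(1.00, 1.00, 1.00))
  expect_equal(dc$sd, 0)
  expect_equal(dc$mean, 2)

  set.seed(8)
  fm <- runif(5, 0.9, 1.2)
  fc <- fm * (1 + rnorm(5, 0, 0.02))
  d5 <- diff_statistics(fc, fm, band_percent = 2)
  dd <- 100 * (fc - fm)
  expect_equal(d5$mean, sum(dd) / 5)
  expect_equal(d5$sd, sqrt(sum((dd - mean(dd))^2) / 4))   # sample SD, n-1
  expect_equal(d5$max, max(dd))
  expect_equal(d5$min, min(dd))
  expect_equal(d5$fraction_within, mean(abs(dd) <= 2))

  perm <- sample(5)
  dp <- diff_statistics(fc[perm], fm[perm], band_percent = 2)
  expect_equal(dp[c("mean", "sd", "max", "min", "fraction_within")],
               d5[c("mean", "sd", "max", "min", "fraction_within")])

  expect_error(diff_statistics(1.0, 1.0), "2 fields")
  expect_error(diff_statistics(c(1, -1), c(1, 1)), "positive")
})

test_that("band membership uses the closed interval", {
  d <- diff_statistics(c(1.011, 1.0), c(1.0, 1.0), band_percent = 1.1)
  expect_equal(d$fraction_within, 1)   # |1.1| <= 1.1 counts as within
})

test_that("positional_uncertainty: uniform zero, linear gradient, dense oracle", {
  gU <- analytic_grid(function(x, y, z) 3)
  expect_equal(positional_uncertainty(gU, c(0, 0, 0)), 0)

  # pure x gradient g on dose D: peak-to-peak over a 2 mm cube = 2*g/D
  gL <- analytic_grid(function(x, y, z) 10 + 0.5 * x)
  pu <- positional_uncertainty(gL, c(0, 0, 0), cube_side = 2)
  expect_equal(pu, 2 * 0.5 / 10, tolerance = 1e-9)

  # smooth curved field against a much denser sampling oracle
  gN <- analytic_grid(function(x, y, z) 20 + 0.1 * x + 0.05 * y * z + 0.02 * z^2)
  v <- positional_uncertainty(gN, c(1, -2, 3))
  oracle <- positional_uncertainty(gN, c(1, -2, 3), n_samples = 21)
  expect_lt(abs(v - oracle), 0.005 * oracle + 1e-12)
  expect_gte(v, 0)

  expect_error(positional_uncertainty(gU, c(100, 0, 0)), "outside")
})

test_that("positional_uncertainty on an SOBP plateau is small", {
  # on the analytic SOBP itself the plateau is flat to well under 2%
  comm <- comm_default()
  s <- commissioning_sobp(comm, 190, 80)
  gS <- analytic_grid(function(x, y, z) curve_value(s$curve, z),
                      dims = c(11, 11, 40),
                      origin = c(-11, -11, s$curve$nominal_range - 80))
  expect_lt(positional_uncertainty(gS, c(0, 0, s$curve$nominal_range - 40)), 0.02)
  # on a simulated grid the metric additionally carries the Monte Carlo
  # voxel noise; bound it by the flat-field level plus that noise
  g <- run_simulation(bsd_config(190, 80, 0), transport_config(6e5, seed = 19),
                      comm, window_halfwidth = 35)
  se_vox <- estimate_statistical_error(g) * sqrt(g$n_batches)   # per-voxel sigma
  expect_lt(positional_uncertainty(g, c(0, 0, 0)), 0.02 + 4 * se_vox)
})

test_that("compare_profiles: identity, uniform scale, summary", {
  m <- matrix(runif(27 * 27), 27, 27)
  same <- compare_profiles(m, m)
  expect_true(all(same$diff == 0))
  expect_equal(same$sd, 0)
  up <- compare_profiles(m * 1.02, m)
  expect_equal(up$diff, m * 0.02)
  expect_equal(up$mean, mean(m) * 0.02)
  expect_error(compare_profiles(m, m[1:10, 1:10]), "lattice")
})

test_that("a re-simulation with a new seed differs only within combined errors on the array lattice", {
  comm <- comm_default()
  cfg <- bsd_config(190, 80, 0)
  g1 <- run_simulation(cfg, transport_config(8e5, seed = 23), comm,
                       window_halfwidth = 35)
  g2 <- run_simulation(cfg, transport_config(8e5, seed = 24), comm,
                       window_halfwidth = 35)
  # small seven29-style sub-lattice around the axis at the isocenter plane
  cell <- detector_cell("array_cell")
  off <- seq(-20, 20, by = 10)
  v1 <- outer(off, off, Vectorize(function(a, b) detector_average(g1, cell, c(a, b, 0))))
  v2 <- outer(off, off, Vectorize(function(a, b) detector_average(g2, cell, c(a, b, 0))))
  cmp <- compare_profiles(v2 / mean(v1), v1 / mean(v1))
  se <- estimate_statistical_error(g1) * sqrt(2)
  # >90% of points consistent with the combined statistical error
  expect_gt(mean(abs(cmp$diff) < 4 * se), 0.9)
})

test_that("field set round-trips through CSV with validation", {
  df <- data.frame(field_id = c("f1", "f2"), site = c("prostate", "lung"),
                   energy_mev = c(235, 150), sobp_mm = c(60, 50),
                   rs_mm_wel = c(55.1, 21.5),
                   f_meas_clinical = c(1.1, 0.95),
                   f_calc_clinical = c(1.09, 0.96))
  p <- tempfile(fileext = ".csv")
  write_field_set(df, p)
  back <- read_field_set(p)
  expect_equal(back$f_meas_clinical, df$f_meas_clinical)
  d <- diff_statistics(back)
  expect_equal(d$n_fields, 2)
  bad <- df; bad$f_meas_clinical[1] <- -1
  write_field_set(bad, p)
  expect_error(read_field_set(p), "positive")
})
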