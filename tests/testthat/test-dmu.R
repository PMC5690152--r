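# DMU factors: detector averaging, F_BSD lookup, field-size correction,
# composition.

test_that("detector_average: uniform field, single voxel, linear gradient, quadrature oracle", {
  cell1 <- detector_cell("farmer")
  expect_equal(cell1$extent, c(6.1, 23.4))
  cell2 <- detector_cell("array_cell")
  expect_equal(cell2$extent, c(5, 5))
  expect_equal(cell2$wel_offset, 8)

  gU <- analytic_grid(function(x, y, z) 7)
  expect_equal(detector_average(gU, cell1, c(0, 0, 0)), 7)

  # cell equal to exactly one voxel returns that voxel's value (locally
  # linear dose)
  gV <- analytic_grid(function(x, y, z) 2 + 0.25 * x - 0.15 * y)
  one_vox <- structure(list(kind = "array_cell", extent = c(2, 2), wel_offset = 0),
                       class = "detector_cell")
  expect_equal(detector_average(gV, one_vox, c(0, 0, 0)), 2, tolerance = 1e-9)

  # linear gradient: average equals the value at the cell center
  gL <- analytic_grid(function(x, y, z) 5 + 0.3 * x + 0.1 * y)
  expect_equal(detector_average(gL, cell1, c(2, -3, 0)),
               5 + 0.3 * 2 + 0.1 * (-3), tolerance = 1e-9)

  # smooth nonlinear field vs a much denser quadrature oracle
  gN <- analytic_grid(function(x, y, z) 10 + 0.02 * x^2 - 0.01 * x * y + 0.03 * y^2)
  v <- detector_average(gN, cell1, c(1, 2, 0))
  oracle <- detector_average(gN, cell1, c(1, 2, 0), quad_spacing = 0.05)
  expect_lt(abs(v / oracle - 1), 0.005)

  expect_error(detector_average(gU, cell1, c(100, 0, 0)), "outside")
})

test_that("lookup_fbsd: node-exact, linear in RS, guarded domain", {
  tab <- generate_fbsd_table(1)
  expect_identical(lookup_fbsd(tab, 190, 80, 0), 1)
  g <- tab[tab$energy_mev == 190 & tab$sobp_mm == 80, ]
  g <- g[order(g$rs_mm_wel), ]
  expect_equal(lookup_fbsd(tab, 190, 80, g$rs_mm_wel[2]), g$value[2])
  mid <- mean(g$rs_mm_wel[1:2])
  expect_equal(lookup_fbsd(tab, 190, 80, mid), mean(g$value[1:2]))
  expect_error(lookup_fbsd(tab, 190, 80, max(g$rs_mm_wel) + 5), "bounds")
  expect_error(lookup_fbsd(tab, 200, 80, 0), "energy")
  expect_error(lookup_fbsd(tab, 190, 45, 0), "SOBP")
})

test_that("field_size_correction: normalization point, flat low-energy curves, mean-radius mapping", {
  fmeas <- generate_fmeas_fs_table(150)
  fcalc <- field_size_table(150, FS_APERTURE_SIDES, rep(1, 5), kind = "calculated")
  # the standard 185 mm square needs no correction
  expect_equal(field_size_correction(fmeas, fcalc, square_aperture(185)), 1)
  # low energy: within 1% of unity everywhere on the tabulated domain
  for (A in c(40, 60, 120)) {
    f <- field_size_correction(fmeas, fcalc, square_aperture(A))
    expect_lt(abs(f - 1), 0.01)
  }
  # an irregular aperture maps through its mean radius: a circle with the
  # mean radius of the 70 mm square gets the same correction
  f235m <- generate_fmeas_fs_table(235)
  f235c <- field_size_table(235, FS_APERTURE_SIDES, rep(1, 5), kind = "calculated")
  rho70 <- square_mean_radius(70)
  f_sq <- field_size_correction(f235m, f235c, square_aperture(70))
  f_ci <- field_size_correction(f235m, f235c, circular_aperture(rho70))
  expect_equal(f_sq, f_ci, tolerance = 1e-3)
  # beyond the largest tabulated square: clamp to no correction
  expect_equal(field_size_correction(f235m, f235c, circular_aperture(150)), 1)
  # below the smallest tabulated square: outside the validated domain
  expect_error(field_size_correction(f235m, f235c, circular_aperture(15)),
               "smallest")
  # continuity across table nodes in mean-radius space
  rr <- seq(square_mean_radius(45), square_mean_radius(120), length.out = 40)
  ff <- vapply(rr, function(r) field_size_correction(f235m, f235c,
                                                     circular_aperture(r)),
               numeric(1))
  expect_lt(max(abs(diff(ff))), 0.01)
})

test_that("compose_clinical_dmu multiplies and stores the exact breakdown", {
  r <- compose_clinical_dmu(1.0, 0.9, 1.02, 0.98)
  expect_equal(r$dmu_clinical, 0.9 * 1.02 * 0.98)
  expect_equal(r$breakdown$f_clinical,
               r$breakdown$f_bsd * r$breakdown$f_psd * r$breakdown$f_fs)
  r2 <- compose_clinical_dmu(1.23, 1, 1, 1)
  expect_equal(r2$dmu_clinical, 1.23)
  expect_error(compose_clinical_dmu(1, -0.5, 1, 1), "positive")
  expect_error(compose_clinical_dmu(0, 1, 1, 1), "positive")
})

test_that("compute_fpsd validates shared beam-spreading parameters", {
  comm <- comm_default()
  b <- bsd_config(190, 80, 0)
  p <- beamline_config(190, 60, 0, condition_label = "PSD")
  expect_error(compute_fpsd(b, p, comm, transport_config(1e3, seed = 1)),
               "share")
})

test_that("simulate_dmu is reproducible and carries coherent errors", {
  comm <- comm_default()
  cfg <- bsd_config(190, 80, 0)
  tc <- transport_config(1e5, seed = 17)
  a <- simulate_dmu(cfg, comm, tc)
  b <- simulate_dmu(cfg, comm, tc)
  expect_identical(a$value, b$value)
  expect_identical(a$se, b$se)
  expect_equal(a$se, a$value * a$rel_se)
  expect_gt(a$value, 0)
})
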