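# Beam model: range-energy law, pristine curves, SOBP synthesis, synthetic
# commissioning tables.

test_that("range-energy conversion is monotone, invertible and matches a CSDA-style oracle", {
  expect_error(range_from_energy(0), "energy")
  expect_error(range_from_energy(400), "energy")
  r <- range_from_energy(c(150, 190, 235))
  expect_true(all(diff(r) > 0))
  expect_equal(energy_from_range(r), c(150, 190, 235), tolerance = 1e-12)

  # independent oracle: numerically integrate dz = dE / S(E) with the
  # stopping power implied by the same power law, S = dE/dR = 1/(alpha p E^(p-1));
  # the quadrature must recover the closed form within 5%
  const <- beam_constants()
  ee <- seq(1e-3, 190, length.out = 20001)
  S <- 1 / (const$alpha * const$p * ee^(const$p - 1))
  r_or <- sum(1 / S) * diff(ee)[1]
  expect_equal(range_from_energy(190), r_or, tolerance = 0.05)
})

test_that("wel_scale is a plain product with guarded domain", {
  expect_identical(wel_scale(10, 1.0), 10)
  expect_equal(wel_scale(10, 0.97), 9.7)
  expect_identical(wel_scale(0, 2.3), 0)
  expect_error(wel_scale(-1, 1), ">= 0")
  expect_error(wel_scale(1, 0), "> 0")
})

test_that("pristine Bragg curve has entrance plateau, peak near range, bounded support", {
  for (e in c(150, 235)) {
    bp <- pristine_bragg_curve(e)
    R <- range_from_energy(e)
    expect_gt(bp$values[1], 0)
    expect_lt(bp$values[1], max(bp$values))
    peak_depth <- bp$depths[which.max(bp$values)]
    expect_lt(abs(peak_depth - R), 3)
    expect_true(all(bp$values[bp$depths > R + 6 * (R - peak_depth) + 10] >= 0))
    expect_equal(max(bp$values), 1)
  }
})

test_that("depth_dose_curve validates its invariants", {
  expect_error(depth_dose_curve(c(0, 1, 1.5), c(1, 1, 1), 10), "uniform")
  expect_error(depth_dose_curve(c(0, 1, 2), c(1, -1, 1), 10), ">= 0")
  expect_error(depth_dose_curve(c(0, 1.5, 3), c(1, 1, 1), 10), "spacing")
  cv <- depth_dose_curve(seq(0, 10, 0.5), rep(1, 21), 10)
  expect_s3_class(cv, "depth_dose_curve")
  expect_equal(curve_value(cv, c(-1, 3.25, 12)), c(0, 1, 0))
})

test_that("SOBP is flat, normalized at center, with nonnegative weights and stated width", {
  s <- build_sobp(190, 30)
  expect_lte(s$flatness, 0.02)
  expect_true(all(s$spec$weights >= 0))
  expect_gt(sum(s$spec$weights), 0)
  R <- s$curve$nominal_range
  expect_equal(curve_value(s$curve, R - 15), 1.0, tolerance = 1e-9)
  fr <- flat_region(s$curve, 0.95)
  expect_lt(abs(diff(fr) - 30), 5)
  expect_error(build_sobp(190, 45), "grid")
})

test_that("SOBP distal edge is fixed by energy while the proximal edge tracks the width", {
  widths <- c(30, 60, 100)
  fr <- vapply(widths, function(w) flat_region(build_sobp(190, w)$curve, 0.95),
               numeric(2))
  # distal positions agree within the grid spacing
  expect_lt(max(fr[2, ]) - min(fr[2, ]), 0.5)
  # proximal edge moves upstream linearly with width (slope -1)
  slope <- diff(fr[1, c(1, 3)]) / diff(widths[c(1, 3)])
  expect_lt(abs(slope + 1), 0.05)
})

test_that("synthetic F_BSD table is normalized, monotone and seed-reproducible", {
  tab <- generate_fbsd_table(seed = 3)
  expect_identical(tab, generate_fbsd_table(seed = 3))
  expect_false(identical(tab$value, generate_fbsd_table(seed = 4)$value))
  std <- tab$value[tab$energy_mev == 190 & tab$sobp_mm == 80 & tab$rs_mm_wel == 0]
  expect_identical(std, 1)
  # decreasing with RS thickness and with SOBP width
  expect_lt(lookup_fbsd(tab, 190, 80, 60), lookup_fbsd(tab, 190, 80, 0))
  v100 <- tab$value[tab$energy_mev == 190 & tab$sobp_mm == 100 & tab$rs_mm_wel == 0]
  v30 <- tab$value[tab$energy_mev == 190 & tab$sobp_mm == 30 & tab$rs_mm_wel == 0]
  expect_lt(v100, v30)
  # full grid: three energies x eight widths
  expect_identical(sort(unique(tab$energy_mev)), c(150, 190, 235))
  expect_identical(sort(unique(tab$sobp_mm)), seq(30, 100, by = 10))
})

test_that("synthetic measured field-size curves show the commissioned trends", {
  t235 <- generate_fmeas_fs_table(235)
  expect_identical(t235$f_values[t235$aperture_sides == 185], 1)
  drop <- 100 * (1 - t235$f_values[t235$aperture_sides == 40])
  expect_equal(drop, 5, tolerance = 1e-12)
  expect_true(all(diff(t235$f_values) > 0))   # monotone rise toward 185
  for (e in c(150, 190)) {
    tt <- generate_fmeas_fs_table(e)
    expect_lt(max(abs(1 - tt$f_values)), 0.01)
    expect_identical(tt$f_values[tt$aperture_sides == 185], 1)
  }
  expect_error(generate_fmeas_fs_table(200), "energy")
})

test_that("field_size_table rejects broken normalization", {
  expect_error(field_size_table(235, c(40, 185), c(0.95, 0.99)), "exactly 1")
  expect_error(field_size_table(235, c(40, 100), c(0.95, 1)), "185")
  expect_error(field_size_table(235, c(40, 185), c(1.2, 1)), "0, 1.01")
})
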