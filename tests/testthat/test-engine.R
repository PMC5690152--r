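# Transport engine: source sampling, determinism, batch statistics,
# aperture cut geometry, kernel cross-validation, step-size stability.

test_that("source sampler: unbiased positions, SOBP constituent mixture, degenerate limits", {
  comm <- comm_default()
  s <- commissioning_sobp(comm, 190, 80)
  set.seed(5)
  n <- 1e5
  p <- sample_source_protons(comm$source, n, s, s$pristine$nominal_range, 40)
  # aim fluence keeps the mean lateral direction centered
  expect_lt(abs(mean(p$x)), 4 * comm$source$lateral_sigma / sqrt(n))
  expect_equal(sqrt(sum(p[1, c("dx", "dy", "dz")]^2)), 1, tolerance = 1e-12)
  # constituent mixture matches the SOBP weights (chi-square)
  w <- s$spec$weights
  keep <- w / sum(w) * n >= 5
  obs <- tabulate(p$constituent, nbins = length(w))
  cs <- suppressWarnings(chisq.test(obs[keep], p = w[keep] / sum(w[keep]),
                                    rescale.p = TRUE))
  expect_gt(cs$p.value, 1e-4)
  # degenerate source: all protons exactly on the aim ray through the axis
  src0 <- effective_source(Inf, 0, 0)
  p0 <- sample_source_protons(src0, 100, s, s$pristine$nominal_range, 1e-9)
  expect_true(all(abs(p0$x) < 1e-8))
  expect_true(all(p0$dz == 1))
})

test_that("fixed seed gives bit-identical dose grids; different seeds differ", {
  comm <- comm_default()
  cfg <- bsd_config(190, 80, 0)
  tc <- transport_config(5e4, seed = 42)
  g1 <- run_simulation(cfg, tc, comm, window_halfwidth = 30)
  g2 <- run_simulation(cfg, tc, comm, window_halfwidth = 30)
  expect_identical(g1$dose, g2$dose)
  expect_identical(g1$batch_dose, g2$batch_dose)
  g3 <- run_simulation(cfg, transport_config(5e4, seed = 43), comm,
                       window_halfwidth = 30)
  expect_false(identical(g1$dose, g3$dose))
})

test_that("compiled kernel reproduces the reference transport exactly (scattering off)", {
  comm <- comm_default()
  s <- commissioning_sobp(comm, 190, 80)
  cfg <- beamline_config(190, 80, 20,
                         compensator = uniform_compensator(15, wel_ratio = 0.97),
                         aperture = square_aperture(80), condition_label = "PSD")
  set.seed(99)
  p <- sample_source_protons(comm$source, 60, s, s$pristine$nominal_range, 30)
  pr <- transport_device_stack(p, cfg, comm$const, scatter = FALSE)
  dims <- c(31L, 31L, 124L)
  org <- c(-31, -31, -cfg$measurement_depth)
  dr <- deposit_in_phantom(pr, s$pristine, org, dims, welr = 1, scatter = FALSE)
  ht <- protonDMU:::highland_tables(comm$const)
  res <- protonDMU:::smc_batch_cpp(
    p$x, p$y, p$z[1], p$dx, p$dy, p$dz, p$residual,
    20, -500, TRUE, cfg$compensator$thickness, cfg$compensator$origin[1],
    cfg$compensator$origin[2], cfg$compensator$spacing,
    cfg$compensator$wel_ratio, -cfg$compensator$plane_distance,
    TRUE, cfg$aperture$edge_points[, 1], cfg$aperture$edge_points[, 2], -300,
    org[3], 1, 2, org[1], org[2], dims[1], dims[2], dims[3], 2,
    s$pristine$values, s$pristine$spacing, s$pristine$nominal_range,
    ht$kfac, ht$dr, ht$g, ht$dl, FALSE, FALSE, FALSE, 1234)
  dc <- aperm(array(res$dose, c(dims[3], dims[1], dims[2])), c(2, 3, 1))
  expect_lt(max(abs(dc - dr)), 1e-12 * max(dr))
})

test_that("device stack arithmetic: drift only, uniform range loss, aperture cut", {
  comm <- comm_default()
  s <- commissioning_sobp(comm, 190, 80)
  set.seed(7)
  p <- sample_source_protons(comm$source, 200, s, s$pristine$nominal_range, 30)
  # no devices beyond a huge aperture: state unchanged except drift
  cfg0 <- bsd_config(190, 80, 0, aperture = square_aperture(400))
  out0 <- transport_device_stack(p, cfg0, scatter = FALSE)
  expect_equal(out0$residual, p$residual)
  expect_equal(out0$dx, p$dx)
  expect_true(all(out0$alive))
  expect_equal(out0$z, rep(-cfg0$measurement_depth, 200))
  # uniform compensator: exact uniform range loss for survivors
  cfgc <- beamline_config(190, 80, 0, compensator = uniform_compensator(10),
                          aperture = square_aperture(400), condition_label = "PSD")
  outc <- transport_device_stack(p, cfgc, scatter = FALSE)
  expect_equal(outc$residual[outc$alive], p$residual[outc$alive] - 10)
  # proton aimed outside the aperture is terminated
  p1 <- p[1, ]; p1$x <- 300; p1$dx <- 0; p1$dy <- 0; p1$dz <- 1
  expect_false(transport_device_stack(p1, bsd_config(190, 80, 0),
                                      scatter = FALSE)$alive)
})

test_that("single straight proton reproduces curve samples at step centers", {
  comm <- comm_parallel()
  s <- commissioning_sobp(comm, 190, 80)
  R0 <- s$pristine$nominal_range
  p <- data.frame(x = 0, y = 0, z = -100, dx = 0, dy = 0, dz = 1,
                  residual = R0, constituent = 1L, alive = TRUE, l_cum = 0)
  dims <- c(11L, 11L, 60L)
  dose <- deposit_in_phantom(p, s$pristine, c(-11, -11, -100), dims,
                             welr = 1, scatter = FALSE)
  # the proton travels on the axis: all dose in the central column
  expect_equal(sum(dose[6, 6, ]), sum(dose))
  z <- -100 + (seq_len(60) - 0.5) * 2
  depth <- z + 100
  expect_equal(dose[6, 6, ], curve_value(s$pristine, depth) * 2)
})

test_that("aperture cut footprint is the projected opening within one voxel (no scattering)", {
  comm <- comm_parallel()
  cfg <- fs_config(190, 40)
  tc <- transport_config(2e5, seed = 9, scatter = FALSE)
  g <- run_simulation(cfg, tc, comm, window_halfwidth = 40, grid_halfwidth = 50)
  iz <- 2L   # just inside the phantom
  sl <- g$dose[, , iz]
  x <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$vox
  hit <- apply(sl, 1, max) > 0
  expect_lt(abs(min(x[hit]) - (-20)), 2 + 1e-9)
  expect_lt(abs(max(x[hit]) - 20), 2 + 1e-9)
})

test_that("batch statistical error: zero spread, known-distribution calibration, scaling", {
  # identical batches -> zero error
  bd <- array(1, c(3, 3, 3, 8))
  g0 <- fake_grid(array(1, c(3, 3, 3)), batch_dose = bd, batch_index = 1:3,
                  n_batches = 8)
  expect_identical(estimate_statistical_error(g0, c(3, 3, 3)), 0)
  # batches drawn from a known normal: estimator close to sigma/sqrt(n)/mu
  set.seed(12)
  nb <- 20; mu <- 10; sigma <- 1
  est <- replicate(100, {
    v <- rnorm(nb, mu, sigma)
    bd <- array(rep(v, each = 1), c(1, 1, 1, nb))
    g <- fake_grid(array(mu, c(1, 1, 1)), batch_dose = bd, batch_index = 1L,
                   n_batches = nb)
    estimate_statistical_error(g, c(1, 1, 1))
  })
  expect_lt(abs(mean(est) / (sigma / sqrt(nb) / mu) - 1), 0.3)
  # zero dose is flagged
  gz <- fake_grid(array(0, c(1, 1, 1)),
                  batch_dose = array(0, c(1, 1, 1, nb)),
                  batch_index = 1L, n_batches = nb)
  expect_error(estimate_statistical_error(gz, c(1, 1, 1)), "undefined")
})

test_that("estimated variance falls with particle count", {
  comm <- comm_default()
  cfg <- bsd_config(190, 80, 0)
  se1 <- estimate_statistical_error(
    run_simulation(cfg, transport_config(1e5, seed = 3), comm,
                   window_halfwidth = 35))
  se2 <- estimate_statistical_error(
    run_simulation(cfg, transport_config(8e5, seed = 3), comm,
                   window_halfwidth = 35))
  # 8x protons: expect close to sqrt(8) = 2.83x reduction; allow wide slack
  expect_lt(se2, se1 / 1.6)
})

test_that("halving the step does not move the isocenter dose beyond statistical error", {
  comm <- comm_default()
  cfg <- bsd_config(190, 80, 0)
  g2 <- run_simulation(cfg, transport_config(6e5, seed = 13, step = 2), comm,
                       window_halfwidth = 35)
  g1 <- run_simulation(cfg, transport_config(6e5, seed = 14, step = 1), comm,
                       window_halfwidth = 35)
  d2 <- dose_at(g2, c(0, 0, 0)); d1 <- dose_at(g1, c(0, 0, 0))
  se <- sqrt(estimate_statistical_error(g2)^2 + estimate_statistical_error(g1)^2)
  expect_lt(abs(d1 / d2 - 1), 3 * se + 0.005)
})

test_that("doubling all constituent weights leaves the normalized output unchanged", {
  comm <- comm_default()
  s <- commissioning_sobp(comm, 190, 80)
  s2 <- s
  s2$spec$weights <- 2 * s$spec$weights
  set.seed(77)
  p1 <- sample_source_protons(comm$source, 1000, s, 237, 30)
  set.seed(77)
  p2 <- sample_source_protons(comm$source, 1000, s2, 237, 30)
  expect_identical(p1, p2)   # mixture probabilities are scale-free
})

test_that("an aperture that blocks the whole beam is reported", {
  comm <- comm_default()
  suppressWarnings({
    cfg <- beamline_config(190, 80, 0,
                           aperture = circular_aperture(5, center = c(120, 0)),
                           condition_label = "FS")
  })
  expect_error(run_simulation(cfg, transport_config(1e3, seed = 1), comm,
                              window_halfwidth = 10),
               "survived")
})
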