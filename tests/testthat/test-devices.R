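# Device geometry: aperture polygons, mean aperture radius, compensator
# interpolation, phantom depth formula.

test_that("mean aperture radius: circle, square closed form, off-center oracle", {
  expect_equal(mean_aperture_radius(circular_aperture(50)), 50, tolerance = 1e-4)
  # square: closed-form mean distance from center to perimeter
  sq <- square_aperture(185)
  expect_equal(mean_aperture_radius(sq), square_mean_radius(185), tolerance = 1e-3)
  # off-center circle: brute-force perimeter integration oracle
  r <- 30; cx <- 10
  th <- seq(0, 2 * pi, length.out = 20001)[-20001]
  oracle <- mean(sqrt((cx + r * cos(th))^2 + (r * sin(th))^2))
  ap <- circular_aperture(30, center = c(10, 0))
  expect_equal(mean_aperture_radius(ap), oracle, tolerance = 1e-3)
})

test_that("mean aperture radius is rotation invariant", {
  set.seed(4)
  th <- sort(runif(40, 0, 2 * pi))
  rad <- 40 + 15 * sin(3 * th) + rnorm(40, 0, 2)
  poly <- cbind(rad * cos(th), rad * sin(th))
  m0 <- mean_aperture_radius(aperture_collimator(poly))
  for (a in c(0.7, 2.1)) {
    rot <- poly %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    expect_equal(mean_aperture_radius(aperture_collimator(rot)), m0,
                 tolerance = 1e-3)
  }
})

test_that("point_in_aperture matches an independent ray-casting oracle", {
  set.seed(11)
  for (k in 1:10) {
    nv <- sample(5:40, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(1, 20, 60) + runif(nv, -5, 5)
    poly <- cbind(rad * cos(th), rad * sin(th))
    # a sparse vertex set may leave the axis outside the opening: benign here
    ap <- suppressWarnings(aperture_collimator(poly))
    x <- runif(1000, -70, 70); y <- runif(1000, -70, 70)
    expect_identical(point_in_aperture(ap, x, y), pip_oracle(poly, x, y))
  }
  sq <- square_aperture(185)
  expect_true(point_in_aperture(sq, 0, 0))
  expect_false(point_in_aperture(sq, 200, 200))
})

test_that("aperture constructor rejects self-intersecting polygons and flags off-axis openings", {
  bow <- rbind(c(-10, -10), c(10, 10), c(10, -10), c(-10, 10))
  expect_error(aperture_collimator(bow), "self-intersecting")
  expect_warning(circular_aperture(5, center = c(30, 0)), "axis")
})

test_that("compensator lookup is bilinear with edge clamping", {
  comp <- uniform_compensator(10, halfwidth = 50)
  expect_equal(compensator_thickness_at(comp, c(0, 17.3, -49), c(3, -8, 12)),
               rep(10, 3))
  # node-exact and cell-center mean on a structured map
  th <- outer(1:5, 1:5, function(i, j) i + 10 * j)
  comp2 <- range_compensator(th, origin = c(0, 0), spacing = 2, wel_ratio = 0.97)
  expect_equal(compensator_thickness_at(comp2, 4, 6), th[3, 4] * 0.97)
  corners <- c(th[2, 2], th[3, 2], th[2, 3], th[3, 3])
  expect_equal(compensator_thickness_at(comp2, 3, 3), mean(corners) * 0.97)
  # outside the extent: clamped to the nearest edge value
  expect_equal(compensator_thickness_at(comp2, 100, 0), th[5, 1] * 0.97)
  expect_error(range_compensator(matrix(-1, 2, 2)), ">= 0")
})

test_that("phantom depth formula reproduces the commissioning arithmetic", {
  expect_equal(phantom_depth_for_sobp_center(200, 80, 0, 1.0), 160)
  expect_equal(phantom_depth_for_sobp_center(200, 80, 0, 0.97), 160 / 0.97)
  expect_error(phantom_depth_for_sobp_center(100, 80, 80, 1.0), "reach")
})

test_that("range shifter and STD condition are validated", {
  expect_error(range_shifter(130), "120")
  expect_error(range_shifter(-1), "120")
  expect_s3_class(std_config(), "beamline_config")
  expect_error(beamline_config(150, 80, 0, condition_label = "STD"), "STD")
  expect_error(beamline_config(190, 80, 10, condition_label = "STD"), "STD")
})
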