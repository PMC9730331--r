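test_that("exact ellipse data is recovered to numerical precision", {
  f <- fit_ellipse(ellipse_points(0.5, 0.3))
  expect_equal(f$semi_major, 0.5, tolerance = 1e-6)
  expect_equal(f$semi_minor, 0.3, tolerance = 1e-6)
  expect_lt(f$rms_algebraic, 1e-10)

  # circle: equal axes, any orientation
  fc <- fit_ellipse(ellipse_points(0.7, 0.7))
  expect_equal(fc$semi_major, 0.7, tolerance = 1e-6)
  expect_equal(fc$semi_minor, 0.7, tolerance = 1e-6)

  # similarity invariance: rotation + translation leave the axes alone
  f2 <- fit_ellipse(ellipse_points(0.5, 0.3, rot = 37 * pi / 180,
                                   center = c(2.3, -1.1)))
  expect_equal(f2$semi_major, 0.5, tolerance = 1e-6)
  expect_equal(f2$semi_minor, 0.3, tolerance = 1e-6)
  expect_equal(f2$orientation, 37 * pi / 180, tolerance = 1e-6)
  expect_equal(f2$center, c(2.3, -1.1), tolerance = 1e-6)

  # the conic really is an ellipse
  k <- f2$conic
  expect_lt(k[["b"]]^2 - 4 * k[["a"]] * k[["c"]], 0)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_ellipse(ellipse_points(1, 0.5)[1:4, ]), ">= 5")
  line <- cbind(1:10, 2 * (1:10) + 1)
  expect_error(fit_ellipse(line), "collinear")
})

test_that("randomized ellipses are recovered (property)", {
  set.seed(31)
  for (i in 1:25) {
    a <- runif(1, 0.2, 2); b <- runif(1, 0.1, a)
    rot <- runif(1, 0, pi); ctr <- runif(2, -3, 3)
    f <- fit_ellipse(ellipse_points(a, b, n = 60, rot = rot, center = ctr))
    expect_equal(f$semi_major, a, tolerance = 1e-6)
    expect_equal(f$semi_minor, b, tolerance = 1e-6)
  }
})

test_that("measurement on rasterized lesions matches analytic truth", {
  ph <- lesion_phantom(c(0.5, 0.3), n_slices = 1)
  m <- measure_lesion(ph$lesion_truth[[1]])
  vox_cm <- 0.08
  expect_lt(abs(m$max_diameter_cm - 1.0), vox_cm)
  expect_lt(abs(m$volume_cc - pi * 0.5 * 0.3 * 0.6) / (pi * 0.5 * 0.3 * 0.6),
            0.10)
  expect_equal(m$slice_profile_cm, 0.6)

  # two identical slices: same diameter, double volume
  ph2 <- lesion_phantom(c(0.5, 0.3), n_slices = 2)
  m2 <- measure_lesion(ph2$lesion_truth[[1]])
  expect_equal(m2$max_diameter_cm, m$max_diameter_cm, tolerance = 1e-9)
  expect_equal(m2$volume_cc, 2 * m$volume_cc, tolerance = 1e-9)
  expect_equal(m2$n_slices, 2L)

  # pixel-count area agrees with the ellipse area within rasterization
  mp <- measure_lesion(ph$lesion_truth[[1]], area_method = "pixel")
  expect_lt(abs(mp$volume_cc - m$volume_cc) / m$volume_cc, 0.15)
})

test_that("coordinate scaling scales diameter linearly and area-volume quadratically", {
  pts <- ellipse_points(0.5, 0.3, rot = 0.4)
  f1 <- fit_ellipse(pts)
  f2 <- fit_ellipse(pts * 1.7)
  expect_equal(f2$semi_major / f1$semi_major, 1.7, tolerance = 1e-6)
  expect_equal(ellipse_area(f2) / ellipse_area(f1), 1.7^2,
               tolerance = 1e-6)
})

test_that("empty ROIs are rejected; a single voxel still closes a contour", {
  empty <- mask3d(array(0L, c(8, 8, 2)), voxel_size = c(1, 1))
  expect_error(measure_lesion(empty), "empty")
  # a closed boundary contour is never collinear, so even a one-voxel
  # ROI yields a (voxel-sized) ellipse rather than a degeneracy error
  tiny <- array(0L, c(8, 8, 1)); tiny[4, 4, 1] <- 1L
  m <- measure_lesion(mask3d(tiny, voxel_size = c(1, 1)))
  expect_lt(m$max_diameter_cm, 0.2)
})
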