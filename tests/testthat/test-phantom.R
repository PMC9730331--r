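test_that("lesion ground truth matches analytic ellipse formulas", {
  ph <- lesion_phantom(c(0.5, 0.3), n_slices = 1)
  tm <- ph$truth_measurements
  expect_equal(tm$diameter_cm, 1.0, tolerance = 1e-9)
  expect_equal(tm$volume_cc, pi * 0.5 * 0.3 * 0.6, tolerance = 1e-9)

  ph3 <- lesion_phantom(c(0.4, 0.25), n_slices = 3)
  expect_equal(ph3$truth_measurements$diameter_cm, 0.8, tolerance = 1e-9)
  expect_equal(ph3$truth_measurements$volume_cc,
               0.6 * 3 * pi * 0.4 * 0.25, tolerance = 1e-9)
})

test_that("phantom generation is deterministic given the seed", {
  a <- small_phantom(noise_sigma = 5, seed = 7L)
  b <- small_phantom(noise_sigma = 5, seed = 7L)
  c <- small_phantom(noise_sigma = 5, seed = 8L)
  expect_identical(a$volumes$dwi$data, b$volumes$dwi$data)
  expect_false(identical(a$volumes$dwi$data, c$volumes$dwi$data))
})

test_that("zones partition the gland and lesions stay inside it", {
  sp <- small_spec(lesions = list(
    lesion_spec(c(24, 28, 4), c(0.35, 0.2)),
    lesion_spec(c(18, 22, 3), c(0.3, 0.2)),
    lesion_spec(c(30, 22, 5), c(0.25, 0.15))))
  ph <- generate_phantom(sp)
  g <- ph$gland_truth$labels > 0
  pz <- ph$pz_truth$labels > 0
  tz <- ph$tz_truth$labels > 0
  # voxelwise partition
  expect_true(all((pz | tz) == g))
  expect_false(any(pz & tz))
  # lesions disjoint and inside the gland (brute-force voxel scan)
  les <- lapply(ph$lesion_truth, function(m) m$labels > 0)
  for (i in seq_along(les)) expect_true(all(g[les[[i]]]))
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(any(les[[i]] & les[[j]]))
})

test_that("noise-free phantoms are piecewise constant per region", {
  ph <- small_phantom()
  d <- ph$volumes$dwi$data
  g <- ph$gland_truth$labels > 0
  expect_equal(stats::sd(d[ph$pz_truth$labels > 0]), 0)
  expect_equal(stats::sd(d[ph$tz_truth$labels > 0]), 0)
  expect_equal(stats::sd(d[!g]), 0)
})

test_that("a lesion centred outside the gland is rejected by index", {
  sp <- small_spec(lesions = list(lesion_spec(c(2, 2, 1), c(0.3, 0.2))))
  expect_error(generate_phantom(sp), "lesion 1")
})

test_that("rician noise model produces nonnegative magnitude images", {
  ph <- small_phantom(noise_sigma = 10, noise_model = "rician")
  expect_true(all(ph$volumes$dwi$data >= 0))
})

test_that("feature table sampling matches its class parameters", {
  # large-sample mean of the score-5 diameter within 3 SE of 1.45 cm
  tab <- generate_feature_table(c("5" = 1000), seed = 42L)
  se <- 0.15 / sqrt(1000)
  expect_lt(abs(mean(tab$diameter_cm) - 1.45), 3 * se)
  expect_true(all(tab$diameter_cm > 0) && all(tab$volume_cc > 0))

  # degenerate SDs reproduce the class means exactly
  cp <- default_class_params <- data.frame(
    score = c(2L, 5L), diameter_mean = c(0.47, 1.45),
    diameter_sd = 0, volume_mean = c(0.13, 0.99), volume_sd = 0)
  tab0 <- generate_feature_table(c("2" = 5, "5" = 5), class_params = cp,
                                 seed = 1L)
  expect_equal(tab0$diameter_cm, rep(c(0.47, 1.45), each = 5))
  expect_equal(tab0$volume_cc, rep(c(0.13, 0.99), each = 5))

  # determinism and seed sensitivity
  expect_identical(generate_feature_table(c("3" = 10), seed = 3L),
                   generate_feature_table(c("3" = 10), seed = 3L))
  expect_false(identical(generate_feature_table(c("3" = 10), seed = 3L),
                         generate_feature_table(c("3" = 10), seed = 4L)))

  expect_error(generate_feature_table(c("7" = 10)), "unknown score")
})
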