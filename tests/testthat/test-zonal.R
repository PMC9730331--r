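test_that("atlas probabilities count zone occurrences", {
  fam <- atlas_family(n = 3)
  # identical subjects: probabilities are exactly 0 or 1
  same <- list(fam[[1]], fam[[1]], fam[[1]])
  atl <- build_atlas(same)
  expect_true(all(atl$p_pz %in% c(0, 1)))
  expect_equal(atl$statistical_atlas, fam[[1]]$volume$data)

  # two subjects differing at one voxel -> probability 0.5 there
  a <- fam[[1]]; b <- fam[[1]]
  pz_b <- b$pz$labels
  flip <- which(pz_b > 0)[1]
  pz_b[flip] <- 0L
  b2 <- list(volume = b$volume,
             pz = mask3d(pz_b, b$pz$voxel_size),
             tz = b$tz)
  atl2 <- build_atlas(list(a, b2))
  expect_equal(atl2$p_pz[flip], 0.5)

  # permutation invariance over training subjects
  atl_fwd <- build_atlas(fam)
  atl_rev <- build_atlas(rev(fam))
  expect_equal(atl_fwd$p_pz, atl_rev$p_pz)
  expect_equal(atl_fwd$statistical_atlas, atl_rev$statistical_atlas)

  bad <- list(volume = array(0, c(2, 2, 2)), pz = array(FALSE, c(2, 2, 2)),
              tz = array(FALSE, c(2, 2, 2)))
  expect_error(build_atlas(list(fam[[1]], bad)), "grid")
})

test_that("atlas probabilities decay outward across a jittered boundary", {
  fam <- atlas_family(n = 6, jitter = 0.05)
  atl <- build_atlas(fam)
  # along the posterior-normal (y) direction through the gland centre,
  # p_pz must be non-increasing from the PZ side to the TZ side
  prof <- atl$p_pz[24, , 4]
  band <- which(prof > 0 & prof < 1)
  if (length(band) >= 2)
    expect_true(all(diff(prof[min(band):max(band)]) <= 0) ||
                all(diff(prof[min(band):max(band)]) >= 0))
})

test_that("thresholding at 0.5 is strict: ties fall to the PV set", {
  dm <- c(3, 3, 1)
  atl <- structure(list(
    p_pz = array(c(0.9, 0.5, 0.2, rep(0, 6)), dm),
    p_tz = array(c(0.05, 0.5, 0.9, rep(0, 6)), dm),
    statistical_atlas = array(0, dm), mu_pz = 0.8, mu_tz = 0.5,
    n_subjects = 2), class = "probabilistic_atlas")
  gland <- array(c(rep(TRUE, 3), rep(FALSE, 6)), dm)
  z <- threshold_zones(atl, gland, 0.5)
  expect_true(z$pz[1, 1, 1])    # p_pz = 0.9 -> PZ
  expect_true(z$pv[2, 1, 1])    # both exactly 0.5 -> PV
  expect_true(z$tz[3, 1, 1])    # p_tz = 0.9 -> TZ
  expect_true(all((z$pz | z$tz | z$pv) == gland))
  expect_false(any(z$pz & z$tz) || any(z$pz & z$pv) || any(z$tz & z$pv))

  # empty gland -> three empty sets
  z0 <- threshold_zones(atl, array(FALSE, dm))
  expect_false(any(z0$pz) || any(z0$tz) || any(z0$pv))

  # extreme thresholds
  zlo <- threshold_zones(atl, gland, 0)
  expect_false(any(zlo$pv[c(1, 2, 3)]))   # every p > 0 voxel assigned
  zhi <- threshold_zones(atl, gland, 1)
  expect_true(all(zhi$pv == gland))       # nothing exceeds 1
})

test_that("partial-volume cost assigns voxels by the three terms", {
  dm <- c(5, 1, 1)
  # layout along x: [TZ, pv?, pv?, pv?, PZ]
  pz <- array(c(FALSE, FALSE, FALSE, FALSE, TRUE), dm)
  tz <- array(c(TRUE, FALSE, FALSE, FALSE, FALSE), dm)
  pv <- array(c(FALSE, TRUE, TRUE, TRUE, FALSE), dm)
  vol <- volume3d(array(c(50, 100, 75, 60, 100), dm), voxel_size = c(1, 1))
  atl <- structure(list(p_pz = array(0.4, dm), p_tz = array(0.4, dm),
                        statistical_atlas = array(0, dm),
                        mu_pz = 1, mu_tz = 0, n_subjects = 1),
                   class = "probabilistic_atlas")
  # equal probabilities; distance-neutral centre voxel with intensity
  # exactly the PZ mean -> PZ
  res <- pv_correct(pv, vol, atl, pz, tz,
                    pv_cost_params(w_int = 1, w_prob = 0, w_dist = 0))
  expect_true(res$pz[3, 1, 1])      # 75 is neither mean; normalized
  expect_true(res$pz[2, 1, 1])      # 100 = max -> normalized 1 = mu_pz
  expect_true(res$tz[4, 1, 1])      # 60 closer to the TZ mean (50)
  # distance-only: voxel 2 adjacent to TZ -> TZ, voxel 4 adjacent to PZ
  resd <- pv_correct(pv, vol, atl, pz, tz,
                     pv_cost_params(w_int = 0, w_prob = 0, w_dist = 1))
  expect_true(resd$tz[2, 1, 1])
  expect_true(resd$pz[4, 1, 1])
  # exact tie goes to PZ by default
  expect_true(resd$pz[3, 1, 1])
  # zero PV voxels: output equals input
  res0 <- pv_correct(array(FALSE, dm), vol, atl, pz, tz)
  expect_identical(res0$pz, pz)
  expect_identical(res0$tz, tz)
  expect_error(pv_correct(pv, vol, atl, array(FALSE, dm), tz),
               "zone statistics")
})

test_that("zonal segmentation partitions the gland exactly", {
  fam <- atlas_family(n = 4, jitter = 0.06)
  atl <- build_atlas(fam[-1])
  target <- fam[[1]]$phantom
  zones <- segment_zones(target$gland_truth, target$volumes$dwi, atl)
  g <- target$gland_truth$labels > 0
  pz <- zones$pz$labels > 0
  tz <- zones$tz$labels > 0
  expect_true(all((pz | tz) == g))
  expect_equal(sum(pz & tz), 0)
})
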