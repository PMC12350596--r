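# ROI measurement and volumetry: arithmetic, ordering invariance,
# deterministic automatic placement, and the full noiseless measurement
# chain.

make_uniform_volume <- function(value, grid = c(40, 40, 10)) {
  array(value, dim = grid)
}

four_rois <- function(radius_mm = 5) {
  roi_set(tibble::tibble(cx = c(12, 12, 28, 28), cy = c(12, 28, 12, 28),
                         slice = 5, radius_mm = radius_mm))
}

test_that("uniform liver at 60 HU measures exactly 60", {
  expect_equal(
    measure_hepatic_mean(make_uniform_volume(60), four_rois(), c(1, 1, 1)),
    60)
})

test_that("hepatic mean is the unweighted mean of the four ROI means", {
  vol <- make_uniform_volume(0)
  rs <- four_rois()
  vals <- c(58, 60, 62, 64)
  for (i in 1:4) {
    r <- rs$liver[i, ]
    vox <- hepafunc:::roi_voxels(r, dim(vol), c(1, 1, 1))
    vol[cbind(vox, r$slice)] <- vals[i]
  }
  expect_equal(measure_hepatic_mean(vol, rs, c(1, 1, 1)), 61)
  # invariant to ROI ordering
  rs_rev <- roi_set(rs$liver[4:1, ])
  expect_equal(measure_hepatic_mean(vol, rs_rev, c(1, 1, 1)), 61)
})

test_that("ROIs overlapping non-target labels are rejected", {
  vol <- make_uniform_volume(60)
  mask <- array(TRUE, dim = dim(vol))
  mask[20:40, , ] <- FALSE
  expect_error(
    measure_hepatic_mean(vol, four_rois(), c(1, 1, 1), mask = mask),
    "outside the target organ", class = "hepafunc_roi_error")
})

test_that("enhancement is plain subtraction and antisymmetric", {
  expect_equal(enhancement(100, 40), 60)
  expect_equal(enhancement(40, 40), 0)
  expect_equal(enhancement(40, 50), -10)
  expect_equal(enhancement(37.2, 81.5), -enhancement(81.5, 37.2))
})

test_that("mask volume converts voxel counts to mL and is additive", {
  m <- array(FALSE, dim = c(20, 20, 20))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(mask_volume(m, c(1, 1, 1)), 1)
  expect_equal(mask_volume(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0)
  m2 <- array(FALSE, dim = c(10, 10, 10))
  m2[1:5, 1:5, 1:5] <- TRUE
  expect_equal(mask_volume(m2, c(2, 2, 2)), 1)
  # additivity over disjoint masks
  a <- array(FALSE, c(20, 20, 20)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(20, 20, 20)); b[10:12, , ] <- TRUE
  expect_equal(mask_volume(a | b, c(1, 2, 3)),
               mask_volume(a, c(1, 2, 3)) + mask_volume(b, c(1, 2, 3)))
  expect_error(mask_volume(a, c(1, 0, 1)), class = "hepafunc_spec_error")
})

test_that("automatic ROI placement is deterministic with the nominal radius", {
  ph <- generate_phantom(small_phantom_spec())
  rs1 <- auto_place_rois(ph$labels, ph$organ_levels, ph$spacing)
  rs2 <- auto_place_rois(ph$labels, ph$organ_levels, ph$spacing)
  expect_identical(rs1, rs2)
  expect_equal(nrow(rs1$liver), 4)
  expect_equal(unique(rs1$liver$radius_mm), sqrt(250 / pi), tolerance = 1e-12)
  # every hepatic ROI voxel lies inside the liver mask
  liver <- ph$labels == ph$organ_levels["liver"]
  for (i in 1:4) {
    vox <- hepafunc:::roi_voxels(rs1$liver[i, ], dim(ph$labels), ph$spacing)
    expect_true(all(liver[cbind(vox, rs1$liver$slice[i])]))
  }
})

test_that("a too-small organ raises an instructive placement error", {
  ps <- phantom_spec(grid = c(40, 40, 20), spacing = c(2, 2, 2),
                     organs = list(
                       liver = list(center = c(40, 40, 20), radii = c(8, 8, 8),
                                    phases = c(pre = 55)),
                       aorta = list(center = c(64, 64, 20), radii = c(6, 6, 10),
                                    phases = c(pre = 45))))
  ph <- generate_phantom(ps)
  expect_error(auto_place_rois(ph$labels, ph$organ_levels, ph$spacing),
               "nominal_area", class = "hepafunc_roi_error")
})

test_that("the noiseless measurement chain reproduces phantom intensities exactly", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  rs <- auto_place_rois(ph$labels, ph$organ_levels, ph$spacing)
  pre <- measure_hepatic_mean(ph$phases$pre, rs, ph$spacing)
  pvp <- measure_hepatic_mean(ph$phases$pvp, rs, ph$spacing)
  dp <- measure_hepatic_mean(ph$phases$dp, rs, ph$spacing)
  expect_equal(pre, 55)
  expect_equal(pvp, 118.7)
  expect_equal(dp, 90.6)
  iwr <- compute_iwr(enhancement(pvp, pre), enhancement(dp, pre))
  expect_equal(iwr, (63.7 - 35.6) / 63.7 * 100, tolerance = 1e-12)
})
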