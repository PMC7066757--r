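test_that("build_voi bounds the landmarks with a margin and validates", {
  img <- vol_image(array(0, c(120, 120, 60)), c(0.98, 0.98, 3),
                   origin = c(-30, -30, -30), modality = "CT")
  lm <- toy_landmarks()
  # femur landmarks span x [10, 60]; margin 20 mm at 0.98 mm spacing adds
  # ceil(20/0.98) = 21 voxels per side
  box <- build_voi(lm, "femur", img, margin_mm = c(20, 20, 20))
  expect_equal(box$lower[1], floor((10 + 30) / 0.98) - 21)
  expect_equal(box$upper[1], floor((60 + 30) / 0.98) + 21 + 1)
  # clamping: a margin pushing past the grid edge stops at the grid
  big <- build_voi(lm, "femur", img, margin_mm = c(500, 500, 500))
  expect_equal(big$lower, c(0L, 0L, 0L))
  expect_equal(big$upper, c(120L, 120L, 60L))
  # margin 0 bounds the landmarks exactly (every landmark inside, half-open)
  b0 <- build_voi(lm, "femur", img, margin_mm = c(0, 0, 0))
  idx <- world_to_index(img, unclass(lm)[VOI_LANDMARKS$femur, ])
  expect_true(all(t(idx) >= b0$lower - 1e-9))
  expect_true(all(t(idx) < b0$upper))
  # missing landmark errors by name
  lm2 <- landmark_set(unclass(lm)[rownames(lm) != "TibiaMedialPeak", ])
  expect_error(build_voi(lm2, "tibia", img), "TibiaMedialPeak")
  # monotone in margin: larger margins never shrink the box
  prev <- b0
  for (m in c(5, 10, 25, 60)) {
    bm <- build_voi(lm, "femur", img, margin_mm = rep(m, 3))
    expect_true(all(bm$lower <= prev$lower) && all(bm$upper >= prev$upper))
    prev <- bm
  }
})

test_that("crop preserves world coordinates and full-extent crop is identity", {
  img <- smooth_volume(c(12, 14, 10), seed = 4, spacing = c(1, 2, 3))
  full <- structure(list(bone = "femur", lower = c(0L, 0L, 0L),
                         upper = dim(img$voxels)), class = "voi_box")
  expect_equal(crop(img, full)$voxels, img$voxels)
  box <- structure(list(bone = "femur", lower = c(2L, 3L, 1L),
                        upper = c(9L, 11L, 8L)), class = "voi_box")
  cr <- crop(img, box)
  expect_equal(index_to_world(cr, c(0, 0, 0)),
               index_to_world(img, box$lower))
  expect_equal(cr$voxels[1, 1, 1], img$voxels[3, 4, 2])
})

test_that("segment_bone isolates bone and masks the dilated prosthesis", {
  # analytic phantom VOI: soft tissue 40, bone 700, implant 3000
  arr <- array(40, c(30, 30, 12))
  bone <- array(FALSE, dim(arr)); bone[8:22, 8:22, 3:10] <- TRUE
  arr[bone] <- 700
  imp <- array(FALSE, dim(arr)); imp[14:16, 14:16, 5:7] <- TRUE
  arr[imp] <- 3000
  voi <- vol_image(arr, c(1, 1, 3), modality = "CT")
  m <- segment_bone(voi, bone_low = 200, prosthesis_low = 2500)
  expect_true(m$prosthesis_excluded)
  imp_dil <- spectreg:::dilate_mask(imp, 2, 1)
  expect_equal(m$mask, bone & !imp_dil)
  # pre-operative branch: no implant voxels at all
  arr2 <- arr; arr2[imp] <- 700
  m2 <- segment_bone(vol_image(arr2, c(1, 1, 3), modality = "CT"))
  expect_false(m2$prosthesis_excluded)
  expect_equal(m2$mask, bone)
  # degenerate input: uniform air
  expect_warning(
    me <- segment_bone(toy_image(c(5, 5, 5), c(1, 1, 1), -1024)),
    "empty")
  expect_true(me$empty)
  expect_error(segment_bone(voi, bone_low = 3000, prosthesis_low = 2500),
               "below")
})

test_that("prosthesis dilation radii nest and segmentation commutes with crop", {
  arr <- array(FALSE, c(20, 20, 8)); arr[9:12, 9:12, 4:5] <- TRUE
  prev <- NULL
  for (r in 0:3) {
    cur <- spectreg:::dilate_mask(arr, r, 1)
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
  # segment-then-crop equals crop-then-segment when the crop keeps the
  # whole dilated prosthesis neighbourhood
  spec <- small_spec(seed = 6)
  scan <- generate_knee_phantom(spec, "postop")
  box <- build_voi(scan$landmarks, "tibia", scan$ct)
  m_crop_first <- segment_bone(crop(scan$ct, box))
  m_full <- segment_bone(scan$ct)
  sub <- m_full$mask[(box$lower[1] + 1):box$upper[1],
                     (box$lower[2] + 1):box$upper[2],
                     (box$lower[3] + 1):box$upper[3]]
  interior <- m_crop_first$mask
  # compare away from the crop boundary (dilation kernels see less context
  # at the edge)
  d <- dim(interior)
  i <- 4:(d[1] - 3); j <- 4:(d[2] - 3); k <- 3:(d[3] - 2)
  expect_equal(interior[i, j, k], sub[i, j, k])
})
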