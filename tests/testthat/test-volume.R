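test_that("vol_image validates its geometry and maps indices to world", {
  expect_error(vol_image(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(vol_image(matrix(0, 2, 2), c(1, 1, 1)), "3-D")
  img <- vol_image(array(0, c(4, 5, 6)), c(0.98, 0.98, 3), c(-10, 5, 2))
  w <- index_to_world(img, c(2, 3, 4))
  expect_equal(drop(w), c(-10 + 2 * 0.98, 5 + 3 * 0.98, 2 + 4 * 3))
  # index -> world -> index is exact for random fractional indices
  idx <- matrix(runif(30, 0, 3), 10, 3)
  expect_equal(world_to_index(img, index_to_world(img, idx)), idx,
               tolerance = 1e-12)
})

test_that("NIfTI round trip preserves voxels, spacing and origin", {
  for (spc in list(c(0.98, 0.98, 3), c(1.27, 1.27, 3))) {
    img <- vol_image(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spc,
                     c(-250, -250, 0), "CT")
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_image(img, f)
    back <- read_image(f, "CT")
    expect_equal(back$voxels, img$voxels)
    expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
    expect_equal(back$origin, img$origin, tolerance = 1e-6)
  }
  # integer voxels survive bitwise
  imi <- vol_image(array(sample.int(1000, 60), c(3, 4, 5)), c(1, 1, 1),
                   modality = "SPECT")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_image(imi, f)
  expect_identical(as.numeric(read_image(f, "SPECT")$voxels),
                   as.numeric(imi$voxels))
})

test_that("read_paired_scan validates inputs and reads header geometry", {
  dir <- withr::local_tempdir()
  ct <- vol_image(array(rnorm(60), c(4, 5, 3)), c(0.98, 0.98, 3),
                  modality = "CT")
  sp <- vol_image(array(runif(60), c(4, 5, 3)), c(4.79, 4.79, 4.79),
                  modality = "SPECT")
  write_image(ct, file.path(dir, "ct.nii.gz"))
  write_image(sp, file.path(dir, "spect.nii.gz"))
  writeLines("FKC 1 2 3", file.path(dir, "lm.txt"))
  scan <- read_paired_scan(file.path(dir, "ct.nii.gz"),
                           file.path(dir, "spect.nii.gz"),
                           file.path(dir, "lm.txt"), "L", "preop")
  expect_equal(scan$ct$spacing, c(0.98, 0.98, 3), tolerance = 1e-6)
  expect_equal(scan$spect$spacing, rep(4.79, 3), tolerance = 1e-6)
  # unknown landmark name lists the valid names
  writeLines("FHC 1 2 3", file.path(dir, "bad.txt"))
  expect_error(read_landmarks(file.path(dir, "bad.txt")), "FHC")
  expect_error(read_landmarks(file.path(dir, "bad.txt")), "FKC")
  # DICOM series directories are rejected with guidance
  expect_error(read_image(dir, "CT"), "DICOM")
})

test_that("resample preserves physical extent and interpolates sanely", {
  # SPECT 128^3 at 4.79 mm onto the common grid: extent-preserving dims
  expect_identical(spectreg:::resample_dims(c(128, 128, 128), rep(4.79, 3),
                                            c(0.98, 0.98, 3)),
                   c(626L, 626L, 205L))
  img <- smooth_volume(c(12, 12, 12), seed = 2)
  # identity spacing + nearest leaves the grid untouched
  same <- resample(img, img$spacing, "nearest")
  expect_equal(same$voxels, img$voxels)
  # a constant image stays constant inside the extent under every scheme
  const <- toy_image(c(10, 10, 10), c(2, 2, 2), value = 7)
  for (m in c("nearest", "linear", "cubic_bspline")) {
    out <- resample(const, c(1.3, 1.7, 2.9), m)
    inside <- out$voxels[2:13, 2:10, 1:6]
    expect_equal(inside, array(7, dim(inside)), tolerance = 1e-6)
  }
  # down-up round trip of a smooth phantom: MAE under 1% of dynamic range
  sm <- smooth_volume(c(24, 24, 24), seed = 3, spacing = c(1, 1, 1))
  down <- resample(sm, c(1.5, 1.5, 1.5), "linear")
  up <- resample(down, c(1, 1, 1), "linear")
  core <- 3:20
  mae <- mean(abs(up$voxels[core, core, core] -
                    sm$voxels[core, core, core]))
  expect_lt(mae, 0.01 * diff(range(sm$voxels)))
  expect_error(resample(img, c(0, 1, 1)), "positive")
})

test_that("sagittal reflection mirrors voxels and landmarks consistently", {
  spec <- small_spec(seed = 5)
  scan <- generate_knee_phantom(spec, "postop")
  scan$laterality <- "R"
  left <- reflect_sagittal(scan)
  expect_equal(left$laterality, "L")
  # voxel multiset (intensity histogram) unchanged
  expect_equal(sort(as.numeric(left$ct$voxels)),
               sort(as.numeric(scan$ct$voxels)))
  # index i maps to N-1-i; landmark x maps to 2*xc - x
  xc <- spectreg:::grid_center(scan$ct)[1]
  expect_equal(unclass(left$landmarks)[, 1],
               2 * xc - unclass(scan$landmarks)[, 1])
  d1 <- dim(scan$ct$voxels)[1]
  expect_equal(left$ct$voxels[d1 - 10, 20, 30], scan$ct$voxels[11, 20, 30])
  # mirrored landmark sits on the mirrored intensity feature: the FME voxel
  # value in the left image equals the original value at the original FME
  v_at <- function(img, p) {
    i <- round(world_to_index(img, p))
    img$voxels[i[1] + 1, i[2] + 1, i[3] + 1]
  }
  expect_equal(v_at(left$ct, unclass(left$landmarks)["FME", ]),
               v_at(scan$ct, unclass(scan$landmarks)["FME", ]))
  # involution: reflecting back restores everything
  left$laterality <- "R"
  back <- reflect_sagittal(left)
  expect_equal(back$ct$voxels, scan$ct$voxels)
  expect_equal(unclass(back$landmarks), unclass(scan$landmarks))
  # left input is a no-op
  expect_identical(reflect_sagittal(back), back)
})
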