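test_that("phantom generation is a pure function of spec and seed", {
  spec <- small_spec(seed = 3)
  a <- generate_knee_phantom(spec, "postop")
  b <- generate_knee_phantom(spec, "postop")
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$spect$voxels, b$spect$voxels)
  spec2 <- small_spec(seed = 4)
  expect_false(identical(generate_knee_phantom(spec2)$ct$voxels,
                         a$ct$voxels))
})

test_that("voxelized bone volume matches a fine-grid geometric oracle", {
  # 1 mm rendering vs an independent 0.5 mm numeric integration of the
  # same solids
  spec <- phantom_spec(dims = c(150, 150, 160), spacing = c(1, 1, 1),
                       ct_noise_sd = 0, texture_amp = c(bone = 0, soft = 0),
                       implant = FALSE, seed = 1)
  ph <- generate_knee_phantom(spec, "preop")
  vol_1mm <- sum(ph$ct$voxels >= 200)  # bone voxels at 1 mm^3 each
  Wf <- spectreg:::grid_world(c(300, 300, 320), c(0.5, 0.5, 0.5))
  fine <- spectreg:::phantom_bone_masks(spec$geom, Wf)$bone
  vol_fine <- sum(fine) * 0.5^3
  expect_equal(vol_1mm, vol_fine, tolerance = 0.05)
})

test_that("implant voxels appear only in post-operative scans", {
  spec <- small_spec(seed = 8)
  post <- generate_knee_phantom(spec, "postop")
  expect_gt(sum(post$ct$voxels >= 2500), 0)
  pre <- generate_knee_phantom(spec, "preop")
  expect_equal(sum(pre$ct$voxels >= 2500), 0)
  spec_off <- small_spec(seed = 8, implant = FALSE)
  expect_equal(sum(generate_knee_phantom(spec_off,
                                         "postop")$ct$voxels >= 2500), 0)
})

test_that("SPECT uptake co-localizes with the CT bone", {
  spec <- small_spec(seed = 9)
  ph <- generate_knee_phantom(spec, "postop")
  sp_ct <- resample(ph$spect, ph$ct$spacing, "linear")
  bone <- segment_bone(ph$ct)$mask
  bone_dil <- spectreg:::dilate_mask(bone, 4, 2)
  ds <- dim(sp_ct$voxels)
  hot <- which(sp_ct$voxels > quantile(sp_ct$voxels, 0.995))
  k <- (hot - 1) %/% (ds[1] * ds[2])
  j <- ((hot - 1) %/% ds[1]) %% ds[2]
  i <- (hot - 1) %% ds[1]
  dc <- dim(bone)
  keep <- i < dc[1] & j < dc[2] & k < dc[3]
  expect_gt(mean(bone_dil[cbind(i, j, k)[keep, ] + 1]), 0.95)
})

test_that("ground-truth deformations invert and apply as the pull-back", {
  # identity deformation leaves voxels untouched under nearest resampling
  spec <- small_spec(seed = 10)
  ph <- generate_knee_phantom(spec, "postop")
  id <- ground_truth_deformation("rigid")
  same <- apply_ground_truth(ph, id, interpolator = "nearest")
  expect_equal(same$ct$voxels, ph$ct$voxels)
  # a one-voxel translation equals an index shift
  tr <- ground_truth_deformation("rigid",
                                 translation = c(ph$ct$spacing[1], 0, 0))
  shifted <- apply_ground_truth(ph, tr, interpolator = "nearest")
  d1 <- dim(ph$ct$voxels)[1]
  expect_equal(shifted$ct$voxels[2:d1, , ], ph$ct$voxels[1:(d1 - 1), , ])
  expect_equal(unclass(shifted$landmarks)[, 1],
               unclass(ph$landmarks)[, 1] + ph$ct$spacing[1])
  # forward o inverse = identity on a probe grid, for every kind
  ctr <- spec$dims * spec$spacing / 2
  gts <- list(
    random_rigid_scaling(3L, center = ctr),
    ground_truth_deformation("affine",
                             A = diag(3) + matrix(runif(9, -0.05, 0.05), 3),
                             translation = c(4, -2, 1), center = ctr),
    ground_truth_deformation("bspline", bspline = {
      tf <- bspline_transform(ctr - 80, c(40, 40, 40), c(5, 5, 5))
      set.seed(2)
      tf$coef[] <- runif(length(tf$coef), -6, 6)
      tf
    }))
  probe <- as.matrix(expand.grid(ctr[1] + seq(-20, 20, length = 10),
                                 ctr[2] + seq(-20, 20, length = 10),
                                 ctr[3] + seq(-20, 20, length = 10)))
  for (gt in gts) {
    fw <- transform_point(gt$forward, probe)
    back <- transform_point(gt$inverse, fw)
    expect_lt(max(abs(back - probe)), 1e-3)
  }
})

test_that("cohorts record their anthropometric and misalignment truths", {
  spec <- small_spec(seed = 12)
  co <- generate_cohort(3, spec, scale_range = 0.10, seed = 5)
  expect_length(co, 3)
  expect_null(co[[1]]$anat)        # subject 1 is the base/reference
  for (i in 2:3) {
    s <- diag(co[[i]]$anat$A)
    expect_true(all(s >= 0.9 & s <= 1.1))
  }
  # the pre-operative scan is the implant-free anatomy, misaligned
  expect_equal(sum(co[[2]]$preop$ct$voxels >= 2500), 0)
  expect_gt(sum(co[[2]]$postop$ct$voxels >= 2500), 0)
  expect_s3_class(co[[2]]$gt, "gt_deformation")
  # single-subject cohort renders the base spec
  one <- generate_cohort(1, spec, seed = 5)
  expect_length(one, 1)
})
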