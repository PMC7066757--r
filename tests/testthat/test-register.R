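# Registration unit checks run reduced iteration budgets (see
# helper-fixtures.R); the full tuned configuration is exercised by the
# acceptance suite.

make_pair <- function(seed = 20, translation = NULL) {
  spec <- small_spec(seed = seed)
  post <- generate_knee_phantom(spec, "postop")
  spec_pre <- spec
  spec_pre$implant <- FALSE
  spec_pre$seed <- seed + 1000L
  pre <- generate_knee_phantom(spec_pre, "preop")
  if (!is.null(translation)) {
    gt <- ground_truth_deformation("rigid", translation = translation)
    pre <- apply_ground_truth(pre, gt)
  }
  list(post = post, pre = pre)
}

test_that("self-registration stays at the identity", {
  spec <- small_spec(seed = 30)
  ph <- generate_knee_phantom(spec, "postop")
  voi <- build_voi(ph$landmarks, "femur", ph$ct)
  fixed <- crop(ph$ct, voi)
  mask <- segment_bone(fixed)
  res <- suppressWarnings(
    register_affine(fixed, fixed, mask, fast_affine(), seed = 1))
  d <- dim(fixed$voxels)
  corners <- index_to_world(fixed, as.matrix(expand.grid(
    c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1))))
  moved <- predict(res, corners)
  err_vox <- abs(moved - corners) / rep(fixed$spacing, each = 8)
  expect_lt(max(err_vox), 0.5)
})

test_that("a known rigid translation is recovered within a voxel", {
  pair <- make_pair(21, translation = c(6, -4, 5))
  res <- suppressWarnings(
    register_intra(pair$post, pair$pre, bone = "femur",
                   config = fast_affine(), seed = 2,
                   resample_spect = FALSE))
  # the recovered pull-back should map fixed points by about +(6,-4,5)
  p <- unclass(pair$post$landmarks)[c("FKC", "FME", "FLE", "FTP"), ]
  err <- transform_point(res$transform, p) - sweep(p, 2, c(6, -4, 5), "+")
  err_vox <- abs(err) / rep(pair$post$ct$spacing, each = 4)
  expect_lt(max(err_vox), 1)
  # the metric improved over the run (median across stages)
  s <- summary(res)
  expect_gte(median(s$stage_gain), 0)
})

test_that("registration is deterministic given config and seed", {
  pair <- make_pair(22, translation = c(4, 3, -3))
  cfg <- fast_affine(max_iterations = 60L)
  r1 <- suppressWarnings(register_intra(pair$post, pair$pre,
                                        config = cfg, seed = 5,
                                        resample_spect = FALSE))
  r2 <- suppressWarnings(register_intra(pair$post, pair$pre,
                                        config = cfg, seed = 5,
                                        resample_spect = FALSE))
  expect_identical(r1$transform$A, r2$transform$A)
  expect_identical(r1$transform$t, r2$transform$t)
  r3 <- suppressWarnings(register_intra(pair$post, pair$pre,
                                        config = cfg, seed = 6,
                                        resample_spect = FALSE))
  expect_false(identical(r1$transform$t, r3$transform$t))
})

test_that("the shared-transform contract applies the CT transform to SPECT", {
  pair <- make_pair(23, translation = c(5, 0, 3))
  res <- suppressWarnings(
    register_intra(pair$post, pair$pre, bone = "femur",
                   config = fast_affine(), seed = 3))
  expect_s3_class(res$spect_aligned, "vol_image")
  expect_equal(dim(res$spect_aligned$voxels), dim(res$fixed$voxels))
  # the SPECT was resampled through exactly the same parameters object
  again <- resample_moving(pair$pre$spect, res$transform, res$fixed,
                           interpolator = "linear")
  expect_identical(res$spect_aligned$voxels, again$voxels)
})

test_that("B-spline self-registration keeps displacements sub-voxel and
          refines an affine start", {
  spec <- small_spec(seed = 31)
  ph <- generate_knee_phantom(spec, "postop")
  voi <- build_voi(ph$landmarks, "femur", ph$ct)
  fixed <- crop(ph$ct, voi)
  mask <- segment_bone(fixed, prosthesis_low = Inf)
  res <- suppressWarnings(
    register_bspline(fixed, fixed, fast_bspline(),
                     initial = affine_transform(), fixed_mask = mask,
                     seed = 4))
  expect_s3_class(res$bspline, "bspline_transform")
  expect_lt(max(abs(res$bspline$coef)), 0.5 * min(fixed$spacing))
  # stage-1 control spacing: base (32,32,16) voxels times multiplier (8,8,4)
  cfg <- registration_config("bspline")
  expect_equal(cfg$grid_spacing_voxels * cfg$grid_multipliers[[1]],
               c(256, 256, 64))
})

test_that("inter-subject registration of a subject to itself is near
          identity", {
  spec <- small_spec(seed = 32)
  ph <- generate_knee_phantom(spec, "postop")
  res <- suppressWarnings(
    register_inter(ph, ph, bone = "femur",
                   config_affine = fast_affine(max_iterations = 80L),
                   config_bspline = fast_bspline(max_iterations = 40L),
                   seed = 7))
  p <- unclass(ph$landmarks)[c("FKC", "FME", "FLE", "FTP"), ]
  moved <- transform_point(res$transform, p)
  err_vox <- abs(moved - p) / rep(ph$ct$spacing, each = 4)
  expect_lt(max(err_vox), 1)
})

test_that("registration configs serialize to YAML and back", {
  f <- withr::local_tempfile(fileext = ".yaml")
  for (mode in c("affine", "bspline")) {
    cfg <- registration_config(mode)
    write_config(cfg, f)
    back <- read_config(f)
    expect_equal(back$metric, cfg$metric)
    expect_equal(back$histogram_bins, cfg$histogram_bins)
    expect_equal(back$max_iterations, cfg$max_iterations)
    expect_equal(back$smoothing_factors, cfg$smoothing_factors)
    if (mode == "bspline")
      expect_equal(back$grid_multipliers, cfg$grid_multipliers)
  }
  expect_error(registration_config("affine", nonsense = 1), "unknown")
})
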