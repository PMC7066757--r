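test_that("the normalization ROI has the documented geometry", {
  grid <- toy_image(c(160, 160, 80), c(0.98, 0.98, 3), modality = "SPECT")
  fkc <- c(78, 78, 123)
  roi <- build_normalization_roi(fkc, grid)
  expect_equal(roi_voxel_count(roi), 2100)
  expect_equal(roi$dims, c(35L, 20L, 3L))
  # the box starts 100 mm distal to the FKC along +z
  expect_equal(roi$lower[3], round((123 + 100) / 3))
  # single-voxel box at the offset position
  r1 <- build_normalization_roi(fkc, grid, dims_voxels = c(1, 1, 1))
  expect_equal(roi_voxel_count(r1), 1)
  expect_equal(r1$lower, as.integer(round(c(78 / 0.98, 78 / 0.98,
                                            223 / 3))))
  # offset 0 anchors the box at the FKC slice
  r0 <- build_normalization_roi(fkc, grid, dims_voxels = c(5, 5, 1),
                                offset_mm = 0)
  expect_equal(r0$lower[3], round(123 / 3))
  # a box leaving the grid is refused with advice
  expect_error(build_normalization_roi(c(78, 78, 200), grid),
               "smaller offset")
})

test_that("uptake normalization divides by the ROI mean", {
  grid <- toy_image(c(60, 60, 80), c(2, 2, 3), modality = "SPECT")
  fkc <- c(60, 60, 100)
  roi <- build_normalization_roi(fkc, grid, dims_voxels = c(10, 10, 2))
  const <- grid; const$voxels[] <- 5
  out <- normalize_uptake(const, roi)
  expect_equal(out$voxels, array(1, dim(out$voxels)))
  expect_equal(attr(out, "normalization_mean"), 5)
  # phantom-style case: ROI mean 250, hotspot 1000 -> normalized 4
  img <- grid; img$voxels[] <- 250; img$voxels[10, 10, 10] <- 1000
  n <- normalize_uptake(img, roi)
  expect_equal(n$voxels[10, 10, 10], 4, tolerance = 1e-3)
  # ROI mean of the output is exactly one; scale invariance
  set.seed(1)
  img$voxels[] <- rexp(length(img$voxels)) + 0.1
  n1 <- normalize_uptake(img, roi)
  expect_equal(mean(spectreg:::roi_values(n1, roi)), 1)
  img10 <- img; img10$voxels <- img$voxels * 17.3
  expect_equal(normalize_uptake(img10, roi)$voxels, n1$voxels,
               tolerance = 1e-12)
  bad <- grid; bad$voxels[] <- 0
  expect_error(normalize_uptake(bad, roi), "positive")
})

test_that("difference maps subtract voxelwise and are antisymmetric", {
  a <- smooth_volume(c(8, 8, 8), seed = 1, modality = "SPECT")
  b <- smooth_volume(c(8, 8, 8), seed = 2, modality = "SPECT")
  expect_equal(difference_map(a, a)$voxels, array(0, c(8, 8, 8)))
  shifted <- a; shifted$voxels <- a$voxels + 0.3
  expect_equal(difference_map(shifted, a)$voxels, array(0.3, c(8, 8, 8)))
  expect_equal(difference_map(a, b)$voxels, -difference_map(b, a)$voxels)
  c <- b; c$spacing <- c(2, 2, 2)
  expect_error(difference_map(a, c), "same grid")
})

test_that("aggregate maps average with counts, NA exclusion and symmetry", {
  maps <- lapply(1:4, function(s) {
    m <- smooth_volume(c(6, 6, 6), seed = s, modality = "SPECT")
    class(m) <- c("diff_map", class(m))
    m
  })
  expect_error(aggregate_map(list()), "at least one")
  one <- aggregate_map(maps[1])
  expect_equal(one$mean$voxels, maps[[1]]$voxels)
  # m and -m average to zero
  neg <- maps[[1]]; neg$voxels <- -neg$voxels
  expect_equal(aggregate_map(list(maps[[1]], neg))$mean$voxels,
               array(0, c(6, 6, 6)))
  # permutation invariance
  agg1 <- aggregate_map(maps)
  agg2 <- aggregate_map(maps[c(3, 1, 4, 2)])
  expect_equal(agg1$mean$voxels, agg2$mean$voxels)
  expect_equal(agg1$sd, agg2$sd)
  # NA voxels are excluded from that voxel's mean and count
  maps[[2]]$voxels[1, 1, 1] <- NA
  agg <- aggregate_map(maps)
  expect_equal(agg$count[1, 1, 1], 3L)
  expect_equal(agg$mean$voxels[1, 1, 1],
               mean(vapply(maps[c(1, 3, 4)],
                           function(m) m$voxels[1, 1, 1], 0)))
  # linearity: aggregate of differences equals difference of means when
  # every voxel has a full count
  pres <- lapply(5:7, function(s) smooth_volume(c(6, 6, 6), seed = s,
                                                modality = "SPECT"))
  posts <- lapply(8:10, function(s) smooth_volume(c(6, 6, 6), seed = s,
                                                  modality = "SPECT"))
  dm <- Map(difference_map, posts, pres)
  agg_d <- aggregate_map(dm)$mean$voxels
  mean_arr <- function(l) Reduce(`+`, lapply(l, `[[`, "voxels")) / length(l)
  expect_equal(agg_d, mean_arr(posts) - mean_arr(pres), tolerance = 1e-12)
})
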