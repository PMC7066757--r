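test_that("Dice coefficient counts voxels exactly", {
  A <- array(FALSE, c(3, 3, 3)); B <- A
  A[1:4] <- TRUE              # |A| = 4
  B[2:7] <- TRUE              # |B| = 6, overlap {2,3,4} = 3
  r <- dice(A, B)
  expect_equal(r$dsc, 0.6)
  expect_equal(c(r$n_a, r$n_b, r$n_intersection), c(4L, 6L, 3L))
  expect_equal(dice(B, A)$dsc, r$dsc)      # symmetry
  expect_equal(dice(A, A)$dsc, 1)
  expect_equal(dice(A, !A)$dsc, 0)
  expect_message(z <- dice(A & FALSE, B & FALSE), "empty")
  expect_equal(z$dsc, 0)
  expect_error(dice(A, array(TRUE, c(2, 2, 2))), "congruent")
  # monotone: trading an unshared voxel in each mask for a shared one
  # never decreases DSC
  A2 <- A; B2 <- B
  A2[4] <- FALSE; A2[8] <- TRUE
  B2[7] <- FALSE; B2[8] <- TRUE
  expect_gte(dice(A2, B2)$dsc, r$dsc)
})

test_that("landmark differences follow the (2,2,0)-voxel criterion", {
  ref <- landmark_set(rbind(FKC = c(10, 10, 30), FME = c(30, 10, 30),
                            FLE = c(-10, 10, 30), FTP = c(10, -5, 10)))
  expect_true(landmark_error(ref, ref)$pass)
  # 1.96 mm at 0.98 mm spacing is exactly 2 voxels: the pass boundary
  sh <- unclass(ref); sh["FKC", 1] <- sh["FKC", 1] + 1.96
  r <- landmark_error(ref, landmark_set(sh), spacing = c(0.98, 0.98, 3))
  expect_equal(r$table$x[r$table$landmark == "FKC"], 2)
  expect_true(r$pass)
  # 3 mm at 3 mm slice thickness is 1 slice: fails the zero threshold
  sz <- unclass(ref); sz["FME", 3] <- sz["FME", 3] + 3
  r2 <- landmark_error(ref, landmark_set(sz), spacing = c(0.98, 0.98, 3))
  expect_false(r2$pass)
  expect_equal(r2$table$z[r2$table$landmark == "FME"], 1)
  # translation consistency: shifting both sets leaves zero differences
  shift <- c(5.5, -3.3, 7)
  both <- landmark_error(
    landmark_set(sweep(unclass(ref), 2, shift, "+")),
    landmark_set(sweep(unclass(ref), 2, shift, "+")))
  expect_true(all(both$table[, c("x", "y", "z")] == 0))
  expect_error(landmark_error(ref, landmark_set(rbind(FKC = c(0, 0, 0)))),
               "names differ")
  # rounding is half away from zero
  expect_equal(spectreg:::round_half_away(c(0.5, -0.5, 1.49, 2.5)),
               c(1, -1, 1, 3))
})

test_that("signed-rank comparison matches exact enumeration", {
  # all ties: degenerate, p = 1 by convention
  r0 <- compare_dsc_prepost(rep(0.8, 6), rep(0.8, 6))
  expect_equal(r0$p.value, 1)
  # n = 6, all improved: one-sided 1/64, two-sided 2/64
  pre <- c(0.70, 0.72, 0.74, 0.76, 0.78, 0.80)
  post <- pre + c(0.05, 0.06, 0.04, 0.07, 0.03, 0.08)
  r <- compare_dsc_prepost(pre, post)
  expect_equal(r$p.value, 2 / 64)
  expect_true(r$significant)    # 0.03125 < 0.05
  expect_error(compare_dsc_prepost(1:3 / 10, 1:4 / 10), "equal length")
  # a cohort with a genuine improvement is detected
  set.seed(9)
  pre10 <- runif(10, 0.70, 0.78)
  post10 <- pre10 + runif(10, 0.05, 0.15)
  expect_lt(compare_dsc_prepost(pre10, post10)$p.value, 0.05)
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  g1 <- c(0.9, 0.91, 0.92, 0.93)
  g2 <- c(0.70, 0.71, 0.72, 0.73)
  r <- compare_dsc_by_resolution(g1, g2)
  expect_equal(r$p.value, 2 / 70)       # U = 16 (or 0), exact two-sided
  expect_true(r$significant)
  # identical groups: no evidence of a difference
  expect_gt(compare_dsc_by_resolution(g1, g1)$p.value, 0.5)
  expect_error(compare_dsc_by_resolution(numeric(0), g2), "non-empty")
  # a constant shift smaller than the group separation keeps the exact
  # p-value (ranks unchanged)
  expect_equal(compare_dsc_by_resolution(g1 + 0.005, g2)$p.value,
               r$p.value)
})
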