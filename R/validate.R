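# Quantitative validation: Dice similarity coefficient, landmark distances
# against the (2, 2, 0)-voxel criterion, and the non-parametric tests.

#' Dice similarity coefficient of two binary masks
#'
#' Exact integer-count computation of `2 |A n B| / (|A| + |B|)`; defined as
#' 0 when both masks are empty.
#'
#' @param mask_a,mask_b `bone_mask` objects (or logical arrays) on
#'   congruent grids.
#' @param context optional free-form description carried in the result.
#' @return an object of class `dsc_result` with fields `dsc`, `n_a`, `n_b`,
#'   `n_intersection`.
#' @export
dice <- function(mask_a, mask_b, context = NULL) {
  a <- if (inherits(mask_a, "bone_mask")) mask_a$mask else mask_a
  b <- if (inherits(mask_b, "bone_mask")) mask_b$mask else mask_b
  if (!identical(dim(a), dim(b)))
    stop("masks must be on congruent grids")
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  dsc <- if (na + nb == 0L) {
    message("both masks empty; DSC defined as 0")
    0
  } else 2 * ni / (na + nb)
  structure(list(dsc = dsc, n_a = na, n_b = nb, n_intersection = ni,
                 context = context),
            class = "dsc_result")
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("<dsc_result> DSC = %.4f (|A| = %d, |B| = %d, |AnB| = %d)%s\n",
              x$dsc, x$n_a, x$n_b, x$n_intersection,
              if (is.null(x$context)) "" else paste0("  [", x$context, "]")))
  invisible(x)
}

# round half away from zero (Table-style voxel differences are integral per
# case even though averages are reported fractionally)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-axis landmark distances in voxels against the (2, 2, 0) criterion
#'
#' World coordinate differences are converted to voxel indices
#' (`|delta| / spacing`, rounded half away from zero) per axis; a landmark
#' passes when its differences are at most `threshold` on every axis. The
#' default threshold (2, 2, 0) demands in-plane agreement within two CT
#' voxels and the exact same slice, so registered points stay within one
#' SPECT voxel.
#'
#' @param reference_landmarks,mapped_landmarks [landmark_set()]s with the
#'   same names.
#' @param spacing voxel size in mm of the grid the criterion refers to.
#' @param threshold per-axis allowed voxel-index difference.
#' @return an object of class `landmark_error` whose `table` mirrors the
#'   per-landmark x/y/z layout, plus an overall `pass` flag.
#' @export
landmark_error <- function(reference_landmarks, mapped_landmarks,
                           spacing = c(0.98, 0.98, 3),
                           threshold = c(2, 2, 0)) {
  ra <- unclass(reference_landmarks); mb <- unclass(mapped_landmarks)
  if (!setequal(rownames(ra), rownames(mb)))
    stop("landmark names differ between the two sets")
  mb <- mb[rownames(ra), , drop = FALSE]
  dv <- abs(ra - mb)
  dvox <- sweep(dv, 2L, spacing, "/")
  dint <- round_half_away(dvox)
  pass <- dint[, 1] <= threshold[1] & dint[, 2] <= threshold[2] &
    dint[, 3] <= threshold[3]
  tab <- data.frame(landmark = rownames(ra), x = dint[, 1], y = dint[, 2],
                    z = dint[, 3], pass = pass, row.names = NULL)
  structure(list(table = tab, voxel_differences = dvox,
                 threshold = threshold, pass = all(pass)),
            class = "landmark_error")
}

#' @export
print.landmark_error <- function(x, ...) {
  cat(sprintf("<landmark_error> threshold (%s) voxels, %s\n",
              paste(x$threshold, collapse = ";"),
              if (x$pass) "PASS" else "FAIL"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Paired test of the effect of registration on DSC
#'
#' Two-sided Wilcoxon signed-rank test of post- versus pre-registration
#' DSC, with a Kolmogorov-Smirnov normality check of the paired
#' differences reported alongside. When every pair is tied the test is
#' degenerate and p = 1 is reported by convention.
#'
#' @param pre_values,post_values paired DSC vectors of equal length.
#' @param alpha significance level (default 0.05).
#' @return an object of class `dsc_test`.
#' @export
compare_dsc_prepost <- function(pre_values, post_values, alpha = 0.05) {
  if (length(pre_values) != length(post_values))
    stop("paired DSC vectors must have equal length")
  d <- post_values - pre_values
  norm_p <- if (length(unique(d)) > 1 && stats::sd(d) > 0)
    suppressWarnings(stats::ks.test((d - mean(d)) / stats::sd(d),
                                    "pnorm")$p.value)
  else NA_real_
  if (all(d == 0)) {
    res <- list(method = "Wilcoxon signed rank test (degenerate: all ties)",
                statistic = NA_real_, p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(post_values, pre_values,
                                              paired = TRUE, exact = TRUE))
    res <- list(method = wt$method, statistic = unname(wt$statistic),
                p.value = wt$p.value)
  }
  structure(c(res, list(normality_p = norm_p, alpha = alpha,
                        significant = res$p.value < alpha,
                        n = length(d))),
            class = "dsc_test")
}

#' Two-group test of the effect of CT resolution on DSC
#'
#' Two-sided Mann-Whitney U test between DSC values from same-resolution
#' and mixed-resolution scan pairs.
#'
#' @param group_same,group_diff DSC vectors for the two groups.
#' @param alpha significance level (default 0.05).
#' @return an object of class `dsc_test`.
#' @export
compare_dsc_by_resolution <- function(group_same, group_diff,
                                      alpha = 0.05) {
  if (!length(group_same) || !length(group_diff))
    stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(group_same, group_diff,
                                            exact = TRUE))
  structure(list(method = "Mann-Whitney U test",
                 statistic = unname(wt$statistic), p.value = wt$p.value,
                 alpha = alpha, significant = wt$p.value < alpha,
                 n = c(length(group_same), length(group_diff))),
            class = "dsc_test")
}

#' @export
print.dsc_test <- function(x, ...) {
  cat(sprintf("<dsc_test> %s\n  p = %.4g (%ssignificant at %.2g)\n",
              x$method, x$p.value, if (x$significant) "" else "not ",
              x$alpha))
  if (!is.null(x$normality_p) && is.finite(x$normality_p))
    cat(sprintf("  KS normality check of differences: p = %.4g\n",
                x$normality_p))
  invisible(x)
}
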