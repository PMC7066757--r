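# Intensity-statistics similarity metrics: sampled Parzen joint histograms,
# mutual information (MI) and normalized mutual information (NMI), with the
# analytic stochastic gradient used by the optimizer.

# dynamic range with percentile clipping (guards against metal-streak
# outliers inflating the histogram range)
intensity_range <- function(vals, clip = c(0.01, 0.99)) {
  r <- unname(stats::quantile(vals, probs = clip, names = FALSE,
                              type = 7))
  if (!all(is.finite(r))) stop("non-finite intensity range")
  if (r[2] <= r[1]) r[2] <- r[1] + 1e-6
  r
}

# continuous bin coordinate in [0, bins-1]
bin_coord <- function(v, range, bins) {
  u <- (v - range[1]) / (range[2] - range[1]) * (bins - 1)
  pmin(pmax(u, 0), bins - 1)
}

#' Sampled Parzen joint histogram
#'
#' For each sample point the fixed intensity is read at the point and the
#' moving intensity interpolated at `transform(point)`; points that map
#' outside the moving extent (or outside `moving_mask`, when given) are
#' discarded. Counts are spread over the two neighbouring bins per axis with
#' linear (first-order Parzen) weights and normalized to sum to one.
#'
#' @param fixed,moving `vol_image` objects.
#' @param transform fixed-to-moving world transform.
#' @param points n x 3 world points (from [sample_points()]).
#' @param bins histogram bins per axis (16 affine / 32 non-rigid defaults
#'   come from [registration_config()]).
#' @param interpolator moving-image interpolator, `"nearest"` or `"linear"`.
#' @param moving_mask optional `bone_mask` on the moving grid.
#' @param fixed_range,moving_range optional intensity ranges; default is the
#'   1--99 percentile range of each image.
#' @return bins x bins probability matrix (rows: fixed, columns: moving).
#' @export
joint_histogram <- function(fixed, moving, transform, points, bins = 16,
                            interpolator = c("linear", "nearest"),
                            moving_mask = NULL, fixed_range = NULL,
                            moving_range = NULL) {
  interpolator <- match.arg(interpolator)
  if (bins < 2) stop("'bins' must be at least 2")
  if (is.null(fixed_range)) fixed_range <- intensity_range(fixed$voxels)
  if (is.null(moving_range)) moving_range <- intensity_range(moving$voxels)
  fidx <- world_to_index(fixed, points)
  fvals <- if (interpolator == "nearest")
    interp_nearest(fixed$voxels, fidx, fill = NA_real_)
  else interp_linear(fixed$voxels, fidx, fill = NA_real_)$value
  q <- transform_world_safe(transform, points)
  mi <- world_to_index(moving, q$pts)
  mvals <- if (interpolator == "nearest")
    interp_nearest(moving$voxels, mi, fill = NA_real_)
  else interp_linear(moving$voxels, mi, fill = NA_real_)$value
  mvals[!q$ok] <- NA_real_
  if (!is.null(moving_mask)) {
    inm <- interp_nearest(moving_mask$mask + 0,
                          world_to_index(as_grid(moving_mask), q$pts),
                          fill = 0) > 0.5
    mvals[!inm] <- NA_real_
  }
  keep <- is.finite(fvals) & is.finite(mvals)
  if (!any(keep))
    stop("no sample point overlaps the moving image (empty joint histogram)")
  parzen_joint(fvals[keep], mvals[keep], fixed_range, moving_range, bins)
}

as_grid <- function(mask)
  list(spacing = mask$spacing, origin = mask$origin)

parzen_joint <- function(f, m, frange, mrange, bins) {
  uf <- bin_coord(f, frange, bins)
  um <- bin_coord(m, mrange, bins)
  f0 <- pmin(floor(uf), bins - 2); wf1 <- uf - f0; wf0 <- 1 - wf1
  m0 <- pmin(floor(um), bins - 2); wm1 <- um - m0; wm0 <- 1 - wm1
  idx <- c(1 + f0 + bins * m0, 2 + f0 + bins * m0,
           1 + f0 + bins * (m0 + 1), 2 + f0 + bins * (m0 + 1))
  w <- c(wf0 * wm0, wf1 * wm0, wf0 * wm1, wf1 * wm1)
  P <- numeric(bins * bins)
  acc <- rowsum(w, idx)
  P[as.integer(rownames(acc))] <- acc
  matrix(P / sum(P), bins, bins)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint probability matrix (bits)
#'
#' `MI = H(F) + H(M) - H(F, M)` with entropies in bits and `0 log 0 := 0`.
#'
#' @param joint probability matrix summing to one.
#' @return MI in bits (non-negative up to floating-point error).
#' @export
mutual_information <- function(joint) {
  check_joint(joint)
  entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint)) -
    entropy_bits(joint)
}

#' Normalized mutual information of a joint probability matrix
#'
#' `NMI = (H(F) + H(M)) / H(F, M)`, which lies in `[1, 2]`; identical
#' images give 2, independent images 1.
#'
#' @inheritParams mutual_information
#' @export
normalized_mutual_information <- function(joint) {
  check_joint(joint)
  hj <- entropy_bits(joint)
  if (hj <= 0)
    stop("degenerate joint histogram (single occupied cell): NMI undefined")
  (entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint))) / hj
}

check_joint <- function(joint) {
  if (!is.matrix(joint) || any(joint < -1e-12) ||
      abs(sum(joint) - 1) > 1e-6)
    stop("'joint' must be a probability matrix summing to 1")
  invisible(joint)
}

# d(metric)/dP for every histogram cell, with log arguments floored to keep
# empty-cell derivatives finite
metric_dP <- function(P, metric = c("NMI", "MI")) {
  metric <- match.arg(metric)
  eps <- 1e-12
  pf <- rowSums(P); pm <- colSums(P)
  lf <- log2(pmax(pf, eps)); lm <- log2(pmax(pm, eps))
  lj <- log2(pmax(P, eps))
  il2 <- 1 / log(2)
  if (metric == "MI") {
    sweep(sweep(lj, 1L, lf, "-"), 2L, lm, "-") - il2
  } else {
    hf <- entropy_bits(pf); hm <- entropy_bits(pm); hj <- entropy_bits(P)
    dhf <- -(lf + il2); dhm <- -(lm + il2); dhj <- -(lj + il2)
    outer(dhf, dhm, "+") / hj - (hf + hm) / hj^2 * dhj
  }
}

# One stochastic metric evaluation with gradient machinery.
#
# fvals: fixed intensities at the sample points (NA = invalid)
# midx:  continuous 0-based moving-grid indices of the transformed points
# Returns the metric value (computed from `value_interp` intensities), and
# for the retained points the derivative of the metric w.r.t. the moving
# intensity together with the trilinear moving-intensity gradient per voxel
# index, from which drivers chain d(point)/d(parameters).
metric_eval <- function(fvals, moving_arr, midx, bins, frange, mrange,
                        metric = c("NMI", "MI"),
                        value_interp = c("linear", "nearest"),
                        want_grad = TRUE) {
  metric <- match.arg(metric)
  value_interp <- match.arg(value_interp)
  lin <- interp_linear(moving_arr, midx, fill = NA_real_,
                       want_grad = want_grad)
  keep <- is.finite(fvals) & lin$inside
  if (sum(keep) < 8)
    stop("no overlap between fixed samples and the moving image")
  f <- fvals[keep]
  mlin <- lin$value[keep]
  P <- parzen_joint(f, mlin, frange, mrange, bins)
  value <- if (metric == "NMI") normalized_mutual_information(P)
           else mutual_information(P)
  if (value_interp == "nearest") {
    mnn <- interp_nearest(moving_arr, midx[keep, , drop = FALSE],
                          fill = NA_real_)
    ok <- is.finite(mnn)
    Pnn <- parzen_joint(f[ok], mnn[ok], frange, mrange, bins)
    value <- if (metric == "NMI") normalized_mutual_information(Pnn)
             else mutual_information(Pnn)
  }
  if (!want_grad)
    return(list(value = value, keep = keep))
  n <- sum(keep)
  L <- metric_dP(P, metric)
  uf <- bin_coord(f, frange, bins)
  um <- bin_coord(mlin, mrange, bins)
  f0 <- pmin(floor(uf), bins - 2); wf1 <- uf - f0; wf0 <- 1 - wf1
  m0 <- pmin(floor(um), bins - 2)
  dbin_dm <- (bins - 1) / (mrange[2] - mrange[1])
  # clamp: no gradient through saturated bin coordinates
  sat <- um <= 0 | um >= bins - 1
  # dP(f_bin, m0)/dm = -w_f/(N*binwidth), dP(f_bin, m0+1)/dm = +w_f/(...)
  iL <- function(fb, mb) L[cbind(fb + 1L, mb + 1L)]
  dC_dm <- (wf0 * (iL(f0, m0 + 1L) - iL(f0, m0)) +
              wf1 * (iL(f0 + 1L, m0 + 1L) - iL(f0 + 1L, m0))) *
    dbin_dm / n
  dC_dm[sat] <- 0
  list(value = value, keep = keep, dC_dm = dC_dm,
       dm_didx = lin$grad[keep, , drop = FALSE])
}
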