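# Radiotracer-uptake normalization, voxel-wise pre/post difference maps and
# cohort aggregate maps.

#' Build the uptake normalization region of interest
#'
#' A rectangular box of `dims_voxels` voxels (default 35 x 20 x 3 = 2100)
#' centred in-plane on the FKC landmark and starting `offset_mm` (default
#' 100 mm) distally along +z, used to estimate each subject's baseline
#' tracer metabolization.
#'
#' @param fkc world position (mm) of the femoral knee centre landmark.
#' @param grid the `vol_image` the ROI indexes (the resampled SPECT carried
#'   on the common grid).
#' @param dims_voxels box dimensions in voxels.
#' @param offset_mm distance from the FKC along +z to the start of the box.
#' @return an object of class `norm_roi` with 0-based half-open `lower` /
#'   `upper` index bounds.
#' @export
build_normalization_roi <- function(fkc, grid, dims_voxels = c(35, 20, 3),
                                    offset_mm = 100) {
  dims_voxels <- as.integer(rep_len(dims_voxels, 3L))
  stopifnot(all(dims_voxels >= 1L))
  ci <- round(world_to_index(grid, fkc))
  lower <- c(ci[1] - dims_voxels[1] %/% 2,
             ci[2] - dims_voxels[2] %/% 2,
             round((fkc[3] + offset_mm - grid$origin[3]) / grid$spacing[3]))
  upper <- lower + dims_voxels
  d <- img_dim(grid)
  if (any(lower < 0) || any(upper > d))
    stop("normalization ROI exits the grid; use a smaller offset or box ",
         "(need indices [", paste(lower, collapse = ","), ") to [",
         paste(upper, collapse = ","), ") in a ",
         paste(d, collapse = "x"), " grid)")
  structure(list(lower = as.integer(lower), upper = as.integer(upper),
                 dims = dims_voxels, anchor = as.numeric(fkc),
                 offset_mm = offset_mm,
                 grid_dims = d, spacing = grid$spacing,
                 origin = grid$origin),
            class = "norm_roi")
}

#' Number of voxels in a normalization ROI
#' @param roi a [build_normalization_roi()] result.
#' @export
roi_voxel_count <- function(roi) as.integer(prod(roi$dims))

#' @export
print.norm_roi <- function(x, ...) {
  cat(sprintf("<norm_roi> %d x %d x %d = %d voxels (%.1f mm^3), %g mm along +z from FKC\n",
              x$dims[1], x$dims[2], x$dims[3], roi_voxel_count(x),
              roi_voxel_count(x) * prod(x$spacing), x$offset_mm))
  invisible(x)
}

roi_values <- function(image, roi) {
  if (!identical(img_dim(image), roi$grid_dims))
    stop("image grid does not match the ROI's grid")
  image$voxels[(roi$lower[1] + 1):roi$upper[1],
               (roi$lower[2] + 1):roi$upper[2],
               (roi$lower[3] + 1):roi$upper[3]]
}

#' Normalize tracer uptake by the ROI mean
#'
#' Divides every voxel by the mean uptake inside the normalization ROI, so
#' the ROI mean of the output is exactly one and scans of subjects with
#' different tracer metabolization become comparable.
#'
#' @param spect a SPECT `vol_image` on the ROI's grid.
#' @param roi a [build_normalization_roi()] result.
#' @return the normalized `vol_image`; the normalization mean is attached
#'   as attribute `normalization_mean`.
#' @export
normalize_uptake <- function(spect, roi) {
  m <- mean(roi_values(spect, roi))
  if (!is.finite(m) || m <= 0)
    stop("ROI mean uptake is not positive; cannot normalize")
  spect$voxels <- spect$voxels / m
  attr(spect, "normalization_mean") <- m
  spect
}

#' Voxel-wise post-minus-pre uptake difference
#'
#' @param post_norm normalized post-operative SPECT.
#' @param pre_norm_in_post_space normalized pre-operative SPECT already
#'   resampled into the post-operative grid through the intra-subject
#'   transform.
#' @param subject_id carried into the result.
#' @return a `diff_map` (a `vol_image` subclass).
#' @export
difference_map <- function(post_norm, pre_norm_in_post_space,
                           subject_id = NULL) {
  a <- post_norm; b <- pre_norm_in_post_space
  if (!identical(img_dim(a), img_dim(b)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop("difference_map needs both volumes on the same grid")
  out <- a
  out$voxels <- a$voxels - b$voxels
  attr(out, "subject_id") <- subject_id
  class(out) <- c("diff_map", class(a))
  out
}

#' Cohort aggregate of difference maps
#'
#' Voxel-wise arithmetic mean over all co-registered subjects' difference
#' maps (all on the reference grid); voxels outside a subject's valid
#' extent (NA) are excluded from that voxel's mean, and the per-voxel
#' subject count is recorded. A per-voxel standard deviation companion is
#' included as an extension beyond the plain mean map.
#'
#' @param maps list of `diff_map`s on a common grid.
#' @return an object of class `aggregate_map` with fields `mean` (a
#'   `vol_image`), `count` and `sd` arrays.
#' @export
aggregate_map <- function(maps) {
  if (!length(maps)) stop("need at least one difference map")
  d <- img_dim(maps[[1]])
  for (m in maps)
    if (!identical(img_dim(m), d) ||
        max(abs(m$spacing - maps[[1]]$spacing)) > 1e-6 ||
        max(abs(m$origin - maps[[1]]$origin)) > 1e-6)
      stop("all difference maps must share the reference grid")
  n <- length(maps)
  sum1 <- array(0, d); sum2 <- array(0, d); cnt <- array(0L, d)
  for (m in maps) {
    v <- m$voxels
    ok <- is.finite(v)
    v[!ok] <- 0
    sum1 <- sum1 + v
    sum2 <- sum2 + v * v
    cnt <- cnt + ok
  }
  mu <- sum1 / pmax(cnt, 1L)
  mu[cnt == 0L] <- NA_real_
  va <- (sum2 - cnt * mu^2) / pmax(cnt - 1L, 1L)
  sd <- sqrt(pmax(va, 0))
  sd[cnt < 2L] <- NA_real_
  mean_img <- maps[[1]]
  mean_img$voxels <- mu
  class(mean_img) <- "vol_image"
  attr(mean_img, "subject_id") <- NULL
  structure(list(mean = mean_img, count = cnt, sd = sd, n_subjects = n),
            class = "aggregate_map")
}

#' @export
print.aggregate_map <- function(x, ...) {
  cat(sprintf("<aggregate_map> %d subjects, grid %s, mean range [%.3g, %.3g]\n",
              x$n_subjects, paste(img_dim(x$mean), collapse = " x "),
              min(x$mean$voxels, na.rm = TRUE),
              max(x$mean$voxels, na.rm = TRUE)))
  invisible(x)
}
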