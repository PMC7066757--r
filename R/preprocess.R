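# Landmark-driven volumes of interest and threshold-based bone segmentation.

#' Landmark subsets that define each bone's VOI
#'
#' The femoral set includes the fibula head alongside FTP/FLE/FME; an
#' alternative subset can be supplied to [build_voi()] via `landmark_names`.
#' @export
VOI_LANDMARKS <- list(
  femur = c("FibulaHead", "FTP", "FLE", "FME"),
  tibia = c("FKC", "TibiaLateralPeak", "TibiaMedialPeak"),
  patella = c("ProximalMargin", "DistalMargin", "LateralMargin",
              "MedialMargin"))

#' Build a cuboidal volume of interest around a bone's landmarks
#'
#' The box is the axis-aligned bounding box of the bone's landmark subset,
#' expanded by `margin_mm` per side (converted to voxels, rounded up) and
#' clamped to the image grid. Indices are 0-based, inclusive-lower /
#' exclusive-upper.
#'
#' @param landmarks a [landmark_set()].
#' @param bone `"femur"`, `"tibia"` or `"patella"`.
#' @param image the `vol_image` whose grid the box indexes (the resampled CT).
#' @param margin_mm per-axis margin in mm added on each side.
#' @param landmark_names optional character vector overriding the default
#'   landmark subset for the bone.
#' @return an object of class `voi_box` with fields `bone`, `lower`, `upper`.
#' @export
build_voi <- function(landmarks, bone = c("femur", "tibia", "patella"),
                      image, margin_mm = c(20, 20, 20),
                      landmark_names = NULL) {
  bone <- match.arg(bone)
  need <- if (is.null(landmark_names)) VOI_LANDMARKS[[bone]] else landmark_names
  missing <- setdiff(need, rownames(landmarks))
  if (length(missing))
    stop("missing landmark ", paste(missing, collapse = ", "),
         " required for the ", bone, " VOI")
  margin_mm <- rep_len(as.numeric(margin_mm), 3L)
  pts <- world_to_index(image, unclass(landmarks)[need, , drop = FALSE])
  mv <- ceiling(margin_mm / image$spacing - 1e-9)
  lo <- floor(apply(pts, 2, min)) - mv
  hi <- floor(apply(pts, 2, max)) + mv + 1
  d <- img_dim(image)
  lo <- pmax(as.integer(lo), 0L)
  hi <- pmin(as.integer(hi), d)
  if (any(hi <= lo))
    stop("degenerate ", bone, " VOI: landmark box lies outside the image grid")
  structure(list(bone = bone, lower = lo, upper = hi), class = "voi_box")
}

#' @export
print.voi_box <- function(x, ...) {
  cat(sprintf("<voi_box> %s: [%d,%d) x [%d,%d) x [%d,%d) voxels\n", x$bone,
              x$lower[1], x$upper[1], x$lower[2], x$upper[2],
              x$lower[3], x$upper[3]))
  invisible(x)
}

#' Crop a volume to a VOI
#'
#' The origin is shifted so every cropped voxel keeps its world coordinate.
#'
#' @param image a `vol_image`.
#' @param box a [build_voi()] box on the same grid.
#' @return the cropped `vol_image`.
#' @export
crop <- function(image, box) {
  stopifnot(inherits(box, "voi_box"))
  d <- img_dim(image)
  if (any(box$lower < 0) || any(box$upper > d))
    stop("VOI box exceeds the image grid")
  v <- image$voxels[(box$lower[1] + 1):box$upper[1],
                    (box$lower[2] + 1):box$upper[2],
                    (box$lower[3] + 1):box$upper[3], drop = FALSE]
  vol_image(v, spacing = image$spacing,
            origin = image$origin + box$lower * image$spacing,
            modality = image$modality)
}

#' Threshold-based bone segmentation with prosthesis masking
#'
#' Voxels with `bone_low <= HU < prosthesis_low` form the bone mask. Metal
#' voxels (`HU >= prosthesis_low`) are dilated by the configured radius (to
#' swallow residual streak artefacts around the implant) and removed from
#' the mask. Setting `prosthesis_low = Inf` disables prosthesis masking, as
#' used for inter-subject registration where all subjects carry the same
#' implant.
#'
#' @param ct_voi a CT `vol_image` (typically a VOI crop).
#' @param bone_low lower HU bound for bone (default 200, cancellous bone).
#' @param prosthesis_low lower HU bound for metal (default 2500).
#' @param dilate_inplane in-plane dilation radius of the metal mask, voxels.
#' @param dilate_slices dilation of the metal mask along z, slices.
#' @param bone optional bone label carried in the result.
#' @return an object of class `bone_mask` with the logical `mask`, the grid
#'   metadata, a `prosthesis_excluded` flag and an `empty` error flag.
#' @export
segment_bone <- function(ct_voi, bone_low = 200, prosthesis_low = 2500,
                         dilate_inplane = 2, dilate_slices = 1,
                         bone = NULL) {
  stopifnot(inherits(ct_voi, "vol_image"))
  if (ct_voi$modality != "CT") stop("bone segmentation expects a CT volume")
  if (bone_low >= prosthesis_low)
    stop("'bone_low' must be below 'prosthesis_low'")
  v <- ct_voi$voxels
  mask <- v >= bone_low & v < prosthesis_low
  pros <- v >= prosthesis_low
  excluded <- any(pros)
  if (excluded) {
    pros <- dilate_mask(pros, dilate_inplane, dilate_slices)
    mask <- mask & !pros
  }
  empty <- !any(mask)
  if (empty)
    warning("bone mask is empty (no voxel in [", bone_low, ", ",
            prosthesis_low, ") HU)")
  structure(list(mask = mask, bone = bone, prosthesis_excluded = excluded,
                 empty = empty, spacing = ct_voi$spacing,
                 origin = ct_voi$origin),
            class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  cat(sprintf("<bone_mask>%s %d of %d voxels%s%s\n",
              if (is.null(x$bone)) "" else paste0(" ", x$bone),
              sum(x$mask), length(x$mask),
              if (x$prosthesis_excluded) ", prosthesis excluded" else "",
              if (x$empty) ", EMPTY" else ""))
  invisible(x)
}

# binary dilation by a cylindrical structuring element: a disc of radius
# `r_inplane` in x/y, extended `r_slices` slices along z
dilate_mask <- function(mask, r_inplane, r_slices) {
  if (r_inplane <= 0 && r_slices <= 0) return(mask)
  d <- dim(mask)
  out <- mask
  offs <- expand.grid(dx = -r_inplane:r_inplane, dy = -r_inplane:r_inplane,
                      dz = -r_slices:r_slices)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_inplane^2 + 1e-9, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- shift_range(d[1], dx); sy <- shift_range(d[2], dy)
    sz <- shift_range(d[3], dz)
    out[sx$dst, sy$dst, sz$dst] <-
      out[sx$dst, sy$dst, sz$dst] | mask[sx$src, sy$src, sz$src]
  }
  out
}

shift_range <- function(n, s) {
  if (s >= 0) list(dst = (1 + s):n, src = 1:(n - s))
  else list(dst = 1:(n + s), src = (1 - s):n)
}
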