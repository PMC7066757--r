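#' Volumetric scalar image
#'
#' The basic container for a 3-D scan: a scalar voxel array together with the
#' geometric metadata that maps voxel indices to world (scanner) coordinates.
#' The grid axes follow the patient frame: axis 1 is the medio-lateral (x)
#' direction, axis 2 antero-posterior (y), axis 3 the transverse (z) axis.
#' The world position of 0-based voxel index (i, j, k) is
#' `origin + (i, j, k) * spacing`; no rotation is modelled (axis-aligned
#' acquisitions only).
#'
#' @param voxels numeric 3-D array of intensities (HU for CT, counts for
#'   SPECT).
#' @param spacing per-axis voxel size in mm, length 3, strictly positive.
#' @param origin world coordinate (mm) of the centre of voxel (0, 0, 0).
#' @param modality `"CT"` or `"SPECT"`.
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(voxels, spacing, origin = c(0, 0, 0),
                      modality = c("CT", "SPECT")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel sizes in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite world coordinates in mm")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 modality = modality),
            class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<vol_image> %s  %d x %d x %d voxels\n", x$modality,
              d[1], d[2], d[3]))
  cat(sprintf("  spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

img_dim <- function(image) dim(image$voxels)

#' Convert 0-based voxel indices to world coordinates
#'
#' @param image a `vol_image`.
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
index_to_world <- function(image, idx) {
  idx <- rbind3(idx)
  sweep(sweep(idx, 2L, image$spacing, "*"), 2L, image$origin, "+")
}

#' Convert world coordinates to 0-based (fractional) voxel indices
#'
#' @inheritParams index_to_world
#' @param pts n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @export
world_to_index <- function(image, pts) {
  pts <- rbind3(pts)
  sweep(sweep(pts, 2L, image$origin, "-"), 2L, image$spacing, "/")
}

# coerce a length-3 vector or n x 3 matrix to an n x 3 matrix
rbind3 <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns")
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 coordinates")
    matrix(as.numeric(p), 1L, 3L)
  }
}

# default out-of-extent fill per modality: air for CT, zero counts for SPECT
background_fill <- function(modality) if (modality == "CT") -1024 else 0

# physical centre of the grid (through voxel centres), used as mirror plane
grid_center <- function(image) {
  image$origin + (img_dim(image) - 1) / 2 * image$spacing
}

#' Canonical anatomical landmark names
#'
#' Femoral landmarks: fibula head, trochlea proximal (FTP), lateral (FLE) and
#' medial (FME) epicondyles. Tibial: femoral knee centre (FKC) and the tibial
#' lateral/medial peaks. Patellar: the four patella margins.
#' @export
LANDMARK_NAMES <- c("FibulaHead", "FTP", "FLE", "FME",
                    "FKC", "TibiaLateralPeak", "TibiaMedialPeak",
                    "ProximalMargin", "DistalMargin",
                    "LateralMargin", "MedialMargin")

#' Create a named landmark set
#'
#' @param points n x 3 numeric matrix of world coordinates (mm) with row
#'   names taken from [LANDMARK_NAMES].
#' @return n x 3 matrix of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (!is.matrix(points) || ncol(points) != 3L || is.null(rownames(points)))
    stop("'points' must be an n x 3 matrix with landmark row names")
  nm <- rownames(points)
  bad <- setdiff(nm, LANDMARK_NAMES)
  if (length(bad))
    stop("unknown landmark name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(LANDMARK_NAMES, collapse = ", "))
  if (anyDuplicated(nm)) stop("duplicated landmark names")
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  storage.mode(points) <- "double"
  class(points) <- c("landmark_set", "matrix", "array")
  points
}

#' Read a landmark file
#'
#' Plain-text format, one landmark per line: `NAME x y z` in world mm.
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no landmarks found in ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) != 4L))
    stop("malformed landmark line in ", path,
         " (expected 'NAME x y z' per line)")
  nm <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric landmark coordinate in ", path)
  rownames(xyz) <- nm
  landmark_set(xyz)
}

#' Write a landmark file
#' @param landmarks a [landmark_set()].
#' @param path destination file.
#' @export
write_landmarks <- function(landmarks, path) {
  writeLines(sprintf("%s %.9g %.9g %.9g", rownames(landmarks),
                     landmarks[, 1], landmarks[, 2], landmarks[, 3]), path)
  invisible(path)
}

#' Bundle a CT/SPECT pair with its landmarks
#'
#' The two volumes live on different grids but share one world (patient)
#' frame, so a spatial transform estimated on the CT applies verbatim to the
#' SPECT.
#'
#' @param ct,spect `vol_image` objects of the respective modality.
#' @param landmarks a [landmark_set()] in the shared world frame.
#' @param laterality `"L"` or `"R"`.
#' @param timepoint `"preop"` or `"postop"`.
#' @param subject_id identifier string.
#' @return An object of class `paired_scan`.
#' @export
paired_scan <- function(ct, spect, landmarks, laterality = c("L", "R"),
                        timepoint = c("preop", "postop"),
                        subject_id = "subject") {
  laterality <- match.arg(laterality)
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(ct, "vol_image"), inherits(spect, "vol_image"),
            inherits(landmarks, "landmark_set"))
  if (ct$modality != "CT" || spect$modality != "SPECT")
    stop("modalities must be CT and SPECT respectively")
  structure(list(ct = ct, spect = spect, landmarks = landmarks,
                 laterality = laterality, timepoint = timepoint,
                 subject_id = subject_id),
            class = "paired_scan")
}

#' @export
print.paired_scan <- function(x, ...) {
  cat(sprintf("<paired_scan> subject '%s', %s, laterality %s\n",
              x$subject_id, x$timepoint, x$laterality))
  print(x$ct); print(x$spect)
  cat(sprintf("  %d landmarks\n", nrow(x$landmarks)))
  invisible(x)
}

#' Write a volume as NIfTI-1
#'
#' Spacing and origin are stored in the qform; values survive a round trip
#' to at least 6 significant digits (NIfTI headers are single precision).
#'
#' @param image a `vol_image`.
#' @param path destination, `.nii` or `.nii.gz`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "vol_image"))
  arr <- image$voxels
  attr(arr, "pixdim") <- image$spacing
  nim <- RNifti::asNifti(arr)
  m <- diag(c(image$spacing, 1))
  m[1:3, 4] <- image$origin
  nim <- RNifti::`qform<-`(nim, structure(m, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Only axis-aligned acquisitions are supported: a header whose rotation part
#' is not the identity (up to voxel scaling) is rejected.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param modality `"CT"` or `"SPECT"`.
#' @return a `vol_image`.
#' @export
read_image <- function(path, modality = c("CT", "SPECT")) {
  modality <- match.arg(modality)
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series are not supported, ",
         "convert the series to NIfTI-1 (.nii/.nii.gz) first")
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume in ", path, ", got ",
         length(dim(arr)), " dimensions")
  m <- RNifti::xform(nim)
  spc <- RNifti::pixdim(nim)[1:3]
  rot <- m[1:3, 1:3]
  off <- rot - diag(diag(rot))
  if (max(abs(off)) > 1e-4 * max(abs(diag(rot))) || any(diag(rot) <= 0))
    stop("non-axis-aligned orientation in ", path,
         ": only identity direction cosines are supported")
  vol_image(arr, spacing = spc, origin = m[1:3, 4],
            modality = modality)
}

#' Read a CT/SPECT/landmark triplet
#'
#' @param ct_path,spect_path NIfTI files (DICOM series directories are
#'   rejected with a pointer to convert them first).
#' @param landmark_path landmark text file (`NAME x y z` per line).
#' @inheritParams paired_scan
#' @return a [paired_scan()].
#' @export
read_paired_scan <- function(ct_path, spect_path, landmark_path,
                             laterality = c("L", "R"),
                             timepoint = c("preop", "postop"),
                             subject_id = "subject") {
  ct <- read_image(ct_path, "CT")
  spect <- read_image(spect_path, "SPECT")
  lm <- read_landmarks(landmark_path)
  if (any(abs(ct$origin - spect$origin) > 1))
    warning("CT and SPECT origins differ by more than 1 mm; ",
            "both volumes are assumed to share one patient frame")
  paired_scan(ct, spect, lm, laterality = laterality, timepoint = timepoint,
              subject_id = subject_id)
}

# output grid size that covers the same physical extent
resample_dims <- function(dims, spacing, target_spacing) {
  as.integer(ceiling(dims * spacing / target_spacing - 1e-9))
}

#' Resample a volume to a new voxel size
#'
#' The output grid covers the same physical extent
#' (`dim_out = ceiling(dim_in * spacing_in / spacing_out)`) and keeps the
#' input origin; values sampled outside the source extent take the modality
#' background fill (-1024 HU for CT, 0 counts for SPECT).
#'
#' @param image a `vol_image`.
#' @param target_spacing length-3 voxel size in mm.
#' @param interpolation `"nearest"`, `"linear"` or `"cubic_bspline"`.
#' @return the resampled `vol_image`.
#' @export
resample <- function(image, target_spacing,
                     interpolation = c("linear", "nearest", "cubic_bspline")) {
  interpolation <- match.arg(interpolation)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("'target_spacing' must be 3 strictly positive values in mm")
  din <- img_dim(image)
  dout <- resample_dims(din, image$spacing, target_spacing)
  fill <- background_fill(image$modality)
  coefs <- if (interpolation == "cubic_bspline")
    bspline_prefilter(image$voxels) else NULL
  out <- array(fill, dim = dout)
  # index of output voxel centres expressed on the input grid, per axis
  ax <- lapply(1:3, function(a)
    ((seq_len(dout[a]) - 1) * target_spacing[a] +
       image$origin[a] - image$origin[a]) / image$spacing[a])
  # process in z-slabs to bound memory on large grids
  nxy <- dout[1] * dout[2]
  ij <- cbind(rep(ax[[1]], times = dout[2]),
              rep(ax[[2]], each = dout[1]))
  for (k in seq_len(dout[3])) {
    idx <- cbind(ij, ax[[3]][k])
    out[, , k] <- interp_at(image$voxels, idx, method = interpolation,
                            fill = fill, coefs = coefs)
  }
  vol_image(out, spacing = target_spacing, origin = image$origin,
            modality = image$modality)
}

#' Reflect a right-leg scan to left laterality
#'
#' Mirrors CT and SPECT voxel grids and the landmarks about the plane through
#' the centre of the CT grid, perpendicular to the medio-lateral (x) axis, so
#' that all scans share a common 'left' laterality before registration. A
#' left scan is returned unchanged.
#'
#' @param scan a [paired_scan()].
#' @return a `paired_scan` with `laterality == "L"`.
#' @export
reflect_sagittal <- function(scan) {
  stopifnot(inherits(scan, "paired_scan"))
  if (scan$laterality == "L") return(scan)
  xc <- grid_center(scan$ct)[1]
  mirror <- function(img) {
    d <- img_dim(img)
    img$voxels <- img$voxels[d[1]:1, , , drop = FALSE]
    # after index reversal the former last voxel sits first; shift the origin
    # so every value keeps its mirrored world position 2*xc - x
    img$origin[1] <- 2 * xc - (img$origin[1] + (d[1] - 1) * img$spacing[1])
    img
  }
  scan$ct <- mirror(scan$ct)
  scan$spect <- mirror(scan$spect)
  lm <- unclass(scan$landmarks)
  lm[, 1] <- 2 * xc - lm[, 1]
  scan$landmarks <- landmark_set(lm)
  scan$laterality <- "L"
  scan
}
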