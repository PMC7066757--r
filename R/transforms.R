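# Parametric spatial transforms (world mm -> world mm) and their composition.
#
# The pull-back convention is used throughout: a registration transform maps
# FIXED-image coordinates into MOVING-image space, so the moving image can be
# resampled onto the fixed grid.

#' Affine world transform
#'
#' Maps a world point p to `A (p - center) + center + t`.
#'
#' @param A 3 x 3 matrix (rotation/scaling/shear part).
#' @param t length-3 translation in mm.
#' @param center length-3 fixed rotation centre in mm.
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  t <- as.numeric(t); center <- as.numeric(center)
  stopifnot(length(t) == 3L, length(center) == 3L)
  if (abs(det(A)) <= 1e-9)
    stop("affine matrix is singular (|det| <= 1e-9)")
  structure(list(A = A, t = t, center = center), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n  A =\n")
  print(round(x$A, 6))
  cat(sprintf("  t = (%.4g, %.4g, %.4g) mm, centre (%.4g, %.4g, %.4g) mm\n",
              x$t[1], x$t[2], x$t[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Cubic B-spline free-form deformation
#'
#' A dense displacement field parameterised by 3-D displacement coefficients
#' on a uniform control grid; the displacement at p is the tensor-product
#' cubic B-spline combination of the 4 x 4 x 4 neighbouring control points.
#' Zero coefficients give the identity mapping.
#'
#' @param grid_origin world position (mm) of control point (0, 0, 0).
#' @param grid_spacing per-axis control-point spacing in mm.
#' @param grid_dims number of control points per axis.
#' @param coef 4-D array `c(grid_dims, 3)` of displacements in mm (defaults
#'   to zeros, the identity).
#' @return an object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_dims,
                              coef = NULL) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_origin) == 3L, length(grid_spacing) == 3L,
            length(grid_dims) == 3L, all(grid_spacing > 0),
            all(grid_dims >= 4L))
  if (is.null(coef)) coef <- array(0, dim = c(grid_dims, 3L))
  if (!identical(dim(coef), c(grid_dims, 3L)))
    stop("'coef' must be an array of dimension c(grid_dims, 3)")
  structure(list(grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing),
                 grid_dims = grid_dims, coef = coef),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf("<bspline_transform> %d x %d x %d control points, spacing (%.4g, %.4g, %.4g) mm, max |disp| %.3g mm\n",
              x$grid_dims[1], x$grid_dims[2], x$grid_dims[3],
              x$grid_spacing[1], x$grid_spacing[2], x$grid_spacing[3],
              max(abs(x$coef))))
  invisible(x)
}

#' Apply a transform to world points
#'
#' @param transform an `affine_transform`, `bspline_transform` or
#'   `composite_transform`.
#' @param p length-3 point or n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped world coordinates.
#' @export
transform_point <- function(transform, p) UseMethod("transform_point")

#' @export
transform_point.affine_transform <- function(transform, p) {
  p <- rbind3(p)
  pc <- sweep(p, 2L, transform$center, "-")
  sweep(pc %*% t(transform$A), 2L, transform$center + transform$t, "+")
}

#' @export
transform_point.bspline_transform <- function(transform, p) {
  p <- rbind3(p)
  p + bspline_displacement(transform, p)$disp
}

#' @export
transform_point.composite_transform <- function(transform, p) {
  p <- rbind3(p)
  for (tf in transform$transforms) p <- transform_point(tf, p)
  p
}

# displacement and (optionally) the per-point basis weights/support indices
# needed for coefficient gradients
bspline_displacement <- function(transform, p, want_support = FALSE) {
  gd <- transform$grid_dims
  u <- sweep(sweep(rbind3(p), 2L, transform$grid_origin, "-"),
             2L, transform$grid_spacing, "/")
  fl <- floor(u)
  if (any(fl < 1 | fl > rep(gd - 3L, each = nrow(u))))
    stop("point outside the B-spline control grid support")
  w <- lapply(1:3, function(a) cubic_bspline_weights(u[, a] - fl[, a]))
  n <- nrow(u)
  disp <- matrix(0, n, 3)
  nc <- prod(gd)
  cf <- matrix(transform$coef, nc, 3)
  sup_idx <- if (want_support) matrix(0L, n, 64) else NULL
  sup_w <- if (want_support) matrix(0, n, 64) else NULL
  s <- 0L
  for (a in 0:3) {
    ia <- fl[, 1] + a - 1
    for (b in 0:3) {
      jb <- fl[, 2] + b - 1
      wab <- w[[1]][, a + 1] * w[[2]][, b + 1]
      for (cc in 0:3) {
        kc <- fl[, 3] + cc - 1
        s <- s + 1L
        wt <- wab * w[[3]][, cc + 1]
        li <- 1L + ia + gd[1] * (jb + gd[2] * kc)
        disp <- disp + wt * cf[li, , drop = FALSE]
        if (want_support) { sup_idx[, s] <- li; sup_w[, s] <- wt }
      }
    }
  }
  list(disp = disp, support_index = sup_idx, support_weight = sup_w)
}

#' Compose two transforms
#'
#' Under the pull-back convention `compose(outer, inner)` maps a point p to
#' `inner(outer(p))`: for the cohort workflow, a reference-space point goes
#' through the inter-subject transform into subject post-operative space,
#' then through the intra-subject transform into pre-operative space. Two
#' affine transforms collapse to a single `affine_transform`.
#'
#' @param outer,inner transforms.
#' @return an `affine_transform` or a `composite_transform`.
#' @export
compose <- function(outer, inner) {
  if (inherits(outer, "affine_transform") &&
      inherits(inner, "affine_transform")) {
    A <- inner$A %*% outer$A
    t0 <- transform_point(inner, transform_point(outer, c(0, 0, 0)))
    return(affine_transform(A, t = as.numeric(t0), center = c(0, 0, 0)))
  }
  parts <- function(tf)
    if (inherits(tf, "composite_transform")) tf$transforms else list(tf)
  structure(list(transforms = c(parts(outer), parts(inner))),
            class = "composite_transform")
}

#' @export
print.composite_transform <- function(x, ...) {
  cat(sprintf("<composite_transform> %d stages: %s\n",
              length(x$transforms),
              paste(vapply(x$transforms, function(t) class(t)[1], ""),
                    collapse = " -> ")))
  invisible(x)
}

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @return the inverse `affine_transform`.
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  Ai <- solve(transform$A)
  # q = A (p - c) + c + t  =>  p = Ai q + (c - Ai (c + t))
  affine_transform(Ai, t = as.numeric(transform$center -
                                        Ai %*% (transform$center +
                                                  transform$t)),
                   center = c(0, 0, 0))
}

#' Resample a moving image onto a fixed grid through a transform
#'
#' `out(p) = moving(transform(p))` for every fixed-grid voxel centre p
#' (pull-back). Samples falling outside the moving extent take the moving
#' image's modality background fill (or `fill` if given).
#'
#' @param moving the `vol_image` to be deformed.
#' @param transform the fixed-to-moving world transform.
#' @param fixed_grid a `vol_image` providing the output grid.
#' @param interpolator `"nearest"`, `"linear"` or `"cubic_bspline"`.
#' @param fill out-of-extent value; default per moving modality.
#' @return a `vol_image` on the fixed grid.
#' @export
resample_moving <- function(moving, transform, fixed_grid,
                            interpolator = c("linear", "nearest",
                                             "cubic_bspline"),
                            fill = NULL) {
  interpolator <- match.arg(interpolator)
  if (is.null(fill)) fill <- background_fill(moving$modality)
  d <- img_dim(fixed_grid)
  coefs <- if (interpolator == "cubic_bspline")
    bspline_prefilter(moving$voxels) else NULL
  out <- array(fill, dim = d)
  xy <- cbind(rep((seq_len(d[1]) - 1), times = d[2]),
              rep((seq_len(d[2]) - 1), each = d[1]))
  for (k in seq_len(d[3])) {
    pts <- index_to_world(fixed_grid, cbind(xy, k - 1))
    q <- transform_world_safe(transform, pts)
    vi <- world_to_index(moving, q$pts)
    vals <- interp_at(moving$voxels, vi, method = interpolator, fill = fill,
                      coefs = coefs)
    vals[!q$ok] <- fill
    out[, , k] <- vals
  }
  vol_image(out, spacing = fixed_grid$spacing, origin = fixed_grid$origin,
            modality = moving$modality)
}

# like transform_point but flags (instead of failing on) points that leave a
# B-spline support region
transform_world_safe <- function(transform, pts) {
  ok <- rep(TRUE, nrow(pts))
  out <- tryCatch(transform_point(transform, pts), error = function(e) NULL)
  if (!is.null(out)) return(list(pts = out, ok = ok))
  # per-point fallback for composite/B-spline chains near the support edge
  res <- pts
  for (i in seq_len(nrow(pts))) {
    v <- tryCatch(transform_point(transform, pts[i, ]),
                  error = function(e) NULL)
    if (is.null(v)) ok[i] <- FALSE else res[i, ] <- v
  }
  list(pts = res, ok = ok)
}

#' Serialize a transform to a plain-text file
#' @param transform transform object.
#' @param path destination file.
#' @export
write_transform <- function(transform, path) {
  con <- file(path, "w"); on.exit(close(con))
  emit <- function(tf) {
    if (inherits(tf, "affine_transform")) {
      writeLines(c("kind affine",
                   paste("A", paste(sprintf("%.17g", tf$A), collapse = " ")),
                   paste("t", paste(sprintf("%.17g", tf$t), collapse = " ")),
                   paste("center",
                         paste(sprintf("%.17g", tf$center), collapse = " "))),
                 con)
    } else if (inherits(tf, "bspline_transform")) {
      writeLines(c("kind bspline",
                   paste("grid_origin",
                         paste(sprintf("%.17g", tf$grid_origin),
                               collapse = " ")),
                   paste("grid_spacing",
                         paste(sprintf("%.17g", tf$grid_spacing),
                               collapse = " ")),
                   paste("grid_dims", paste(tf$grid_dims, collapse = " ")),
                   paste("coef", paste(sprintf("%.17g", tf$coef),
                                       collapse = " "))),
                 con)
    } else stop("cannot serialize transform of class ", class(tf)[1])
  }
  if (inherits(transform, "composite_transform")) {
    writeLines(sprintf("composite %d", length(transform$transforms)), con)
    for (tf in transform$transforms) emit(tf)
  } else emit(transform)
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path file path.
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  fields <- function() {
    l <- strsplit(lines[pos], " ")[[1]]
    pos <<- pos + 1L
    l
  }
  read_one <- function() {
    kind <- fields()
    if (kind[1] != "kind") stop("malformed transform file")
    if (kind[2] == "affine") {
      A <- as.numeric(fields()[-1]); t <- as.numeric(fields()[-1])
      ce <- as.numeric(fields()[-1])
      affine_transform(matrix(A, 3, 3), t, ce)
    } else {
      go <- as.numeric(fields()[-1]); gs <- as.numeric(fields()[-1])
      gd <- as.integer(fields()[-1]); cf <- as.numeric(fields()[-1])
      bspline_transform(go, gs, gd, array(cf, c(gd, 3L)))
    }
  }
  head <- strsplit(lines[1], " ")[[1]]
  if (head[1] == "composite") {
    pos <- 2L
    n <- as.integer(head[2])
    tfs <- vector("list", n)
    for (i in seq_len(n)) tfs[[i]] <- read_one()
    structure(list(transforms = tfs), class = "composite_transform")
  } else read_one()
}
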