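# Registration drivers: multiresolution affine and B-spline registration
# with Halton-sampled mutual-information metrics and ASGD optimization.

#' Registration configuration
#'
#' Defaults reproduce the tuned parameter set: the affine mode runs a
#' 3-stage smoothing pyramid (factors 442, 221, 111), normalized mutual
#' information over 16 bins, 2000 iterations of ASGD with 2000 Halton sample
#' points per iteration, nearest-neighbour interpolation during optimization
#' and linear interpolation for the final image. The non-rigid mode runs 4
#' stages (884, 442, 221, 111), plain MI over 32 bins, 500 iterations,
#' linear optimization interpolation, cubic B-spline final interpolation,
#' and a control grid of base spacing (32, 32, 16) voxels refined per stage
#' with multipliers (8,8,4), (4,4,2), (2,2,1), (1,1,1).
#'
#' @param mode `"affine"` or `"bspline"`.
#' @param ... any field override (see Details in the fitted object).
#' @return an object of class `reg_config`.
#' @export
registration_config <- function(mode = c("affine", "bspline"), ...) {
  mode <- match.arg(mode)
  cfg <- if (mode == "affine") {
    list(mode = "affine", metric = "NMI", histogram_bins = 16L,
         smoothing_factors = list(c(4, 4, 2), c(2, 2, 1), c(1, 1, 1)),
         max_iterations = 2000L, n_points = 2000L, seed = 0L,
         interpolator = "nearest", final_interpolator = "linear",
         asgd = list(A = 50, alpha = 0.602, a = NULL,
                     target_step_voxels = 0.2),
         clip = c(0.01, 0.99), com_threshold = 200)
  } else {
    list(mode = "bspline", metric = "MI", histogram_bins = 32L,
         smoothing_factors = list(c(8, 8, 4), c(4, 4, 2), c(2, 2, 1),
                                  c(1, 1, 1)),
         max_iterations = 500L, n_points = 2000L, seed = 0L,
         interpolator = "linear", final_interpolator = "cubic_bspline",
         grid_spacing_voxels = c(32, 32, 16),
         grid_multipliers = list(c(8, 8, 4), c(4, 4, 2), c(2, 2, 1),
                                 c(1, 1, 1)),
         asgd = list(A = 50, alpha = 0.602, a = NULL,
                     target_step_voxels = 0.2),
         clip = c(0.01, 0.99))
  }
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "reg_config")
}

#' @export
print.reg_config <- function(x, ...) {
  cat(sprintf("<reg_config> %s: %s metric, %d bins, %d resolutions, %d iterations x %d points\n",
              x$mode, x$metric, x$histogram_bins,
              length(x$smoothing_factors), x$max_iterations, x$n_points))
  invisible(x)
}

#' Write / read a registration configuration
#' @param config a `reg_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- registration_config(cfg$mode)
  keep <- intersect(names(cfg), names(base))
  base[keep] <- cfg[keep]
  # YAML loses the list-of-vectors structure; restore numeric vectors
  base$smoothing_factors <- lapply(base$smoothing_factors, as.numeric)
  if (!is.null(base$grid_multipliers))
    base$grid_multipliers <- lapply(base$grid_multipliers, as.numeric)
  base
}

# intensity-weighted centre of mass; weights below `thr` are ignored
center_of_mass <- function(image, thr = 200) {
  w <- pmax(image$voxels - thr, 0)
  s <- sum(w)
  d <- img_dim(image)
  if (s <= 0) return(grid_center(image))
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  idx <- c(sum(w * i), sum(w * j), sum(w * k)) / s
  image$origin + idx * image$spacing
}

mask_centroid <- function(mask) {
  mask_moments(mask)$center
}

# centroid and second central moments (world mm) of a binary mask
mask_moments <- function(mask) {
  d <- dim(mask$mask)
  vox <- which(mask$mask)
  k <- (vox - 1L) %/% (d[1] * d[2])
  j <- ((vox - 1L) %/% d[1]) %% d[2]
  i <- (vox - 1L) %% d[1]
  P <- sweep(cbind(i, j, k) %*% diag(mask$spacing), 2L, mask$origin, "+")
  mu <- colMeans(P)
  Pc <- sweep(P, 2L, mu, "-")
  list(center = mu, cov = crossprod(Pc) / nrow(Pc))
}

# Rodrigues rotation about a unit axis
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# minimal rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  c <- sum(a * b)
  if (c > 1 - 1e-12) return(diag(3))
  w <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
  diag(3) + K + (K %*% K) / (1 + c)
}

# Moments-plus-exhaustive affine initialization.
#
# Long bones are nearly axisymmetric, so the second moments determine the
# centroid, the long-axis direction and two scale factors reliably, but not
# the rotation about the long axis. The initializer therefore (1) matches
# centroids, long axes, the longitudinal scale and an isotropic transverse
# scale from the mask moments, then (2) resolves the residual rotation
# about the long axis by a coarse exhaustive search over the smoothed NMI,
# the standard remedy when a gradient-based optimizer's capture range is
# smaller than the expected misalignment.
moments_init <- function(fixed, moving, fixed_mask, thr = 200,
                         search_deg = 12, step_deg = 2,
                         smoothing = c(4, 4, 2), n_points = 4000,
                         fs = NULL, ms = NULL) {
  mf <- mask_moments(fixed_mask)
  mmask <- structure(list(mask = moving$voxels >= thr &
                            moving$voxels < 2500,
                          spacing = moving$spacing,
                          origin = moving$origin), class = "bone_mask")
  if (sum(mmask$mask) < 100)
    return(list(A = diag(3),
                t = center_of_mass(moving, thr) - mf$center,
                center = mf$center))
  mm <- mask_moments(mmask)
  ef <- eigen(mf$cov, symmetric = TRUE)
  em <- eigen(mm$cov, symmetric = TRUE)
  uf <- ef$vectors[, 1]; um <- em$vectors[, 1]
  if (sum(uf * um) < 0) um <- -um
  Q0 <- rotation_between(uf, um)
  s_long <- sqrt(max(em$values[1], 1e-9) / max(ef$values[1], 1e-9))
  s_perp <- sqrt(max(sum(em$values[2:3]), 1e-9) /
                   max(sum(ef$values[2:3]), 1e-9))
  clamp <- function(x) min(max(x, 0.75), 1.35)
  s_long <- clamp(s_long); s_perp <- clamp(s_perp)
  S <- s_long * tcrossprod(uf) + s_perp * (diag(3) - tcrossprod(uf))
  base_A <- Q0 %*% S
  t0 <- mm$center - mf$center
  # exhaustive residual-rotation search on stage-1-smoothed images
  if (is.null(fs)) fs <- smooth_level(fixed, smoothing)
  if (is.null(ms)) ms <- smooth_level(moving, smoothing)
  frange <- intensity_range(fs$voxels[fixed_mask$mask])
  mrange <- intensity_range(ms$voxels)
  pts <- sample_points(fixed_mask, n_points, 0L, 0L, warn = FALSE)
  fvals <- interp_linear(fs$voxels, world_to_index(fs, pts),
                         fill = NA_real_)$value
  pc <- sweep(pts, 2L, mf$center, "-")
  score <- function(A) {
    q <- sweep(pc %*% t(A), 2L, mf$center + t0, "+")
    tryCatch(metric_eval(fvals, ms$voxels, world_to_index(ms, q), 16,
                         frange, mrange, metric = "NMI",
                         value_interp = "linear",
                         want_grad = FALSE)$value,
             error = function(e) -Inf)
  }
  thetas <- seq(-search_deg, search_deg, by = step_deg) * pi / 180
  best <- base_A; best_v <- -Inf
  for (th in thetas) {
    A <- rotation_about(um, th) %*% base_A
    v <- score(A)
    if (v > best_v) { best_v <- v; best <- A }
  }
  list(A = best, t = t0, center = mf$center)
}

# auto-scale the ASGD numerator so the first step displaces the image by
# about one (in-plane) voxel; disp_unit is the maximum displacement (mm)
# the image would see under a unit-gain step along the probed gradient
asgd_gain <- function(disp_unit, voxel_mm, A, alpha) {
  if (!is.finite(disp_unit) || disp_unit < 1e-12) return(1)
  (voxel_mm / disp_unit) * A^alpha
}

# displacement at the region corners induced by a unit-gain affine step
affine_step_disp <- function(g_z, scales, corners, ctr) {
  dx <- g_z / scales
  dA <- matrix(dx[1:9], 3, 3)
  dt <- dx[10:12]
  disp <- sweep(sweep(corners, 2L, ctr, "-") %*% t(dA), 2L, dt, "+")
  max(sqrt(rowSums(disp^2)))
}

#' Affine intensity-based registration
#'
#' Runs the multiresolution affine protocol: a moments-based
#' initialization (centroid, long axis, scales, plus an exhaustive search
#' for the rotation about the long axis), then per pyramid stage a fresh
#' Halton sample of `n_points` fixed-mask
#' points per iteration, a Parzen joint histogram over `histogram_bins`
#' bins, the configured (normalized) mutual-information metric, and ASGD
#' updates of the 12 affine parameters, each stage warm-started from the
#' previous one.
#'
#' @param fixed,moving CT `vol_image`s (typically VOI crops) on the common
#'   resampled grid.
#' @param fixed_mask `bone_mask` defining the sampling region on the fixed
#'   grid.
#' @param config an affine [registration_config()].
#' @param seed integer controlling every stochastic draw; identical
#'   `(config, seed)` give bitwise-identical parameters.
#' @return an object of class `reg_result`; see [coef.reg_result()],
#'   [predict.reg_result()].
#' @export
register_affine <- function(fixed, moving, fixed_mask,
                            config = registration_config("affine"),
                            seed = config$seed) {
  if (config$mode != "affine") stop("config$mode must be 'affine'")
  if (isTRUE(fixed_mask$empty) || !any(fixed_mask$mask))
    stop("fixed mask is empty; registration refused")
  smoothed <- lapply(config$smoothing_factors, function(f)
    list(fs = smooth_level(fixed, f), ms = smooth_level(moving, f)))
  init <- moments_init(fixed, moving, fixed_mask, config$com_threshold,
                       fs = smoothed[[1]]$fs, ms = smoothed[[1]]$ms)
  ctr <- init$center
  x0 <- c(init$A, init$t)  # A (column-major) and t
  # lever arm: unit matrix-entry change displaces edge points by ~R mm
  d <- dim(fixed_mask$mask)
  corners <- index_to_world(list(spacing = fixed_mask$spacing,
                                 origin = fixed_mask$origin),
                            as.matrix(expand.grid(c(0, d[1] - 1),
                                                  c(0, d[2] - 1),
                                                  c(0, d[3] - 1))))
  R <- max(sqrt(rowSums(sweep(corners, 2L, ctr, "-")^2)))
  scales <- c(rep(R, 9), rep(1, 3))
  z <- x0 * scales
  voxel_mm <- config$asgd$target_step_voxels * min(fixed$spacing)
  warned <- FALSE
  trace <- list()
  n_stages <- length(config$smoothing_factors)
  for (s in seq_len(n_stages)) {
    fs <- smoothed[[s]]$fs
    ms <- smoothed[[s]]$ms
    frange <- intensity_range(fs$voxels[fixed_mask$mask], config$clip)
    mrange <- intensity_range(ms$voxels, config$clip)
    marr <- ms$voxels
    stage_seed <- derive_seed(seed, 100000L * s)
    fn <- function(zp, k) {
      xp <- zp / scales
      A <- matrix(xp[1:9], 3, 3)
      t <- xp[10:12]
      pts <- sample_points(fixed_mask, config$n_points, stage_seed, k,
                           warn = !warned)
      warned <<- TRUE
      fvals <- interp_linear(fs$voxels, world_to_index(fs, pts),
                             fill = NA_real_)$value
      pc <- sweep(pts, 2L, ctr, "-")
      q <- sweep(pc %*% t(A), 2L, ctr + t, "+")
      midx <- world_to_index(ms, q)
      me <- metric_eval(fvals, marr, midx, config$histogram_bins,
                        frange, mrange, metric = config$metric,
                        value_interp = config$interpolator)
      # cost = -metric; chain through world position: dC/dq = dC/dm * grad_m
      dm_dq <- sweep(me$dm_didx, 2L, ms$spacing, "/")
      w <- -me$dC_dm * dm_dq            # n x 3, d(cost)/d(q_axis)
      pck <- pc[me$keep, , drop = FALSE]
      gA <- crossprod(w, pck)           # 3 x 3: d cost / dA[i, j]
      gt <- colSums(w)
      list(value = -me$value, gradient = c(gA, gt) / scales)
    }
    if (is.null(config$asgd$a)) {
      d0 <- vapply(0:2, function(k)
        affine_step_disp(fn(z, k)$gradient, scales, corners, ctr), 0)
      a <- asgd_gain(stats::median(d0), voxel_mm,
                     config$asgd$A, config$asgd$alpha)
    } else a <- config$asgd$a
    opt <- asgd_minimize(fn, z, config$max_iterations, a = a,
                         A = config$asgd$A, alpha = config$asgd$alpha)
    z <- opt$par_avg
    trace[[s]] <- -opt$trace
  }
  x <- z / scales
  tf <- affine_transform(matrix(x[1:9], 3, 3), x[10:12], center = ctr)
  final <- resample_moving(moving, tf, fixed,
                           interpolator = config$final_interpolator)
  new_reg_result(transform = tf, trace = trace, final_image = final,
                 config = config, seed = seed,
                 fixed = fixed, moving = moving, fixed_mask = fixed_mask)
}

#' Non-rigid (cubic B-spline) registration
#'
#' Refines an affine initialization with a free-form deformation: per stage
#' the control grid is rebuilt at the stage's spacing (base spacing times
#' the stage multiplier), coefficients are warm-started by evaluating the
#' previous stage's displacement at the new knots, and ASGD optimizes the
#' metric over all control-point displacements. The total transform is
#' `compose(initial, bspline)`.
#'
#' @inheritParams register_affine
#' @param initial the affine pre-registration (an `affine_transform`).
#' @param config a bspline [registration_config()].
#' @param fixed_mask optional sampling mask; defaults to the full fixed
#'   grid.
#' @export
register_bspline <- function(fixed, moving, config =
                               registration_config("bspline"),
                             initial = affine_transform(),
                             fixed_mask = NULL, seed = config$seed) {
  if (config$mode != "bspline") stop("config$mode must be 'bspline'")
  stopifnot(inherits(initial, "affine_transform"))
  if (is.null(fixed_mask)) fixed_mask <- full_grid_mask(fixed)
  if (isTRUE(fixed_mask$empty) || !any(fixed_mask$mask))
    stop("fixed mask is empty; registration refused")
  d <- img_dim(fixed)
  # B-spline domain: the affine image of the fixed extent, padded
  corners <- index_to_world(fixed, as.matrix(expand.grid(
    c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1))))
  qc <- transform_point(initial, corners)
  dom_lo <- apply(qc, 2, min)
  dom_hi <- apply(qc, 2, max)
  tfb <- NULL
  warned <- FALSE
  trace <- list()
  n_stages <- length(config$smoothing_factors)
  voxel_mm <- config$asgd$target_step_voxels * min(fixed$spacing)
  for (s in seq_len(n_stages)) {
    gs_mm <- config$grid_spacing_voxels * config$grid_multipliers[[s]] *
      fixed$spacing
    go <- dom_lo - 2 * gs_mm
    gd <- pmax(as.integer(ceiling((dom_hi - go) / gs_mm)) + 3L, 4L)
    coef <- array(0, dim = c(gd, 3L))
    if (!is.null(tfb)) {
      # warm start: previous stage's displacement evaluated at the new knots
      kn <- as.matrix(expand.grid(seq_len(gd[1]) - 1, seq_len(gd[2]) - 1,
                                  seq_len(gd[3]) - 1))
      kw <- sweep(sweep(kn, 2L, gs_mm, "*"), 2L, go, "+")
      inside <- prev_inside(tfb, kw)
      dsp <- matrix(0, nrow(kw), 3)
      if (any(inside))
        dsp[inside, ] <- bspline_displacement(tfb,
                                              kw[inside, , drop = FALSE])$disp
      coef <- array(dsp, dim = c(gd, 3L))
    }
    fs <- smooth_level(fixed, config$smoothing_factors[[s]])
    ms <- smooth_level(moving, config$smoothing_factors[[s]])
    frange <- intensity_range(fs$voxels[fixed_mask$mask], config$clip)
    mrange <- intensity_range(ms$voxels, config$clip)
    marr <- ms$voxels
    stage_seed <- derive_seed(seed, 200000L * s)
    npar <- prod(gd) * 3L
    tf_stage <- bspline_transform(go, gs_mm, gd)
    fn <- function(zp, k) {
      tf_stage$coef <- array(zp, dim = c(gd, 3L))
      pts <- sample_points(fixed_mask, config$n_points, stage_seed, k,
                           warn = !warned)
      warned <<- TRUE
      fvals <- interp_linear(fs$voxels, world_to_index(fs, pts),
                             fill = NA_real_)$value
      q0 <- transform_point(initial, pts)
      bd <- bspline_displacement(tf_stage, q0, want_support = TRUE)
      q <- q0 + bd$disp
      midx <- world_to_index(ms, q)
      me <- metric_eval(fvals, marr, midx, config$histogram_bins,
                        frange, mrange, metric = config$metric,
                        value_interp = config$interpolator)
      dm_dq <- sweep(me$dm_didx, 2L, ms$spacing, "/")
      w <- -me$dC_dm * dm_dq
      grad <- numeric(npar)
      ki <- bd$support_index[me$keep, , drop = FALSE]
      kw <- bd$support_weight[me$keep, , drop = FALSE]
      nc <- prod(gd)
      for (axis in 1:3) {
        contrib <- as.numeric(kw * w[, axis])
        acc <- rowsum(contrib, as.integer(ki))
        ids <- as.integer(rownames(acc)) + (axis - 1L) * nc
        grad[ids] <- grad[ids] + acc
      }
      list(value = -me$value, gradient = grad)
    }
    z <- as.numeric(coef)
    if (is.null(config$asgd$a)) {
      g0 <- vapply(0:2, function(k) max(abs(fn(z, k)$gradient)), 0)
      a <- asgd_gain(stats::median(g0), voxel_mm,
                     config$asgd$A, config$asgd$alpha)
    } else a <- config$asgd$a
    opt <- asgd_minimize(fn, z, config$max_iterations, a = a,
                         A = config$asgd$A, alpha = config$asgd$alpha)
    tfb <- bspline_transform(go, gs_mm, gd, array(opt$par_avg, c(gd, 3L)))
    trace[[s]] <- -opt$trace
  }
  total <- compose(initial, tfb)
  final <- resample_moving(moving, total, fixed,
                           interpolator = config$final_interpolator)
  new_reg_result(transform = total, trace = trace, final_image = final,
                 config = config, seed = seed, fixed = fixed,
                 moving = moving, fixed_mask = fixed_mask,
                 bspline = tfb, initial = initial)
}

prev_inside <- function(tfb, pts) {
  u <- sweep(sweep(pts, 2L, tfb$grid_origin, "-"), 2L, tfb$grid_spacing, "/")
  fl <- floor(u)
  ok <- rep(TRUE, nrow(u))
  for (a in 1:3) ok <- ok & fl[, a] >= 1 & fl[, a] <= tfb$grid_dims[a] - 3L
  ok
}

new_reg_result <- function(transform, trace, final_image, config, seed,
                           fixed, moving, fixed_mask, ...) {
  structure(list(transform = transform, trace = trace,
                 final_image = final_image, config = config, seed = seed,
                 iterations = sum(lengths(trace)),
                 final_metric = {
                   tl <- trace[[length(trace)]]
                   if (length(tl)) tl[length(tl)] else NA_real_
                 },
                 fixed = fixed, moving = moving, fixed_mask = fixed_mask,
                 ...),
            class = "reg_result")
}

#' @export
print.reg_result <- function(x, ...) {
  cat(sprintf("<reg_result> %s registration (%s), %d iterations, final %s = %.4f\n",
              x$config$mode, class(x$transform)[1], x$iterations,
              x$config$metric, x$final_metric))
  invisible(x)
}

#' @export
summary.reg_result <- function(object, ...) {
  stage_gain <- vapply(object$trace, function(tr)
    if (length(tr) > 1) tr[length(tr)] - tr[1] else 0, 0)
  out <- list(mode = object$config$mode, metric = object$config$metric,
              iterations = object$iterations,
              final_metric = object$final_metric,
              stage_start = vapply(object$trace, function(tr) tr[1], 0),
              stage_end = vapply(object$trace,
                                 function(tr) tr[length(tr)], 0),
              stage_gain = stage_gain,
              n_parameters = length(coef(object)))
  class(out) <- "summary.reg_result"
  out
}

#' @export
print.summary.reg_result <- function(x, ...) {
  cat(sprintf("%s registration, %s metric, %d iterations, %d parameters\n",
              x$mode, x$metric, x$iterations, x$n_parameters))
  for (s in seq_along(x$stage_gain))
    cat(sprintf("  stage %d: %s %.4f -> %.4f (gain %+.4f)\n", s, x$metric,
                x$stage_start[s], x$stage_end[s], x$stage_gain[s]))
  invisible(x)
}

#' Transform parameters of a fitted registration
#' @param object a `reg_result`.
#' @param ... unused.
#' @export
coef.reg_result <- function(object, ...) {
  tf <- object$transform
  flatten <- function(t) {
    if (inherits(t, "affine_transform")) c(A = t$A, t = t$t)
    else if (inherits(t, "bspline_transform")) c(coef = as.numeric(t$coef))
    else unlist(lapply(t$transforms, flatten))
  }
  flatten(tf)
}

#' Map fixed-space points (or resample an image) through a fitted
#' registration
#'
#' @param object a `reg_result`.
#' @param newdata n x 3 matrix of fixed-space world points, or a
#'   `vol_image` to resample onto the fixed grid.
#' @param ... passed to [resample_moving()] for image input.
#' @export
predict.reg_result <- function(object, newdata, ...) {
  if (inherits(newdata, "vol_image"))
    resample_moving(newdata, object$transform, object$fixed, ...)
  else transform_point(object$transform, newdata)
}

#' Plot the metric trace of a registration
#' @param x a `reg_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reg_result <- function(x, ...) {
  tr <- unlist(x$trace)
  graphics::plot(seq_along(tr), tr, type = "l",
                 xlab = "iteration", ylab = x$config$metric, ...)
  br <- cumsum(lengths(x$trace))
  graphics::abline(v = br[-length(br)], lty = 3)
  invisible(x)
}

#' Intra-subject registration of a pre-operative scan to the post-operative
#' scan
#'
#' The post-operative scan is the fixed image, with the prosthesis masked
#' out of its bone mask; the pre-operative scan is the moving image. The
#' recovered transform applies identically to the CT and the SPECT (both
#' share one world frame), so the pre-operative SPECT is resampled onto the
#' fixed VOI grid through the same parameters.
#'
#' @param postop,preop preprocessed [paired_scan()]s (resampled, left
#'   laterality).
#' @param bone which VOI to register.
#' @param config affine [registration_config()].
#' @param seed stochastic seed.
#' @param bone_low,prosthesis_low HU thresholds passed to [segment_bone()].
#' @param margin_mm VOI margin passed to [build_voi()].
#' @param resample_spect also resample the pre-operative SPECT onto the
#'   fixed grid (set `FALSE` to skip the extra interpolation).
#' @return a `reg_result` with extra fields `fixed_mask`, `moving_mask`,
#'   `spect_aligned` and `bone`.
#' @export
register_intra <- function(postop, preop, bone = "femur",
                           config = registration_config("affine"),
                           seed = config$seed, bone_low = 200,
                           prosthesis_low = 2500, margin_mm = c(20, 20, 20),
                           resample_spect = TRUE) {
  voi_post <- build_voi(postop$landmarks, bone, postop$ct, margin_mm)
  voi_pre <- build_voi(preop$landmarks, bone, preop$ct, margin_mm)
  fixed <- crop(postop$ct, voi_post)
  moving <- crop(preop$ct, voi_pre)
  fixed_mask <- segment_bone(fixed, bone_low, prosthesis_low, bone = bone)
  moving_mask <- segment_bone(moving, bone_low, prosthesis_low, bone = bone)
  res <- register_affine(fixed, moving, fixed_mask, config, seed)
  res$bone <- bone
  res$moving_mask <- moving_mask
  if (resample_spect)
    res$spect_aligned <- resample_moving(preop$spect, res$transform, fixed,
                                         interpolator = "linear")
  res
}

#' Inter-subject registration of a post-operative scan to a reference
#' subject
#'
#' Affine followed by B-spline non-rigid registration of the subject's
#' post-operative bone image onto the reference subject's. Prosthesis
#' masking is disabled (every subject carries the same implant), so the bone
#' masks are built with `prosthesis_low = Inf`. The result's transform is
#' the composed affine-then-B-spline chain, ready for concatenation with the
#' subject's intra-subject transform.
#'
#' @param reference_postop,subject_postop preprocessed [paired_scan()]s.
#' @param bone which VOI to register.
#' @param config_affine,config_bspline stage configurations.
#' @inheritParams register_intra
#' @export
register_inter <- function(reference_postop, subject_postop,
                           bone = "femur",
                           config_affine = registration_config("affine"),
                           config_bspline = registration_config("bspline"),
                           seed = config_affine$seed, bone_low = 200,
                           margin_mm = c(20, 20, 20)) {
  voi_ref <- build_voi(reference_postop$landmarks, bone,
                       reference_postop$ct, margin_mm)
  voi_sub <- build_voi(subject_postop$landmarks, bone, subject_postop$ct,
                       margin_mm)
  fixed <- crop(reference_postop$ct, voi_ref)
  moving <- crop(subject_postop$ct, voi_sub)
  fixed_mask <- segment_bone(fixed, bone_low, prosthesis_low = Inf,
                             bone = bone)
  aff <- register_affine(fixed, moving, fixed_mask, config_affine, seed)
  res <- register_bspline(fixed, moving, config_bspline,
                          initial = aff$transform,
                          fixed_mask = fixed_mask,
                          seed = derive_seed(seed, 777L))
  res$bone <- bone
  res$affine_stage <- aff
  res
}
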