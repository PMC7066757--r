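# Synthetic paired CT/SPECT knee phantoms with analytic geometry, landmarks,
# uptake hotspots and known ground-truth misalignments. These stand in for
# clinical knee scans, which cannot be redistributed, and provide exact
# ground truth for registration recovery experiments.

#' Phantom specification
#'
#' Describes a synthetic left knee on a CT grid (default 160 x 160 x 80
#' voxels at 0.98 x 0.98 x 3 mm, i.e. roughly 157 x 157 x 240 mm) with the
#' femur at low z and the tibial shaft running distally toward high z. The
#' paired SPECT is generated at 4.79 mm isotropic voxels over the same
#' extent. Bones are cylinders (shafts) and ellipsoids (condyles, tibial
#' plateau, patella) with cortical shells; the post-operative scan adds a
#' metal tibial insert in the medial plateau. Hotspots are Gaussian uptake
#' blobs; the default post-operative-only hotspot sits below the tibial
#' insert in the posterolateral position.
#'
#' @param dims CT grid dimensions.
#' @param spacing CT voxel size in mm.
#' @param spect_spacing SPECT voxel size in mm.
#' @param hu HU levels: soft tissue, trabecular, cortical, implant.
#' @param ct_noise_sd Gaussian CT noise, HU.
#' @param spect_noise_scale multiplicative scale of the Poisson-like SPECT
#'   noise (standard deviation `scale * sqrt(counts)`).
#' @param uptake baseline counts: soft tissue and bone.
#' @param hotspots list of hotspot descriptors
#'   `list(center, amplitude, sigma, timepoint)` with `timepoint` one of
#'   `"both"`, `"preop"`, `"postop"`; `NULL` gives the defaults.
#' @param texture_amp anatomy-locked smooth intensity heterogeneity (HU
#'   standard deviation) inside bone and soft tissue, emulating trabecular
#'   density and soft-tissue structure; both timepoints of a subject share
#'   the same texture (it is tissue, not noise).
#' @param texture_wavelength_mm wavelength range of the texture field.
#' @param texture_seed seed of the texture field; keep it fixed across the
#'   timepoints of one subject and vary it between subjects.
#' @param implant logical: render the tibial insert (post-operative scans).
#' @param anat optional `affine_transform` warping the base anatomy
#'   (anthropometric variation between cohort subjects).
#' @param seed integer driving all random draws.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(160, 160, 80),
                         spacing = c(0.98, 0.98, 3),
                         spect_spacing = c(4.79, 4.79, 4.79),
                         hu = c(soft = 40, trabecular = 300,
                                cortical = 1100, implant = 3000),
                         ct_noise_sd = 15,
                         spect_noise_scale = 0.5,
                         uptake = c(soft = 5, bone = 50),
                         hotspots = NULL,
                         implant = TRUE,
                         anat = NULL,
                         texture_amp = c(bone = 80, soft = 30),
                         texture_wavelength_mm = c(30, 80),
                         texture_seed = 7L,
                         seed = 1L) {
  if (is.unsorted(hu, strictly = TRUE))
    stop("HU levels must increase: soft < trabecular < cortical < implant")
  spec <- list(dims = as.integer(dims), spacing = as.numeric(spacing),
               spect_spacing = as.numeric(spect_spacing), hu = hu,
               ct_noise_sd = ct_noise_sd,
               spect_noise_scale = spect_noise_scale, uptake = uptake,
               hotspots = hotspots, implant = isTRUE(implant), anat = anat,
               texture_amp = texture_amp,
               texture_wavelength_mm = texture_wavelength_mm,
               texture_seed = as.integer(texture_seed),
               seed = as.integer(seed))
  spec$geom <- phantom_geometry(spec)
  if (is.null(spec$hotspots)) spec$hotspots <- default_hotspots(spec$geom)
  structure(spec, class = "phantom_spec")
}

# analytic geometry in world mm for the base (untransformed) anatomy
phantom_geometry <- function(spec) {
  ext <- spec$dims * spec$spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2
  list(
    cx = cx, cy = cy, ext = ext,
    femur_shaft = list(c = c(cx, cy), r = 14, cort = 4, z = c(3, 105)),
    condyle_med = list(c = c(cx + 12, cy, 112), s = c(12, 14, 12)),
    condyle_lat = list(c = c(cx - 12, cy, 112), s = c(12, 14, 12)),
    tibia_plateau = list(c = c(cx, cy, 136), s = c(17, 14, 9)),
    tibia_shaft = list(c = c(cx, cy), r = 12, cort = 3.5,
                       z = c(140, ext[3] - 3)),
    patella = list(c = c(cx, cy - 30, 112), s = c(10, 6, 12)),
    implant_box = list(lo = c(cx + 1, cy - 8, 131), hi = c(cx + 15, cy + 8,
                                                          137)),
    soft_radius = min(cx, cy) - 5)
}

# landmarks at analytic geometric loci of the base anatomy
phantom_landmarks <- function(geom) {
  cx <- geom$cx; cy <- geom$cy
  lm <- rbind(
    FibulaHead = c(cx - 22, cy + 6, 142),
    FTP = c(cx, cy - 13, 101),
    FLE = c(cx - 24, cy, 112),
    FME = c(cx + 24, cy, 112),
    FKC = c(cx, cy, 123),
    TibiaLateralPeak = c(cx - 8, cy, 128),
    TibiaMedialPeak = c(cx + 8, cy, 128),
    ProximalMargin = c(cx, cy - 30, 100),
    DistalMargin = c(cx, cy - 30, 124),
    LateralMargin = c(cx - 10, cy - 30, 112),
    MedialMargin = c(cx + 10, cy - 30, 112))
  landmark_set(lm)
}

default_hotspots <- function(geom) {
  cx <- geom$cx; cy <- geom$cy
  list(
    # physiological joint-line uptake, present at both timepoints
    list(center = c(cx - 5, cy, 120), amplitude = 300, sigma = 8,
         timepoint = "both"),
    # post-operative remodelling below the tibial insert, posterolateral
    list(center = c(cx - 8, cy + 8, 141), amplitude = 800, sigma = 6,
         timepoint = "postop"))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> CT %d x %d x %d @ (%.3g, %.3g, %.3g) mm, implant %s, %d hotspots, seed %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2],
              x$spacing[3], x$implant, length(x$hotspots), x$seed))
  invisible(x)
}

# world coordinate arrays of all voxel centres of a grid, after pulling the
# anatomy transform back (points are tested against the BASE geometry)
grid_world <- function(dims, spacing, anat_inv = NULL) {
  X <- array(rep((seq_len(dims[1]) - 1) * spacing[1], times =
                   dims[2] * dims[3]), dims)
  Y <- array(rep(rep((seq_len(dims[2]) - 1) * spacing[2], each = dims[1]),
                 times = dims[3]), dims)
  Z <- array(rep((seq_len(dims[3]) - 1) * spacing[3],
                 each = dims[1] * dims[2]), dims)
  if (!is.null(anat_inv)) {
    A <- anat_inv$A; tt <- anat_inv$t; ce <- anat_inv$center
    Xc <- X - ce[1]; Yc <- Y - ce[2]; Zc <- Z - ce[3]
    Xn <- A[1, 1] * Xc + A[1, 2] * Yc + A[1, 3] * Zc + ce[1] + tt[1]
    Yn <- A[2, 1] * Xc + A[2, 2] * Yc + A[2, 3] * Zc + ce[2] + tt[2]
    Zn <- A[3, 1] * Xc + A[3, 2] * Yc + A[3, 3] * Zc + ce[3] + tt[3]
    X <- Xn; Y <- Yn; Z <- Zn
  }
  list(X = X, Y = Y, Z = Z)
}

inside_cylinder <- function(W, cyl, shrink = 0) {
  r <- cyl$r - shrink
  (W$X - cyl$c[1])^2 + (W$Y - cyl$c[2])^2 <= r^2 &
    W$Z >= cyl$z[1] & W$Z <= cyl$z[2]
}

inside_ellipsoid <- function(W, ell, scale = 1) {
  ((W$X - ell$c[1]) / (ell$s[1] * scale))^2 +
    ((W$Y - ell$c[2]) / (ell$s[2] * scale))^2 +
    ((W$Z - ell$c[3]) / (ell$s[3] * scale))^2 <= 1
}

inside_box <- function(W, box) {
  W$X >= box$lo[1] & W$X <= box$hi[1] &
    W$Y >= box$lo[2] & W$Y <= box$hi[2] &
    W$Z >= box$lo[3] & W$Z <= box$hi[3]
}

# smooth unit-variance random field evaluated at anatomy coordinates: a sum
# of random plane-wave cosines with wavelengths in `wl` (mm); being a
# function of the pulled-back coordinates, the texture deforms with the
# anatomy and is identical across a subject's timepoints
texture_field <- function(W, wl, seed, n_waves = 40L) {
  par <- with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * n_waves), n_waves, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(k = dirs * (2 * pi / stats::runif(n_waves, wl[1], wl[2])),
         phase = stats::runif(n_waves, 0, 2 * pi),
         amp = stats::rnorm(n_waves))
  })
  t <- 0
  for (j in seq_len(nrow(par$k)))
    t <- t + par$amp[j] * cos(par$k[j, 1] * W$X + par$k[j, 2] * W$Y +
                                par$k[j, 3] * W$Z + par$phase[j])
  t / sqrt(sum(par$amp^2) / 2)
}

# bone occupancy (outer bone surface) and the trabecular interior
phantom_bone_masks <- function(geom, W) {
  outer_m <- inside_cylinder(W, geom$femur_shaft) |
    inside_ellipsoid(W, geom$condyle_med) |
    inside_ellipsoid(W, geom$condyle_lat) |
    inside_ellipsoid(W, geom$tibia_plateau) |
    inside_cylinder(W, geom$tibia_shaft) |
    inside_ellipsoid(W, geom$patella)
  inner <- inside_cylinder(W, geom$femur_shaft, shrink = geom$femur_shaft$cort) |
    inside_ellipsoid(W, geom$condyle_med, scale = 0.72) |
    inside_ellipsoid(W, geom$condyle_lat, scale = 0.72) |
    inside_ellipsoid(W, geom$tibia_plateau, scale = 0.75) |
    inside_cylinder(W, geom$tibia_shaft, shrink = geom$tibia_shaft$cort) |
    inside_ellipsoid(W, geom$patella, scale = 0.7)
  list(bone = outer_m, trabecular = inner & outer_m)
}

#' Generate a synthetic paired CT/SPECT knee scan
#'
#' Deterministic given the spec (including its seed): the same spec renders
#' bitwise-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param timepoint `"preop"` or `"postop"`; the implant is rendered only
#'   when `spec$implant` is `TRUE` (conventionally the post-operative scan)
#'   and hotspots are filtered by their own timepoint tag.
#' @param subject_id identifier carried into the [paired_scan()].
#' @return a [paired_scan()].
#' @export
generate_knee_phantom <- function(spec, timepoint = c("postop", "preop"),
                                  subject_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  timepoint <- match.arg(timepoint)
  geom <- spec$geom
  anat_inv <- if (is.null(spec$anat)) NULL else invert_affine(spec$anat)
  # ---- CT ----
  W <- grid_world(spec$dims, spec$spacing, anat_inv)
  masks <- phantom_bone_masks(geom, W)
  soft <- (W$X - geom$cx)^2 + (W$Y - geom$cy)^2 <= geom$soft_radius^2
  ct <- array(-1024, dim = spec$dims)
  ct[soft] <- spec$hu[["soft"]]
  ct[masks$bone] <- spec$hu[["cortical"]]
  ct[masks$trabecular] <- spec$hu[["trabecular"]]
  if (any(spec$texture_amp > 0)) {
    tex <- texture_field(W, spec$texture_wavelength_mm, spec$texture_seed)
    softonly <- soft & !masks$bone
    ct[softonly] <- ct[softonly] + spec$texture_amp[["soft"]] * tex[softonly]
    ct[masks$bone] <- ct[masks$bone] +
      spec$texture_amp[["bone"]] * tex[masks$bone]
  }
  if (spec$implant && timepoint == "postop")
    ct[inside_box(W, geom$implant_box)] <- spec$hu[["implant"]]
  ct <- ct + with_seed(derive_seed(spec$seed, 11L),
                       array(stats::rnorm(prod(spec$dims),
                                          sd = spec$ct_noise_sd),
                             spec$dims))
  ct_img <- vol_image(ct, spec$spacing, origin = c(0, 0, 0), modality = "CT")
  # ---- SPECT ----
  sdims <- resample_dims(spec$dims, spec$spacing, spec$spect_spacing)
  Ws <- grid_world(sdims, spec$spect_spacing, anat_inv)
  smasks <- phantom_bone_masks(geom, Ws)
  ssoft <- (Ws$X - geom$cx)^2 + (Ws$Y - geom$cy)^2 <= geom$soft_radius^2
  up <- array(0, dim = sdims)
  up[ssoft] <- spec$uptake[["soft"]]
  up[smasks$bone] <- spec$uptake[["bone"]]
  for (h in spec$hotspots) {
    if (!(h$timepoint == "both" || h$timepoint == timepoint)) next
    d2 <- (Ws$X - h$center[1])^2 + (Ws$Y - h$center[2])^2 +
      (Ws$Z - h$center[3])^2
    # the tracer binds to remodelling bone, so hotspots live inside it
    up <- up + h$amplitude * exp(-d2 / (2 * h$sigma^2)) * smasks$bone
  }
  up <- gaussian_smooth(up, c(1, 1, 1))
  noise <- with_seed(derive_seed(spec$seed, 13L),
                     array(stats::rnorm(prod(sdims)), sdims))
  up <- pmax(up + spec$spect_noise_scale * sqrt(pmax(up, 0)) * noise, 0)
  spect_img <- vol_image(up, spec$spect_spacing, origin = c(0, 0, 0),
                         modality = "SPECT")
  lm <- phantom_landmarks(geom)
  if (!is.null(spec$anat))
    lm <- landmark_set(`rownames<-`(transform_point(spec$anat,
                                                    unclass(lm)),
                                    rownames(lm)))
  paired_scan(ct_img, spect_img, lm, laterality = "L",
              timepoint = timepoint, subject_id = subject_id)
}

#' Known ground-truth deformation
#'
#' Wraps a forward world mapping (what a registration must recover) with
#' its inverse. Rigid and affine kinds invert in closed form; a B-spline
#' kind inverts numerically by fixed-point iteration.
#'
#' @param kind `"rigid"`, `"affine"` or `"bspline"`.
#' @param rotation_deg length-3 rotation angles (degrees) about x, y, z
#'   (rigid kind).
#' @param translation length-3 translation in mm.
#' @param scaling length-3 per-axis scaling factors (rigid kind; 1 = none).
#' @param center rotation/scaling centre in mm.
#' @param A 3 x 3 matrix (affine kind).
#' @param bspline a `bspline_transform` (bspline kind).
#' @return an object of class `gt_deformation` with `forward` and `inverse`
#'   transforms.
#' @export
ground_truth_deformation <- function(kind = c("rigid", "affine", "bspline"),
                                     rotation_deg = c(0, 0, 0),
                                     translation = c(0, 0, 0),
                                     scaling = c(1, 1, 1),
                                     center = c(0, 0, 0), A = NULL,
                                     bspline = NULL) {
  kind <- match.arg(kind)
  if (kind == "rigid") {
    th <- rotation_deg * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
                c(-sin(th[2]), 0, cos(th[2])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    A <- Rz %*% Ry %*% Rx %*% diag(scaling)
    fwd <- affine_transform(A, translation, center)
    inv <- invert_affine(fwd)
  } else if (kind == "affine") {
    if (is.null(A)) stop("affine kind needs 'A'")
    fwd <- affine_transform(A, translation, center)
    inv <- invert_affine(fwd)
  } else {
    if (is.null(bspline)) stop("bspline kind needs 'bspline'")
    fwd <- bspline
    inv <- structure(list(forward = bspline),
                     class = "bspline_numeric_inverse")
  }
  structure(list(kind = kind, forward = fwd, inverse = inv),
            class = "gt_deformation")
}

#' @export
transform_point.bspline_numeric_inverse <- function(transform, p) {
  p <- rbind3(p)
  q <- p
  for (i in 1:40) {
    d <- bspline_displacement(transform$forward, q)$disp
    qn <- p - d
    if (max(abs(qn - q)) < 1e-4) { q <- qn; break }
    q <- qn
  }
  q
}

#' @export
print.gt_deformation <- function(x, ...) {
  cat(sprintf("<gt_deformation> %s\n", x$kind))
  invisible(x)
}

#' Seeded random rigid + scaling misalignment
#'
#' Draws rotation angles, translations and per-axis scalings uniformly
#' within the given bounds (defaults: rotation up to 10 degrees,
#' translation up to 15 mm, scaling within 8 percent), the regime used for
#' the registration recovery experiments.
#'
#' @param seed integer.
#' @param max_rotation_deg,max_translation_mm,max_scaling bounds.
#' @param center rotation centre (typically the knee centre).
#' @return a [ground_truth_deformation()] of kind `"rigid"`.
#' @export
random_rigid_scaling <- function(seed, max_rotation_deg = 10,
                                 max_translation_mm = 15,
                                 max_scaling = 0.08, center = c(0, 0, 0)) {
  par <- with_seed(derive_seed(seed, 17L),
                   list(rot = stats::runif(3, -max_rotation_deg,
                                           max_rotation_deg),
                        tr = stats::runif(3, -max_translation_mm,
                                          max_translation_mm),
                        sc = stats::runif(3, 1 - max_scaling,
                                          1 + max_scaling)))
  ground_truth_deformation("rigid", rotation_deg = par$rot,
                           translation = par$tr, scaling = par$sc,
                           center = center)
}

#' Apply a ground-truth deformation to a paired scan
#'
#' The CT and SPECT are resampled through the deformation's inverse, so the
#' forward map is exactly what a registration (fixed = original, moving =
#' deformed) must recover; landmarks travel through the forward map.
#'
#' @param scan a [paired_scan()].
#' @param deformation a [ground_truth_deformation()].
#' @param interpolator resampling scheme.
#' @return the deformed `paired_scan` (same grids).
#' @export
apply_ground_truth <- function(scan, deformation,
                               interpolator = "linear") {
  stopifnot(inherits(deformation, "gt_deformation"))
  lm_new <- transform_point(deformation$forward, unclass(scan$landmarks))
  for (a in 1:3) {
    lim <- scan$ct$origin[a] +
      c(0, (img_dim(scan$ct)[a] - 1) * scan$ct$spacing[a])
    if (any(lm_new[, a] < lim[1] | lm_new[, a] > lim[2]))
      stop("deformation pushes a landmark outside the grid")
  }
  scan$ct <- resample_moving(scan$ct, deformation$inverse, scan$ct,
                             interpolator = interpolator)
  scan$spect <- resample_moving(scan$spect, deformation$inverse,
                                scan$spect, interpolator = interpolator)
  scan$landmarks <- landmark_set(`rownames<-`(lm_new,
                                              rownames(scan$landmarks)))
  attr(scan, "ground_truth") <- deformation
  scan
}

#' Generate a synthetic cohort of pre/post-operative subjects
#'
#' Each subject is an anthropometric affine variation (per-axis scaling and
#' a small shear) of the base anatomy. The post-operative scan carries the
#' implant and the post-operative-only hotspot; the pre-operative scan of
#' the same subject omits both and is misaligned by a seeded random rigid
#' motion (the patient repositioning a registration must undo). Subject 1
#' uses the base anatomy unchanged and is the conventional reference
#' subject.
#'
#' @param n number of subjects.
#' @param base_spec a [phantom_spec()].
#' @param scale_range half-width of the per-axis anthropometric scaling
#'   interval (0.10 = +-10 percent).
#' @param shear_max magnitude bound of the anthropometric shear terms.
#' @param misalign list of bounds for the pre-operative misalignment,
#'   `list(rot, trans, scale)`.
#' @param seed integer.
#' @return a list of class `knee_cohort`; each element holds `postop`,
#'   `preop`, `gt` (the pre-operative misalignment) and `anat`.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            scale_range = 0.10, shear_max = 0.02,
                            misalign = list(rot = 10, trans = 15,
                                            scale = 0),
                            seed = 1L) {
  stopifnot(n >= 1)
  center <- base_spec$dims * base_spec$spacing / 2
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    anat <- if (i == 1L) NULL else {
      par <- with_seed(derive_seed(seed, 1000L + i), {
        list(sc = stats::runif(3, 1 - scale_range, 1 + scale_range),
             sh = stats::runif(2, -shear_max, shear_max))
      })
      A <- diag(par$sc)
      A[1, 3] <- par$sh[1]; A[2, 3] <- par$sh[2]
      affine_transform(A, c(0, 0, 0), center = center)
    }
    args <- unclass(base_spec)[intersect(names(base_spec),
                                         names(formals(phantom_spec)))]
    args$anat <- anat
    args$seed <- derive_seed(seed, 2000L + i)
    args$texture_seed <- derive_seed(seed, 5000L + i)
    spec_post <- do.call(phantom_spec, args)
    post <- generate_knee_phantom(spec_post, "postop",
                                  subject_id = sprintf("S%02d", i))
    spec_pre <- spec_post
    spec_pre$implant <- FALSE
    spec_pre$seed <- derive_seed(seed, 3000L + i)
    pre0 <- generate_knee_phantom(spec_pre, "preop",
                                  subject_id = sprintf("S%02d", i))
    gt <- random_rigid_scaling(derive_seed(seed, 4000L + i),
                               max_rotation_deg = misalign$rot,
                               max_translation_mm = misalign$trans,
                               max_scaling = misalign$scale,
                               center = center)
    pre <- apply_ground_truth(pre0, gt)
    subjects[[i]] <- list(postop = post, preop = pre, gt = gt, anat = anat)
  }
  structure(subjects, class = "knee_cohort", reference = 1L, seed = seed)
}
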