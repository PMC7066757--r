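# End-to-end orchestration: preprocess -> register intra -> register inter
# -> SPECT analysis -> validation.

COMMON_SPACING <- c(0.98, 0.98, 3)

#' Read a cohort manifest
#'
#' Tab-separated text, one row per subject/timepoint, with columns
#' `subject_id`, `timepoint` (`preop`/`postop`), `ct`, `spect`,
#' `landmarks` (paths), `laterality` (`L`/`R`) and `reference`
#' (`TRUE` for exactly one post-operative row in inter-subject mode).
#'
#' @param path manifest file.
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timepoint", "ct", "spect", "landmarks",
            "laterality")
  missing <- setdiff(need, names(mf))
  if (length(missing))
    stop("manifest misses column(s): ", paste(missing, collapse = ", "))
  if (is.null(mf$reference)) mf$reference <- FALSE
  mf
}

#' Preprocess every scan of a manifest
#'
#' Per subject/timepoint: read the CT/SPECT/landmark triplet, resample both
#' volumes to the common 0.98 x 0.98 x 3 mm grid, reflect right legs to
#' left laterality, build the three bone VOIs and segment bone (with
#' prosthesis exclusion on post-operative scans). Outputs are persisted
#' under `outdir` together with a sidecar log of thresholds and margins. A
#' failing subject is skipped with a logged reason; the run continues.
#'
#' @param manifest data frame from [read_manifest()] (or a path).
#' @param outdir output directory.
#' @param bone_low,prosthesis_low HU thresholds for [segment_bone()].
#' @param margin_mm VOI margin for [build_voi()].
#' @return invisibly, a status data frame (one row per manifest row).
#' @export
run_preprocess <- function(manifest, outdir, bone_low = 200,
                           prosthesis_low = 2500,
                           margin_mm = c(20, 20, 20)) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  status <- data.frame(subject_id = manifest$subject_id,
                       timepoint = manifest$timepoint, ok = FALSE,
                       message = "", stringsAsFactors = FALSE)
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      scan <- read_paired_scan(row$ct, row$spect, row$landmarks,
                               laterality = row$laterality,
                               timepoint = row$timepoint,
                               subject_id = row$subject_id)
      scan <- preprocess_scan(scan)
      sdir <- file.path(outdir, paste0(row$subject_id, "_", row$timepoint))
      dir.create(sdir, showWarnings = FALSE)
      write_image(scan$ct, file.path(sdir, "ct.nii.gz"))
      write_image(scan$spect, file.path(sdir, "spect.nii.gz"))
      write_landmarks(scan$landmarks, file.path(sdir, "landmarks.txt"))
      plow <- if (row$timepoint == "postop") prosthesis_low else Inf
      for (bone in names(VOI_LANDMARKS)) {
        box <- build_voi(scan$landmarks, bone, scan$ct, margin_mm)
        voi <- crop(scan$ct, box)
        mask <- suppressWarnings(segment_bone(voi, bone_low, plow,
                                              bone = bone))
        write_image(vol_image(mask$mask + 0, voi$spacing, voi$origin, "CT"),
                    file.path(sdir, paste0(bone, "_mask.nii.gz")))
        writeLines(c(sprintf("bone %s", bone),
                     sprintf("voi_lower %s", paste(box$lower,
                                                   collapse = " ")),
                     sprintf("voi_upper %s", paste(box$upper,
                                                   collapse = " ")),
                     sprintf("bone_low %g", bone_low),
                     sprintf("prosthesis_low %g", plow),
                     sprintf("margin_mm %s", paste(margin_mm,
                                                   collapse = " ")),
                     sprintf("prosthesis_excluded %s",
                             mask$prosthesis_excluded),
                     sprintf("empty %s", mask$empty)),
                   file.path(sdir, paste0(bone, "_voi.txt")))
      }
      "ok"
    }, error = function(e) conditionMessage(e))
    status$ok[r] <- identical(res, "ok")
    status$message[r] <- if (status$ok[r]) "" else res
  }
  utils::write.table(status, file.path(outdir, "preprocess_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(status)
}

# resample a paired scan to the common grid and force left laterality
preprocess_scan <- function(scan, target_spacing = COMMON_SPACING) {
  scan$ct <- resample(scan$ct, target_spacing, "linear")
  scan$spect <- resample(scan$spect, target_spacing, "linear")
  reflect_sagittal(scan)
}

#' Analyze an in-memory cohort end to end
#'
#' For every subject: intra-subject affine registration of the
#' pre-operative scan onto the post-operative scan (prosthesis masked),
#' uptake normalization of both SPECT volumes, the voxel-wise
#' post-minus-pre difference map on the post-operative VOI grid; then
#' inter-subject registration (affine + B-spline, no prosthesis masking) of
#' every non-reference subject onto the reference and resampling of the
#' difference maps into reference space; finally the cohort aggregate map
#' and a validation report (pre/post DSC per subject, landmark differences,
#' Wilcoxon signed-rank test of the DSC improvement).
#'
#' @param cohort a [generate_cohort()] result, or any list of
#'   `list(postop =, preop =)` paired scans.
#' @param bone which VOI drives registration and the maps.
#' @param config_affine,config_bspline [registration_config()]s.
#' @param reference index of the reference subject.
#' @param seed stochastic seed.
#' @param norm_dims,norm_offset normalization ROI geometry.
#' @param inter run the inter-subject stage (skipped with a message for a
#'   single-subject cohort).
#' @return a list of class `cohort_analysis`: `aggregate`, `per_subject`,
#'   `report` (data frame), `dsc_test`.
#' @export
analyze_cohort <- function(cohort, bone = "tibia",
                           config_affine = registration_config("affine"),
                           config_bspline = registration_config("bspline"),
                           reference = 1L, seed = 1L,
                           norm_dims = c(35, 20, 3), norm_offset = 100,
                           inter = length(cohort) > 1L) {
  n <- length(cohort)
  ref_post <- cohort[[reference]]$postop
  voi_ref <- build_voi(ref_post$landmarks, bone, ref_post$ct)
  ref_grid <- crop(ref_post$ct, voi_ref)
  per_subject <- vector("list", n)
  diffs <- list()
  report <- NULL
  for (i in seq_len(n)) {
    sub <- cohort[[i]]
    post <- sub$postop; pre <- sub$preop
    # SPECT carried on the resampled CT grid, normalized per scan
    post_spect <- resample(post$spect, post$ct$spacing, "linear")
    pre_spect <- resample(pre$spect, pre$ct$spacing, "linear")
    roi_post <- build_normalization_roi(post$landmarks["FKC", ],
                                        post_spect, norm_dims, norm_offset)
    roi_pre <- build_normalization_roi(pre$landmarks["FKC", ], pre_spect,
                                       norm_dims, norm_offset)
    post_spect <- normalize_uptake(post_spect, roi_post)
    pre_spect <- normalize_uptake(pre_spect, roi_pre)
    intra <- register_intra(post, pre, bone = bone, config = config_affine,
                            seed = derive_seed(seed, 10L + i),
                            resample_spect = FALSE)
    fixed <- intra$fixed
    # pre/post DSC of the bone masks on the fixed grid
    mm_pre <- resample_moving(vol_image(intra$moving_mask$mask + 0,
                                        intra$moving$spacing,
                                        intra$moving$origin, "CT"),
                              affine_transform(), fixed,
                              interpolator = "nearest", fill = 0)
    mm_post <- resample_moving(vol_image(intra$moving_mask$mask + 0,
                                         intra$moving$spacing,
                                         intra$moving$origin, "CT"),
                               intra$transform, fixed,
                               interpolator = "nearest", fill = 0)
    dsc_pre <- dice(intra$fixed_mask$mask, mm_pre$voxels > 0.5,
                    context = sprintf("%s pre-registration",
                                      post$subject_id))
    dsc_post <- dice(intra$fixed_mask$mask, mm_post$voxels > 0.5,
                     context = sprintf("%s post-registration",
                                       post$subject_id))
    primary <- c("FKC", "FME", "FLE", "FTP")
    mapped <- transform_point(invert_affine(intra$transform),
                              unclass(pre$landmarks)[primary, ,
                                                     drop = FALSE])
    rownames(mapped) <- primary
    lerr <- landmark_error(
      landmark_set(unclass(post$landmarks)[primary, , drop = FALSE]),
      landmark_set(mapped), spacing = post$ct$spacing)
    # difference map on the post-operative VOI grid
    post_voi_spect <- crop(post_spect, build_voi(post$landmarks, bone,
                                                 post$ct))
    pre_aligned <- resample_moving(pre_spect, intra$transform, fixed,
                                   interpolator = "linear", fill = NA_real_)
    dmap <- difference_map(post_voi_spect, pre_aligned,
                           subject_id = post$subject_id)
    inter_res <- NULL
    if (inter && i != reference) {
      inter_res <- register_inter(ref_post, post, bone = bone,
                                  config_affine = config_affine,
                                  config_bspline = config_bspline,
                                  seed = derive_seed(seed, 50L + i))
      dref <- resample_moving(dmap, inter_res$transform, ref_grid,
                              interpolator = "linear", fill = NA_real_)
    } else {
      dref <- if (i == reference) dmap else NULL
    }
    if (!is.null(dref)) {
      attr(dref, "subject_id") <- post$subject_id
      class(dref) <- c("diff_map", "vol_image")
      diffs[[length(diffs) + 1L]] <- dref
    }
    per_subject[[i]] <- list(subject_id = post$subject_id, intra = intra,
                             inter = inter_res, dsc_pre = dsc_pre,
                             dsc_post = dsc_post, landmark_error = lerr,
                             difference = dmap)
    report <- rbind(report, data.frame(
      subject_id = post$subject_id, bone = bone,
      dsc_pre = dsc_pre$dsc, dsc_post = dsc_post$dsc,
      dsc_pass = dsc_post$dsc >= 0.80,
      landmark_pass = lerr$pass, stringsAsFactors = FALSE))
  }
  if (!inter && n > 1L)
    message("inter-subject stage skipped; difference maps stay in ",
            "subject space")
  if (!inter && n == 1L)
    message("single-subject cohort: inter-subject stage skipped")
  test <- if (n >= 2)
    compare_dsc_prepost(report$dsc_pre, report$dsc_post) else NULL
  agg <- if (length(diffs)) aggregate_map(diffs) else NULL
  structure(list(aggregate = agg, per_subject = per_subject,
                 report = report, dsc_test = test,
                 reference = reference, bone = bone),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects, %s VOI, reference subject %d\n",
              nrow(x$report), x$bone, x$reference))
  print(x$report, row.names = FALSE)
  if (!is.null(x$dsc_test)) print(x$dsc_test)
  invisible(x)
}

#' Run the full file-based pipeline
#'
#' Reads a manifest of NIfTI scans, preprocesses them, runs the cohort
#' analysis and writes the aggregate map, the per-subject transforms and a
#' machine-readable validation report under `outdir`.
#'
#' @inheritParams run_preprocess
#' @inheritParams analyze_cohort
#' @return the [analyze_cohort()] result, invisibly.
#' @export
run_full_pipeline <- function(manifest, outdir, bone = "femur",
                              config_affine = registration_config("affine"),
                              config_bspline =
                                registration_config("bspline"),
                              seed = 1L, bone_low = 200,
                              prosthesis_low = 2500) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(manifest$subject_id)
  cohort <- list()
  loaded <- character(0)
  for (id in ids) {
    rows <- manifest[manifest$subject_id == id, ]
    res <- tryCatch({
      get_scan <- function(tp) {
        rr <- rows[rows$timepoint == tp, ]
        if (nrow(rr) != 1L) stop("subject ", id, " needs exactly one ",
                                 tp, " row")
        preprocess_scan(read_paired_scan(rr$ct, rr$spect, rr$landmarks,
                                         laterality = rr$laterality,
                                         timepoint = tp, subject_id = id))
      }
      cohort[[length(cohort) + 1L]] <- list(postop = get_scan("postop"),
                                            preop = get_scan("preop"))
      loaded <- c(loaded, id)
      "ok"
    }, error = function(e) conditionMessage(e))
    if (!identical(res, "ok"))
      warning("subject ", id, " skipped: ", res)
  }
  if (!length(cohort)) stop("no subject could be loaded")
  ref_id <- manifest$subject_id[which(manifest$reference)[1]]
  reference <- if (!is.na(ref_id) && ref_id %in% loaded)
    match(ref_id, loaded) else 1L
  ana <- analyze_cohort(cohort, bone = bone,
                        config_affine = config_affine,
                        config_bspline = config_bspline,
                        reference = reference, seed = seed)
  if (!is.null(ana$aggregate)) {
    write_image(ana$aggregate$mean, file.path(outdir,
                                              "aggregate_mean.nii.gz"))
    write_image(vol_image(ana$aggregate$count + 0,
                          ana$aggregate$mean$spacing,
                          ana$aggregate$mean$origin, "SPECT"),
                file.path(outdir, "aggregate_count.nii.gz"))
  }
  for (ps in ana$per_subject) {
    write_transform(ps$intra$transform,
                    file.path(outdir, paste0(ps$subject_id,
                                             "_intra_transform.txt")))
    if (!is.null(ps$inter))
      write_transform(ps$inter$transform,
                      file.path(outdir, paste0(ps$subject_id,
                                               "_inter_transform.txt")))
  }
  utils::write.table(ana$report, file.path(outdir, "validation_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("subjects %s", paste(loaded, collapse = " ")),
               sprintf("reference %s", loaded[reference]),
               sprintf("bone %s", bone),
               sprintf("seed %d", seed),
               sprintf("version %s",
                       as.character(utils::packageVersion("spectreg")))),
             file.path(outdir, "provenance.txt"))
  invisible(ana)
}
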