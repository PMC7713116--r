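# Per-eye and cohort orchestration: geometry -> drusen -> ez -> ccflow,
# with stage-tagged error propagation and an audit trail (chosen thresholds,
# per-region pixel counts, component counts) carried on the record.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline for one eye
#'
#' Executes segmentation, drusen delineation, EZ normalized reflectivity and
#' CC flow-deficit quantification for a single eye and returns one record
#' row plus the intermediate images. The eye is either a phantom
#' specification (an entry of [generate_cohort()], or a bare
#' [phantom_config()]) or a list with en-face `flow` and `structure`
#' [oct_raster()]s for a CC-only run.
#'
#' Any stage failure propagates with the stage name prefixed. If no pixel of
#' the ROI reaches `min_elevation_um`, the eye is treated as drusen-free
#' (empty drusen mask; the binarization of a flat elevation map would only
#' partition noise).
#'
#' @param eye Eye input (see Details).
#' @param roi_diameter_mm ROI diameter (default 5).
#' @param slab EZ [slab_spec()].
#' @param cc_slab [cc_slab_spec()] (used only when CC en-face images are
#'   derived from a volume).
#' @param phans [phansalkar_params()].
#' @param min_equiv_diameter_um Small-deficit cutoff (default 24 um).
#' @param min_elevation_um Drusen area/volume elevation threshold
#'   (default 20 um).
#' @param elevation_smooth_px Optional Gaussian smoothing (pixels) of the
#'   elevation map before binarization (default 0: the raw surface
#'   difference is binarized).
#' @param vessel_mask Optional logical matrix of major retinal vessels.
#' @param out_dir Optional directory for intermediate images and the record.
#' @return List of class `eye_run`: `record` (one-row data frame) and
#'   `artifacts` (elevation map, masks, EZ en-face, deficit mask, surfaces).
#' @export
run_eye <- function(eye, roi_diameter_mm = 5, slab = slab_spec(),
                    cc_slab = cc_slab_spec(), phans = phansalkar_params(),
                    min_equiv_diameter_um = 24, min_elevation_um = 20,
                    elevation_smooth_px = 0, vessel_mask = NULL,
                    out_dir = NULL) {
  if (inherits(eye, "phantom_config"))
    eye <- list(eye_id = "eye", group = NA_character_, config = eye,
                planted = NULL)
  if (!is.null(eye$config)) {
    cfg <- eye$config
    gen <- with_stage("phantom", generate_volume(cfg))
    cc <- with_stage("phantom", generate_cc_pair(cfg))
    volume <- gen$volume
    truth <- gen$truth
    flow <- cc$flow; struct_raster <- cc$structure
    cc_truth <- cc$truth
  } else {
    volume <- NULL; truth <- NULL; cc_truth <- NULL
    flow <- eye$flow; struct_raster <- eye$structure
    if (is.null(flow)) stop("[stage input] no flow raster supplied")
  }

  pitch <- if (!is.null(volume)) volume$lateral_pitch_um else flow$pitch_um
  shape <- if (!is.null(volume)) dim(volume$values)[2:3] else dim(flow$values)
  roi <- with_stage("geometry",
    circular_roi_mask(shape, pitch, (shape[1] + 1) / 2, (shape[2] + 1) / 2,
                      roi_diameter_mm))

  em <- NULL; masks <- NULL; dav <- NULL; ez <- NULL
  rpe <- NULL; floor <- NULL
  if (!is.null(volume)) {
    rpe <- with_stage("geometry", segment_rpe(volume))
    floor <- with_stage("geometry", fit_rpe_floor(rpe))
    em <- with_stage("drusen",
      elevation_map(rpe, floor, pitch, smooth_sigma_px = elevation_smooth_px))
    masks <- with_stage("drusen", {
      if (max(em$elevation$values[roi]) < min_elevation_um) {
        structure(list(roi = roi,
                       drusen = matrix(FALSE, shape[1], shape[2]),
                       drusen_free = roi, threshold = NA_integer_),
                  class = "region_masks")
      } else drusen_masks(em, roi)
    })
    dav <- with_stage("drusen", drusen_area_volume(em, roi, min_elevation_um))
    ez <- with_stage("ez", {
      enface <- extract_ez_enface(volume, rpe, slab)
      mu_vit <- sample_reference(volume, truth$reference_bands$vitreous)
      mu_rnfl <- sample_reference(volume, truth$reference_bands$rnfl)
      regional_reflectivity(enface, masks, mu_vit, mu_rnfl, vessel_mask)
    })
  } else {
    masks <- structure(list(roi = roi,
                            drusen = matrix(FALSE, shape[1], shape[2]),
                            drusen_free = roi, threshold = NA_integer_),
                       class = "region_masks")
  }

  if (is.null(struct_raster)) stop("[stage ccflow] missing structure raster for compensation")
  comp <- with_stage("ccflow", compensate_flow(flow, struct_raster, roi = roi))
  raw_def <- with_stage("ccflow", phansalkar_binarize(comp, phans))
  def <- with_stage("ccflow",
    remove_small_deficits(raw_def, pitch, min_equiv_diameter_um))
  n_before <- max(label_components(raw_def))
  n_after <- max(label_components(def))

  analysis_roi <- remove_projection_artifacts(masks$roi, vessel_mask)
  fd_rows <- with_stage("ccflow", {
    rows <- list(fd_metrics(def, analysis_roi, pitch, "whole-ROI"))
    df_mask <- remove_projection_artifacts(masks$drusen_free, vessel_mask)
    if (any(df_mask))
      rows[["df"]] <- fd_metrics(def, df_mask, pitch, "drusen-free")
    dr_mask <- remove_projection_artifacts(masks$drusen, vessel_mask)
    if (any(dr_mask))
      rows[["dr"]] <- fd_metrics(def, dr_mask, pitch, "drusen")
    rows
  })
  pick <- function(lbl, col) {
    for (r in fd_rows) if (r$region_label == lbl) return(r[[col]])
    NA_real_
  }

  record <- data.frame(
    eye_id = if (is.null(eye$eye_id)) "eye" else eye$eye_id,
    group = if (is.null(eye$group)) NA_character_ else eye$group,
    ez_norm_whole = if (is.null(ez)) NA_real_ else ez$ez_norm_whole,
    ez_norm_drusen_free = if (is.null(ez)) NA_real_ else ez$ez_norm_drusen_free,
    ez_norm_drusen = if (is.null(ez)) NA_real_ else ez$ez_norm_drusen,
    fd_percent_whole = pick("whole-ROI", "fd_percent"),
    fd_percent_drusen_free = pick("drusen-free", "fd_percent"),
    fd_percent_drusen = pick("drusen", "fd_percent"),
    fd_mean_size_whole = pick("whole-ROI", "fd_mean_size_um2"),
    fd_mean_size_drusen_free = pick("drusen-free", "fd_mean_size_um2"),
    fd_mean_size_drusen = pick("drusen", "fd_mean_size_um2"),
    fd_count_whole = pick("whole-ROI", "fd_count"),
    drusen_area_mm2 = if (is.null(dav)) NA_real_ else dav$area_mm2,
    drusen_volume_mm3 = if (is.null(dav)) NA_real_ else dav$volume_mm3,
    drusen_percent_of_roi = if (is.null(dav)) NA_real_ else dav$percent_of_roi,
    maxentropy_threshold = if (is.null(masks$threshold)) NA_integer_ else
      masks$threshold,
    roi_px = sum(masks$roi), drusen_px = sum(masks$drusen),
    drusen_free_px = sum(masks$drusen_free),
    fd_components_before_removal = n_before,
    fd_components_after_removal = n_after,
    planted_ez_target = if (is.null(eye$planted)) NA_real_ else
      eye$planted$ez_target,
    planted_fd_fraction = if (is.null(cc_truth)) NA_real_ else
      cc_truth$true_fd_fraction,
    stringsAsFactors = FALSE)

  artifacts <- list(roi = roi, elevation = em, masks = masks, ez = ez,
                    compensated = comp, deficits = def, rpe = rpe,
                    floor = floor, truth = truth, cc_truth = cc_truth,
                    fd_rows = do.call(rbind, unname(fd_rows)))
  if (!is.null(out_dir)) write_eye_artifacts(out_dir, record, artifacts, pitch)
  structure(list(record = record, artifacts = artifacts), class = "eye_run")
}

#' Run a phantom cohort through the pipeline
#'
#' Processes every eye of a [generate_cohort()] specification, concatenates
#' the per-eye records, and reproduces the cohort analysis plan: two-group
#' comparisons (normality-gated t / Mann-Whitney) for each outcome variable,
#' and Spearman correlations of EZ normalized reflectivity against CC and
#' drusen metrics in the whole ROI and the drusen-free region. For control
#' eyes (no drusen) the drusen-free values coincide with the whole-ROI
#' values, and affected-group drusen-free metrics are compared against the
#' controls' whole-region values.
#'
#' @param cohort A `phantom_cohort`, or a list of eye inputs accepted by
#'   [run_eye()].
#' @param ... Passed on to [run_eye()].
#' @return List of class `cohort_run`: `records`, `comparisons`,
#'   `correlations`.
#' @export
run_cohort <- function(cohort, ...) {
  eyes <- if (inherits(cohort, "phantom_cohort")) cohort$eyes else cohort
  if (length(eyes) == 0L) stop("empty cohort")
  records <- do.call(rbind, lapply(eyes, function(e) {
    withCallingHandlers(run_eye(e, ...)$record,
                        warning = function(w) invokeRestart("muffleWarning"))
  }))
  groups <- unique(records$group)
  comparisons <- NULL
  if (length(groups) >= 2) {
    amd <- records[records$group == "AMD", ]
    ctl <- records[records$group == "control", ]
    vars <- c(ez = "ez_norm", fd = "fd_percent", fdsize = "fd_mean_size")
    rows <- list()
    for (v in vars) {
      for (reg in c("whole", "drusen_free")) {
        acol <- paste0(v, "_", reg)
        r <- compare_groups(amd[[acol]], ctl[[paste0(v, "_whole")]])
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(variable = v, region = sub("_", "-", reg)), r)
      }
    }
    comparisons <- do.call(rbind, rows)
  } else {
    warning("single-group cohort: comparisons skipped")
  }

  corr_rows <- list()
  add_corr <- function(df, grp, xcol, ycol) {
    ok <- is.finite(df[[xcol]]) & is.finite(df[[ycol]])
    if (sum(ok) >= 4 && stats::sd(df[[xcol]][ok]) > 0 &&
        stats::sd(df[[ycol]][ok]) > 0) {
      r <- spearman_corr(df[[xcol]], df[[ycol]])
      corr_rows[[length(corr_rows) + 1L]] <<-
        cbind(data.frame(group = grp, x = xcol, y = ycol), r)
    }
  }
  for (grp in groups) {
    d <- records[records$group == grp, ]
    add_corr(d, grp, "ez_norm_whole", "fd_percent_whole")
    add_corr(d, grp, "ez_norm_whole", "fd_mean_size_whole")
    add_corr(d, grp, "ez_norm_whole", "drusen_area_mm2")
    add_corr(d, grp, "ez_norm_whole", "drusen_volume_mm3")
    add_corr(d, grp, "ez_norm_drusen_free", "fd_percent_drusen_free")
    add_corr(d, grp, "ez_norm_drusen_free", "fd_mean_size_drusen_free")
  }
  correlations <- if (length(corr_rows)) do.call(rbind, corr_rows) else NULL
  structure(list(records = records, comparisons = comparisons,
                 correlations = correlations), class = "cohort_run")
}

#' Cohort summary table (mean, SD, median, IQR per group and region)
#'
#' @param records Record data frame from [run_cohort()].
#' @return Data frame with one row per variable x group x region.
#' @export
summarize_cohort <- function(records) {
  vars <- c("ez_norm", "fd_percent", "fd_mean_size")
  rows <- list()
  for (grp in unique(records$group)) {
    d <- records[records$group == grp, ]
    for (v in vars) for (reg in c("whole", "drusen_free")) {
      x <- d[[paste0(v, "_", reg)]]
      x <- x[is.finite(x)]
      if (!length(x)) next
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = grp, region = sub("_", "-", reg),
        n = length(x), mean = mean(x), sd = stats::sd(x),
        median = q[2], q1 = q[1], q3 = q[3])
    }
  }
  do.call(rbind, rows)
}
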