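# Raster/volume/mask readers and writers.  En-face images go to 8/16-bit
# grayscale TIFF or PNG; volumes to multi-page TIFF; elevation maps to
# 16-bit TIFF in fixed-point um x 10; scalar truth to a JSON sidecar.

#' Write an en-face raster as grayscale TIFF
#'
#' @param raster An [oct_raster()].
#' @param path Output path.
#' @param max_value Intensity mapped to full scale (default: raster max, or
#'   1 if the raster is empty of signal).
#' @param bits 8 or 16.
#' @export
write_raster_tiff <- function(raster, path, max_value = NULL, bits = 16) {
  stopifnot(inherits(raster, "oct_raster"))
  if (is.null(max_value)) max_value <- max(raster$values, 1e-12)
  m <- pmin(pmax(raster$values / max_value, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a grayscale TIFF as an en-face raster
#'
#' @param path Input path.
#' @param pitch_um Lateral pitch to attach, um/pixel.
#' @param max_value Intensity of the full scale (default 1).
#' @export
read_raster_tiff <- function(path, pitch_um, max_value = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  oct_raster(m * max_value, pitch_um)
}

#' Write an elevation map as 16-bit TIFF (fixed point, um x 10)
#' @param elev An `elevation_map`.
#' @param path Output path.
#' @export
write_elevation_tiff <- function(elev, path) {
  stopifnot(inherits(elev, "elevation_map"))
  m <- pmin(round(elev$elevation$values * 10) / 65535, 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a fixed-point elevation TIFF back into an `elevation_map`
#' @param path Input path.
#' @param pitch_um Lateral pitch, um/pixel.
#' @param render_clip_um Rendering ceiling (default 100).
#' @export
read_elevation_tiff <- function(path, pitch_um, render_clip_um = 100) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(elevation = oct_raster(m * 65535 / 10, pitch_um),
                 render_clip_um = render_clip_um),
            class = "elevation_map")
}

#' Write a logical mask as PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a PNG mask
#' @param path Input path.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write an OCT volume as multi-page TIFF
#' @param volume An [oct_volume()].
#' @param path Output path.
#' @param max_value Intensity mapped to full scale (default: volume max).
#' @export
write_volume_tiff <- function(volume, path, max_value = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(max_value)) max_value <- max(volume$values, 1e-12)
  pages <- lapply(seq_len(dim(volume$values)[1]), function(d)
    pmin(pmax(volume$values[d, , ] / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF volume
#' @param path Input path.
#' @param axial_pitch_um,lateral_pitch_um Pitches to attach.
#' @param max_value Intensity of the full scale (default 1).
#' @export
read_volume_tiff <- function(path, axial_pitch_um, lateral_pitch_um,
                             max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (d in seq_along(pages)) {
    m <- pages[[d]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    arr[d, , ] <- m * max_value
  }
  oct_volume(arr, axial_pitch_um, lateral_pitch_um)
}

# Per-eye artifact dump used by run_eye(out_dir = ...): intermediate images,
# the record row, and an audit log of the numbers needed to recheck any
# metric by hand.
write_eye_artifacts <- function(out_dir, record, artifacts, pitch_um) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(artifacts$elevation)) {
    write_elevation_tiff(artifacts$elevation,
                         file.path(out_dir, "elevation_um.tiff"))
    png::writePNG(render_elevation_8bit(artifacts$elevation) / 255,
                  file.path(out_dir, "elevation_8bit.png"))
  }
  write_mask_png(artifacts$roi, file.path(out_dir, "roi.png"))
  write_mask_png(artifacts$masks$drusen, file.path(out_dir, "drusen.png"))
  write_mask_png(artifacts$masks$drusen_free,
                 file.path(out_dir, "drusen_free.png"))
  write_raster_tiff(artifacts$compensated,
                    file.path(out_dir, "cc_compensated.tiff"), max_value = 1)
  write_mask_png(artifacts$deficits, file.path(out_dir, "deficits.png"))
  utils::write.csv(record, file.path(out_dir, "record.csv"),
                   row.names = FALSE)
  log <- c(sprintf("eye_id: %s", record$eye_id),
           sprintf("maxentropy_threshold_8bit: %s", record$maxentropy_threshold),
           sprintf("roi_px: %d  drusen_px: %d  drusen_free_px: %d",
                   record$roi_px, record$drusen_px, record$drusen_free_px),
           sprintf("fd_components before/after small-deficit removal: %d / %d",
                   record$fd_components_before_removal,
                   record$fd_components_after_removal))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Write scalar phantom truth as a JSON sidecar
#' @param truth List of scalar truth values.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  scalars <- truth[vapply(truth, function(x)
    is.atomic(x) && length(x) == 1L, logical(1))]
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a phantom eye to disk
#'
#' Materializes one phantom: the structural volume as multi-page TIFF, the
#' CC flow/structure pair as 16-bit TIFF, the planted truth rasters
#' (elevation as fixed-point TIFF, masks as PNG) and the scalar truth
#' values as a JSON sidecar.
#'
#' @param config A [phantom_config()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
save_phantom <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_volume(config)
  cc <- generate_cc_pair(config)
  write_volume_tiff(gen$volume, file.path(dir, "volume.tiff"))
  write_raster_tiff(cc$flow, file.path(dir, "cc_flow.tiff"), max_value = 1)
  write_raster_tiff(cc$structure, file.path(dir, "cc_structure.tiff"),
                    max_value = 1)
  write_elevation_tiff(
    structure(list(elevation = gen$truth$true_elevation,
                   render_clip_um = 100), class = "elevation_map"),
    file.path(dir, "true_elevation.tiff"))
  write_mask_png(gen$truth$true_drusen_mask,
                 file.path(dir, "true_drusen_mask.png"))
  write_mask_png(cc$truth$true_fd_mask, file.path(dir, "true_fd_mask.png"))
  write_truth_json(list(true_fd_fraction = cc$truth$true_fd_fraction,
                        seed = config$seed,
                        lateral_pitch_um = config$lateral_pitch_um,
                        axial_pitch_um = config$axial_pitch_um),
                   file.path(dir, "truth.json"))
  invisible(dir)
}
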