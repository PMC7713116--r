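#' Construct an en-face raster
#'
#' A 2-D en-face image on the scanning grid: a numeric `rows x cols` matrix of
#' non-negative intensities plus the lateral pixel pitch. All physical
#' quantities at API boundaries are expressed in micrometres (um) or
#' millimetres (mm), never in pixels.
#'
#' @param values Numeric matrix (rows x cols) of non-negative intensities.
#' @param pitch_um Lateral pixel pitch in um/pixel (default 12, i.e. a
#'   6 x 6 mm field sampled on a 500 x 500 grid).
#' @return An object of class `oct_raster` with elements `values`, `pitch_um`.
#' @export
oct_raster <- function(values, pitch_um = 12) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("raster values must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have positive dimensions")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0)
    stop("pitch_um must be a single positive number")
  structure(list(values = values, pitch_um = pitch_um), class = "oct_raster")
}

#' Construct a structural OCT volume
#'
#' Axial (depth) axis is the first array dimension, oriented vitreous ->
#' choroid; voxel centres sit at `z = (i - 0.5) * axial_pitch_um` from the top
#' of the volume.
#'
#' @param values Numeric 3-D array `(depth x rows x cols)`.
#' @param axial_pitch_um Axial sampling pitch, um/voxel.
#' @param lateral_pitch_um Lateral pixel pitch, um/pixel.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(values, axial_pitch_um, lateral_pitch_um) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume values must be a 3-D array (depth x rows x cols)")
  if (any(dim(values) < 1L)) stop("volume dimensions must be positive")
  if (axial_pitch_um <= 0 || lateral_pitch_um <= 0)
    stop("pitches must be positive")
  structure(list(values = values,
                 axial_pitch_um = axial_pitch_um,
                 lateral_pitch_um = lateral_pitch_um),
            class = "oct_volume")
}

#' Construct an axial surface
#'
#' Per-A-scan axial position map in um from the top of the volume (e.g. the
#' RPE surface, or its pathology-excluding floor fit).
#'
#' @param z_um Numeric matrix (rows x cols) of axial positions in um.
#' @return An object of class `oct_surface`.
#' @export
oct_surface <- function(z_um) {
  if (!is.matrix(z_um) || !is.numeric(z_um))
    stop("surface must be a numeric matrix of z positions (um)")
  if (any(!is.finite(z_um))) stop("surface positions must be finite")
  if (any(z_um < 0)) stop("surface positions must be non-negative")
  structure(list(z_um = z_um), class = "oct_surface")
}

#' @export
print.oct_raster <- function(x, ...) {
  cat(sprintf("<oct_raster> %d x %d px, pitch %.3g um/px (%.2f x %.2f mm)\n",
              nrow(x$values), ncol(x$values), x$pitch_um,
              nrow(x$values) * x$pitch_um / 1000,
              ncol(x$values) * x$pitch_um / 1000))
  invisible(x)
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<oct_volume> %d x %d x %d voxels (depth x rows x cols), %.3g um axial, %.3g um lateral\n",
    d[1], d[2], d[3], x$axial_pitch_um, x$lateral_pitch_um))
  invisible(x)
}

#' @export
print.oct_surface <- function(x, ...) {
  cat(sprintf("<oct_surface> %d x %d px, z range [%.1f, %.1f] um\n",
              nrow(x$z_um), ncol(x$z_um), min(x$z_um), max(x$z_um)))
  invisible(x)
}

# Voxel index range whose centres fall in the half-open axial band
# [z_top, z_bottom) um.  Shared by the phantom layer builder and the slab
# extractors so that noiseless construction and measurement agree exactly.
axial_band_indices <- function(z_top, z_bottom, axial_pitch_um) {
  i_lo <- ceiling(z_top / axial_pitch_um + 0.5)
  i_hi <- ceiling(z_bottom / axial_pitch_um + 0.5) - 1
  list(lo = i_lo, hi = i_hi)
}

assert_same_grid <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "oct_surface")) dim(a$z_um) else dim(a$values)
  db <- if (inherits(b, "oct_surface")) dim(b$z_um) else dim(b$values)
  if (!identical(da, db)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}
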