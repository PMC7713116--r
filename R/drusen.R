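#' RPE elevation map
#'
#' Elevation of the RPE above its pathology-excluding floor fit, in um:
#' `max(0, floor_z - rpe_z)` (depth increases towards the choroid, so an RPE
#' nearer the vitreous than the floor is positively elevated). The rendering
#' ceiling mirrors the heat-map convention of elevation exports: values are
#' mapped linearly from [0, `render_clip_um`] onto 8 bits, with higher
#' elevations saturating.
#'
#' @param rpe,floor [oct_surface()] objects on the same grid.
#' @param pitch_um Lateral pitch of the underlying grid, um/pixel.
#' @param render_clip_um Rendering ceiling in um (default 100).
#' @param smooth_sigma_px Optional Gaussian smoothing (pixels) of the
#'   elevation before clamping at zero, to suppress the axial-quantization
#'   staircase of voxel-resolution segmentation; 0 (the default) keeps the
#'   raw per-pixel difference.
#' @return List of class `elevation_map`: `elevation` (an [oct_raster()] of
#'   um) and `render_clip_um`.
#' @export
elevation_map <- function(rpe, floor, pitch_um, render_clip_um = 100,
                          smooth_sigma_px = 0) {
  stopifnot(inherits(rpe, "oct_surface"), inherits(floor, "oct_surface"))
  assert_same_grid(rpe, floor, "RPE and floor surfaces")
  diffz <- floor$z_um - rpe$z_um
  if (smooth_sigma_px > 0) diffz <- gaussian_smooth(diffz, smooth_sigma_px)
  elev <- pmax(diffz, 0)
  structure(list(elevation = oct_raster(elev, pitch_um),
                 render_clip_um = render_clip_um),
            class = "elevation_map")
}

#' 8-bit rendering of an elevation map
#'
#' @param elev An `elevation_map`.
#' @return Integer matrix of 8-bit levels (0..255); elevation at or above the
#'   clip renders at 255.
#' @export
render_elevation_8bit <- function(elev) {
  stopifnot(inherits(elev, "elevation_map"))
  e <- pmin(elev$elevation$values, elev$render_clip_um)
  matrix(as.integer(round(255 * e / elev$render_clip_um)),
         nrow(e), ncol(e))
}

#' Drusen area and volume inside the ROI
#'
#' Area of the RPE considerably elevated above the floor, and the volume of
#' that elevation, within the fovea-centred circle. "Considerably elevated"
#' is operationalized as `elevation >= min_elevation_um` (default 20 um,
#' configurable).
#'
#' @param elev An `elevation_map`.
#' @param roi Logical ROI mask on the same grid.
#' @param min_elevation_um Elevation threshold in um (>= 0).
#' @return Data frame with `area_mm2`, `volume_mm3`, `percent_of_roi`.
#' @export
drusen_area_volume <- function(elev, roi, min_elevation_um = 20) {
  stopifnot(inherits(elev, "elevation_map"), is.matrix(roi))
  if (min_elevation_um < 0) stop("min_elevation_um must be >= 0")
  e <- elev$elevation$values
  if (!identical(dim(e), dim(roi))) stop("ROI not on the elevation grid")
  px_mm2 <- (elev$elevation$pitch_um / 1000)^2
  sel <- roi & e >= min_elevation_um
  area <- sum(sel) * px_mm2
  volume <- sum(e[sel]) * px_mm2 / 1000    # um * mm^2 -> mm^3
  data.frame(area_mm2 = area, volume_mm3 = volume,
             percent_of_roi = 100 * sum(sel) / sum(roi))
}

#' Maximum-entropy (Kapur) histogram threshold
#'
#' Returns the 8-bit gray level `t` maximizing the sum of Shannon entropies
#' of the background (levels `0..t`) and foreground (levels `t+1..255`)
#' class histograms, computed over 256 bins; empty bins contribute zero
#' entropy and ties are broken by the lowest `t`. Inputs that are not
#' already 8-bit integers are quantized linearly from their range onto
#' 0..255 first.
#'
#' @param image Numeric matrix or vector of intensities.
#' @return The selected threshold on the 8-bit scale; attribute `levels`
#'   holds the quantized values used.
#' @export
max_entropy_threshold <- function(image) {
  v <- as.vector(image)
  if (!length(v)) stop("empty image")
  if (all(v == as.integer(v)) && min(v) >= 0 && max(v) <= 255) {
    q <- as.integer(v)
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) stop("constant image: no threshold exists")
    q <- as.integer(round(255 * (v - rng[1]) / (rng[2] - rng[1])))
  }
  if (length(unique(q)) < 2L)
    stop("constant image after 8-bit quantization: no threshold exists")
  h <- tabulate(q + 1L, nbins = 256L)
  p <- h / sum(h)
  csum <- cumsum(p)
  ent_cum <- cumsum(ifelse(p > 0, -p * log(p), 0))
  ent_tot <- ent_cum[256]
  best_t <- NA_integer_; best_h <- -Inf
  for (t in 0:254) {
    Pb <- csum[t + 1L]
    Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) next
    Hb <- ent_cum[t + 1L] / Pb + log(Pb)
    Hf <- (ent_tot - ent_cum[t + 1L]) / Pf + log(Pf)
    tot <- Hb + Hf
    if (tot > best_h) { best_h <- tot; best_t <- t }
  }
  structure(best_t, levels = q)
}

#' Partition the ROI into drusen and drusen-free regions
#'
#' Applies the maximum-entropy threshold to the 8-bit elevation rendering,
#' using only pixels inside the ROI; pixels above the threshold form the
#' drusen mask and the remainder of the ROI the drusen-free mask. A
#' (near-)constant elevation inside the ROI -- a healthy eye -- yields an
#' empty drusen mask with a warning.
#'
#' @param elev An `elevation_map`.
#' @param roi Logical ROI mask.
#' @return List of class `region_masks`: `roi`, `drusen`, `drusen_free`
#'   (logical matrices partitioning the ROI exactly), plus the `threshold`
#'   chosen on the 8-bit scale (NA for the healthy path).
#' @export
drusen_masks <- function(elev, roi) {
  stopifnot(inherits(elev, "elevation_map"), is.matrix(roi))
  r8 <- render_elevation_8bit(elev)
  if (!identical(dim(r8), dim(roi))) stop("ROI not on the elevation grid")
  vals <- r8[roi]
  if (length(unique(vals)) < 2L) {
    warning("constant elevation inside ROI: no drusen detected (healthy eye)")
    drusen <- matrix(FALSE, nrow(r8), ncol(r8))
    thr <- NA_integer_
  } else {
    thr <- as.integer(max_entropy_threshold(vals))
    drusen <- roi & r8 > thr
  }
  structure(list(roi = roi, drusen = drusen,
                 drusen_free = roi & !drusen, threshold = thr),
            class = "region_masks")
}
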