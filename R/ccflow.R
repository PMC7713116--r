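#' Phansalkar local-threshold parameters
#'
#' Local adaptive threshold for low-contrast images, applied to intensities
#' on the [0, 1] scale: over the circular window of `window_radius_px`
#' around each pixel, with local mean `m` and (population) SD `s`, the
#' threshold is `T = m * (1 + p * exp(-q * m) + k * (s / R - 1))`; a pixel
#' is a flow deficit iff its value is `<= T` (flow signal is the bright
#' phase). The constants default to the method's published values; only the
#' window radius (3 px) is study-specific.
#'
#' @param window_radius_px Circular window radius in pixels (default 3).
#' @param p,q,k,R Threshold constants (defaults 2, 10, 0.25, 0.5).
#' @export
phansalkar_params <- function(window_radius_px = 3, p = 2.0, q = 10.0,
                              k = 0.25, R = 0.5) {
  if (window_radius_px < 1) stop("window radius must be >= 1 pixel")
  if (R <= 0) stop("R must be positive")
  structure(list(window_radius_px = window_radius_px, p = p, q = q,
                 k = k, R = R), class = "phansalkar_params")
}

#' CC slab specification
#'
#' Axial window for the choriocapillaris en-face image: a slab of
#' `thickness_um` placed `offset_below_rpe_fit_um` beneath the RPE-fit
#' (Bruch's-membrane-level) floor surface.
#'
#' @param offset_below_rpe_fit_um Offset below the RPE fit in um (default 29).
#' @param thickness_um Slab thickness in um (default 20).
#' @export
cc_slab_spec <- function(offset_below_rpe_fit_um = 29, thickness_um = 20) {
  if (offset_below_rpe_fit_um <= 0 || thickness_um <= 0)
    stop("CC slab offset and thickness must be positive")
  structure(list(offset_below_rpe_fit_um = offset_below_rpe_fit_um,
                 thickness_um = thickness_um), class = "cc_slab_spec")
}

#' Extract the CC en-face slab from a structural volume
#'
#' Per-A-scan mean over `[floor + offset, floor + offset + thickness)`.
#' This is a phantom-grade stand-in for the device's OCTA decorrelation
#' slab; when paired en-face flow/structure rasters are supplied directly
#' (the normal phantom path via [generate_cc_pair()]) this extractor is
#' bypassed.
#'
#' @param volume An [oct_volume()].
#' @param rpe_floor Floor surface from [fit_rpe_floor()].
#' @param spec A [cc_slab_spec()].
#' @return An [oct_raster()].
#' @export
extract_cc_slab <- function(volume, rpe_floor, spec = cc_slab_spec()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(rpe_floor, "oct_surface"),
            inherits(spec, "cc_slab_spec"))
  vals <- surface_band_mean(volume, rpe_floor$z_um,
                            spec$offset_below_rpe_fit_um,
                            spec$offset_below_rpe_fit_um + spec$thickness_um,
                            what = "CC slab")
  oct_raster(vals, volume$lateral_pitch_um)
}

#' Compensate CC flow for shadowing artifacts
#'
#' Divides the flow raster by a smoothed version of the corresponding
#' structural raster, rescaled to its reference (median) level:
#' `compensated = flow * S_ref / max(S_smooth, eps * S_ref)`, where
#' `S_smooth` is an isotropically (Gaussian) smoothed structure raster and
#' `S_ref` its median over the ROI. The floor fraction `eps` caps the
#' maximum amplification at `1 / eps`; output is clipped to the input's
#' dynamic range.
#'
#' @param flow,structure [oct_raster()] pair on one grid.
#' @param floor_frac Floor fraction `eps` in (0, 1] (default 0.2).
#' @param sigma_um Gaussian smoothing scale for the structure raster, um
#'   (default 15, about the lateral optical resolution: wide enough to
#'   suppress per-pixel speckle in the divisor, narrow enough to track
#'   shadow edges at drusen shoulders).
#' @param roi Optional logical mask over which the reference median is
#'   taken (default: whole image).
#' @return Compensated flow [oct_raster()].
#' @export
compensate_flow <- function(flow, structure, floor_frac = 0.2,
                            sigma_um = 15, roi = NULL) {
  stopifnot(inherits(flow, "oct_raster"), inherits(structure, "oct_raster"))
  assert_same_grid(flow, structure, "flow and structure rasters")
  if (any(structure$values < 0)) stop("structure raster must be non-negative")
  if (all(structure$values == 0)) stop("structure raster is identically zero")
  if (floor_frac <= 0 || floor_frac > 1) stop("floor_frac must be in (0, 1]")
  s_smooth <- gaussian_smooth(structure$values,
                              sigma_um / structure$pitch_um)
  s_ref <- if (is.null(roi)) stats::median(s_smooth) else
    stats::median(s_smooth[roi])
  comp <- flow$values * s_ref / pmax(s_smooth, floor_frac * s_ref)
  rng <- range(flow$values)
  comp <- pmin(pmax(comp, rng[1]), rng[2])
  oct_raster(comp, flow$pitch_um)
}

#' Exclude retinal-vessel projection artifacts from the analyzed area
#'
#' Vessel pixels are removed from the analysis mask: they count neither as
#' deficit nor as analyzed area in all downstream accounting. An empty
#' vessel mask is a no-op.
#'
#' @param analysis_mask Logical matrix of the analyzed region.
#' @param vessel_mask Logical matrix of vessel pixels (or `NULL`).
#' @return Logical analysis mask with vessels removed.
#' @export
remove_projection_artifacts <- function(analysis_mask, vessel_mask = NULL) {
  stopifnot(is.matrix(analysis_mask))
  if (is.null(vessel_mask)) return(analysis_mask)
  if (!identical(dim(vessel_mask), dim(analysis_mask)))
    stop("vessel mask not on the analysis grid")
  analysis_mask & !vessel_mask
}

#' Phansalkar local binarization into a deficit mask
#'
#' Normalizes intensities to [0, 1] (images already inside [0, 1] are used
#' as-is; otherwise min-max rescaled), then thresholds each pixel against
#' its circular-window Phansalkar threshold. Windows are truncated at the
#' image borders (statistics over in-bounds pixels only). An all-zero image
#' is validly all-deficit; a constant image outside [0, 1] cannot be
#' normalized and is rejected.
#'
#' @param image An [oct_raster()] or numeric matrix.
#' @param params A [phansalkar_params()].
#' @return Logical matrix: `TRUE` where the flow signal falls at or below
#'   the local threshold (a flow deficit). Attribute `threshold` holds the
#'   per-pixel threshold map.
#' @export
phansalkar_binarize <- function(image, params = phansalkar_params()) {
  v <- if (inherits(image, "oct_raster")) image$values else image
  stopifnot(is.matrix(v), inherits(params, "phansalkar_params"))
  rng <- range(v)
  if (rng[1] >= 0 && rng[2] <= 1) {
    x <- v
  } else if (rng[2] > rng[1]) {
    x <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    stop("constant image outside [0, 1]: normalization is degenerate")
  }
  st <- local_window_stats(x, params$window_radius_px)
  thr <- st$mean * (1 + params$p * exp(-params$q * st$mean) +
                      params$k * (st$sd / params$R - 1))
  out <- x <= thr
  attr(out, "threshold") <- thr
  out
}

#' Remove small isolated deficits
#'
#' Clears 8-connected deficit components whose equivalent diameter
#' `2 * sqrt(area / pi)` is strictly smaller than the cutoff (default
#' 24 um); all other components are untouched.
#'
#' @param deficits Logical deficit matrix.
#' @param pitch_um Lateral pitch, um/pixel.
#' @param min_equiv_diameter_um Cutoff in um (default 24).
#' @return Logical deficit matrix.
#' @export
remove_small_deficits <- function(deficits, pitch_um,
                                  min_equiv_diameter_um = 24) {
  stopifnot(is.matrix(deficits), is.logical(deficits))
  lab <- label_components(deficits)
  if (max(lab) == 0L) return(deficits)
  areas_um2 <- tabulate(lab[lab > 0L]) * pitch_um^2
  drop <- equiv_diameter_um(areas_um2) < min_equiv_diameter_um
  out <- deficits
  fg <- which(lab > 0L)
  out[fg[drop[lab[fg]]]] <- FALSE
  out
}

#' Flow-deficit metrics over an analysis region
#'
#' `fd_percent` is the share of the analyzed area flagged as deficit;
#' components are 8-connected and, when clipped by the analysis-mask
#' boundary, contribute their in-mask area only (this keeps the whole-ROI
#' value exactly the area-weighted mean of the regional values).
#'
#' @param deficits Logical deficit matrix (after small-deficit removal).
#' @param analysis_mask Logical matrix of the analyzed region (ROI,
#'   drusen-free, ..., with vessels already excluded).
#' @param pitch_um Lateral pitch, um/pixel.
#' @param region_label Label recorded with the row.
#' @return Data frame with `region_label`, `fd_percent`,
#'   `fd_mean_size_um2` (NA when no deficit), `fd_count`,
#'   `analyzed_px`.
#' @export
fd_metrics <- function(deficits, analysis_mask, pitch_um,
                       region_label = "whole-ROI") {
  stopifnot(is.matrix(deficits), is.matrix(analysis_mask))
  if (!identical(dim(deficits), dim(analysis_mask)))
    stop("deficit and analysis masks are not on the same grid")
  if (!any(analysis_mask)) stop("empty analysis mask")
  npx <- sum(analysis_mask)
  in_mask <- deficits & analysis_mask
  fd_percent <- 100 * sum(in_mask) / npx
  lab <- label_components(deficits)
  sizes <- tabulate(lab[in_mask])
  sizes <- sizes[sizes > 0L]
  data.frame(region_label = region_label,
             fd_percent = fd_percent,
             fd_mean_size_um2 = if (length(sizes)) mean(sizes) * pitch_um^2
                                else NA_real_,
             fd_count = length(sizes),
             analyzed_px = npx)
}
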