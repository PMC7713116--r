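#' EZ slab specification
#'
#' Axial window for the ellipsoid-zone en-face image: a slab of
#' `thickness_um` whose inner boundary sits `offset_above_rpe_um` above
#' (towards the vitreous from) the RPE reference surface.
#'
#' @param offset_above_rpe_um Inner-boundary offset in um (default 45).
#' @param thickness_um Slab thickness in um (default 21).
#' @export
slab_spec <- function(offset_above_rpe_um = 45, thickness_um = 21) {
  if (offset_above_rpe_um <= 0 || thickness_um <= 0)
    stop("slab offset and thickness must be positive")
  structure(list(offset_above_rpe_um = offset_above_rpe_um,
                 thickness_um = thickness_um), class = "slab_spec")
}

# Mean intensity over a surface-following axial band [surface + lo,
# surface + hi) um (lo/hi may be negative, i.e. above the surface).
# Rejects when the band exits the volume on more than max_exit_frac of
# A-scans; the rare clipped A-scans average their in-bounds voxels.
surface_band_mean <- function(volume, surface_z, lo_um, hi_um,
                              max_exit_frac = 0.01, what = "slab") {
  ap <- volume$axial_pitch_um
  d <- dim(volume$values)
  depth <- d[1]; nr <- d[2]; nc <- d[3]; npix <- nr * nc
  z <- as.vector(surface_z)
  idx <- axial_band_indices(z + lo_um, z + hi_um, ap)
  if (any(idx$hi < idx$lo)) stop(sprintf("%s has zero axial extent", what))
  exit <- idx$lo < 1L | idx$hi > depth
  if (mean(exit) > max_exit_frac)
    stop(sprintf("%s exits the volume on %.1f%% of A-scans", what,
                 100 * mean(exit)))
  mat <- matrix(volume$values, nrow = depth)
  maxlen <- max(idx$hi - idx$lo) + 1L
  acc <- numeric(npix); cnt <- numeric(npix)
  base <- (seq_len(npix) - 1L) * depth
  for (k in 0:(maxlen - 1L)) {
    i <- idx$lo + k
    ok <- (i <= idx$hi) & (i >= 1L) & (i <= depth)
    if (!any(ok)) next
    acc[ok] <- acc[ok] + mat[base[ok] + i[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  if (any(cnt == 0)) stop(sprintf("%s fully exits the volume on some A-scans", what))
  matrix(acc / cnt, nr, nc)
}

#' Extract the EZ en-face image
#'
#' Per-A-scan mean intensity over the slab
#' `[rpe_z - offset, rpe_z - offset + thickness)` following the RPE contour
#' (the window lies towards the vitreous from the RPE reference).
#'
#' @param volume An [oct_volume()].
#' @param rpe RPE reference surface ([oct_surface()]).
#' @param slab A [slab_spec()].
#' @return An [oct_raster()] EZ en-face image.
#' @export
extract_ez_enface <- function(volume, rpe, slab = slab_spec()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(rpe, "oct_surface"),
            inherits(slab, "slab_spec"))
  vals <- surface_band_mean(volume, rpe$z_um,
                            -slab$offset_above_rpe_um,
                            -slab$offset_above_rpe_um + slab$thickness_um,
                            what = "EZ slab")
  oct_raster(vals, volume$lateral_pitch_um)
}

#' Mean intensity of a reference region
#'
#' Samples the dark (vitreous) or bright (RNFL) normalization reference:
#' the arithmetic mean of volume intensities over an axial band -- scalar
#' bounds or per-A-scan surfaces -- restricted to a lateral mask.
#'
#' @param volume An [oct_volume()].
#' @param band List with `z_top`, `z_bottom` (um; scalars or matrices) and
#'   optionally `mask` (logical lateral matrix).
#' @return Mean intensity (scalar).
#' @export
sample_reference <- function(volume, band) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$values)
  nr <- d[2]; nc <- d[3]
  mask <- band$mask
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!any(mask)) stop("empty reference mask")
  zt <- band$z_top; zb <- band$z_bottom
  if (length(zt) == 1L) zt <- matrix(zt, nr, nc)
  if (length(zb) == 1L) zb <- matrix(zb, nr, nc)
  ap <- volume$axial_pitch_um
  depth <- d[1]
  idx <- axial_band_indices(as.vector(zt), as.vector(zb), ap)
  sel <- as.vector(mask)
  lo <- pmax(idx$lo, 1L); hi <- pmin(idx$hi, depth)
  if (all(hi[sel] < lo[sel])) stop("reference band outside the volume")
  mat <- matrix(volume$values, nrow = depth)
  base <- (seq_len(nr * nc) - 1L) * depth
  tot <- 0; n <- 0
  maxlen <- max(hi - lo) + 1L
  for (k in 0:(maxlen - 1L)) {
    i <- lo + k
    ok <- sel & (i <= hi)
    if (!any(ok)) next
    tot <- tot + sum(mat[base[ok] + i[ok]])
    n <- n + sum(ok)
  }
  tot / n
}

#' Normalized reflectivity from dark/bright references
#'
#' Two-point linear rescaling of the mean EZ intensity between the vitreous
#' (dark) and RNFL (bright) reference intensities:
#' `(mu_ez - mu_vitreous) / (mu_rnfl - mu_vitreous)`. The value is
#' dimensionless, may exceed [0, 1] for extreme inputs (it is not clipped),
#' and is invariant under any global affine intensity transform `a*I + b`
#' with `a > 0` -- the reason the readout is comparable across eyes.
#'
#' @param mu_ez,mu_vitreous,mu_rnfl Mean intensities.
#' @return Normalized reflectivity.
#' @export
normalize_reflectivity <- function(mu_ez, mu_vitreous, mu_rnfl) {
  if (any(mu_rnfl <= mu_vitreous))
    stop("references inverted: RNFL mean must exceed vitreous mean")
  (mu_ez - mu_vitreous) / (mu_rnfl - mu_vitreous)
}

#' Regional normalized EZ reflectivity
#'
#' Mean EZ en-face intensity over each region (whole ROI, drusen-free,
#' drusen), after excluding major retinal vessels, normalized against the
#' vitreous/RNFL references. Regions emptied by vessel exclusion are
#' reported as `NA`.
#'
#' @param enface EZ en-face [oct_raster()].
#' @param masks A `region_masks` object from [drusen_masks()].
#' @param mu_vitreous,mu_rnfl Reference intensities (see
#'   [sample_reference()]).
#' @param vessel_mask Optional logical matrix of pixels occupied by major
#'   retinal vessels (excluded from all regions).
#' @return Data frame of class `ez_result` with one row:
#'   `ez_norm_whole`, `ez_norm_drusen_free`, `ez_norm_drusen`, the raw
#'   region means, and the reference means.
#' @export
regional_reflectivity <- function(enface, masks, mu_vitreous, mu_rnfl,
                                  vessel_mask = NULL) {
  stopifnot(inherits(enface, "oct_raster"), inherits(masks, "region_masks"))
  v <- enface$values
  if (!identical(dim(v), dim(masks$roi))) stop("masks not on the en-face grid")
  if (!any(masks$roi)) stop("empty ROI")
  if (is.null(vessel_mask)) vessel_mask <- matrix(FALSE, nrow(v), ncol(v))
  region_mean <- function(m) {
    sel <- m & !vessel_mask
    if (!any(sel)) NA_real_ else mean(v[sel])
  }
  mu_whole <- region_mean(masks$roi)
  mu_df <- region_mean(masks$drusen_free)
  mu_dr <- region_mean(masks$drusen)
  norm <- function(mu) if (is.na(mu)) NA_real_ else
    normalize_reflectivity(mu, mu_vitreous, mu_rnfl)
  out <- data.frame(ez_norm_whole = norm(mu_whole),
                    ez_norm_drusen_free = norm(mu_df),
                    ez_norm_drusen = norm(mu_dr),
                    ez_raw_whole = mu_whole,
                    ez_raw_drusen_free = mu_df,
                    ez_raw_drusen = mu_dr,
                    mu_vitreous = mu_vitreous, mu_rnfl = mu_rnfl)
  class(out) <- c("ez_result", class(out))
  out
}
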