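#' Fovea-centred circular region of interest
#'
#' Builds the analysis mask used throughout: a circle of the given physical
#' diameter (default 5.0 mm) centred on the manually annotated fovea. A pixel
#' belongs to the ROI iff its centre lies within `diameter_mm / 2` of the
#' centre pixel.
#'
#' @param shape Integer vector `c(rows, cols)` of the raster grid.
#' @param pitch_um Lateral pixel pitch in um/pixel.
#' @param center_row,center_col Pixel coordinates of the fovea (row-major,
#'   origin top-left, pixel centres at integer coordinates).
#' @param diameter_mm Physical ROI diameter in mm (default 5.0).
#' @return Logical matrix of the ROI mask.
#' @export
circular_roi_mask <- function(shape, pitch_um, center_row, center_col,
                              diameter_mm = 5.0) {
  if (diameter_mm <= 0) stop("ROI diameter must be positive")
  if (pitch_um <= 0) stop("pitch must be positive")
  nr <- shape[1]; nc <- shape[2]
  radius_px <- (diameter_mm * 1000 / 2) / pitch_um
  if (center_row - radius_px < 0.5 || center_row + radius_px > nr + 0.5 ||
      center_col - radius_px < 0.5 || center_col + radius_px > nc + 0.5)
    stop("ROI circle does not fit inside the raster (mis-specified fovea?)")
  dr <- (seq_len(nr) - center_row)^2
  dc <- (seq_len(nc) - center_col)^2
  outer(dr, dc, "+") <= radius_px^2
}

#' Equivalent diameter of an area
#'
#' Diameter of the circle with the same area: `2 * sqrt(area / pi)`. Used for
#' the small flow-deficit cutoff (components with equivalent diameter below
#' 24 um are treated as noise).
#'
#' @param area_um2 Non-negative area(s) in um^2.
#' @return Equivalent diameter(s) in um.
#' @export
equiv_diameter_um <- function(area_um2) {
  if (any(area_um2 < 0)) stop("area must be non-negative")
  2 * sqrt(area_um2 / pi)
}

#' Convert an area in um^2 to a pixel count
#'
#' @param area_um2 Non-negative area(s) in um^2.
#' @param pitch_um Lateral pixel pitch in um/pixel.
#' @return Area in pixels (not rounded).
#' @export
um2_to_px <- function(area_um2, pitch_um) {
  if (any(area_um2 < 0)) stop("area must be non-negative")
  if (pitch_um <= 0) stop("pitch must be positive")
  area_um2 / pitch_um^2
}

#' Segment the RPE surface from a structural volume
#'
#' Phantom-grade stand-in for the device's multilayer segmentation. Each
#' A-scan's intensity profile is smoothed along depth with a short boxcar;
#' the brightest band is located by its argmax and the returned surface is
#' the superficial half-maximum edge of that band (the most vitreal
#' contiguous voxel whose smoothed intensity stays above half the peak), so
#' that the reported position is the inner RPE boundary rather than the band
#' centre. The surface is lightly median-filtered laterally.
#'
#' A-scans with no intensity variation are flagged and filled with the median
#' of the valid surface; if more than `max_flagged_frac` of A-scans are
#' flagged the segmentation is rejected.
#'
#' @param volume An [oct_volume()].
#' @param smooth_um Axial boxcar smoothing length in um (default 20,
#'   spanning most of the RPE band).
#' @param lateral_box_px Radius of the lateral box average applied to the
#'   depth profiles before the peak search (default 1, i.e. 3 x 3
#'   A-scans); suppresses speckle outliers that would otherwise pull the
#'   argmax into brighter inner layers.
#' @param top_search_um How far above the argmax to search for the half-max
#'   edge, in um (default 20).
#' @param max_flagged_frac Maximum tolerated fraction of flat A-scans.
#' @return An [oct_surface()] of the inner RPE boundary.
#' @export
segment_rpe <- function(volume, smooth_um = 20, lateral_box_px = 1,
                        top_search_um = 20, max_flagged_frac = 0.05) {
  stopifnot(inherits(volume, "oct_volume"))
  ap <- volume$axial_pitch_um
  d <- dim(volume$values)
  depth <- d[1]; nr <- d[2]; nc <- d[3]; npix <- nr * nc
  mat <- matrix(volume$values, nrow = depth)  # depth x npix, column-major

  # centred boxcar along depth via per-column cumulative sums; the k/2
  # edge rows keep their raw values
  axial_boxcar <- function(m, k) {
    if (k %% 2 == 0) k <- k + 1L
    if (k <= 1L || depth <= k) return(m)
    cs <- matrix(cumsum(m), nrow = depth)
    if (npix > 1L) {
      carry <- cs[depth, 1:(npix - 1L)]
      cs <- cs - rep(c(0, carry), each = depth)
    }
    h <- (k - 1L) %/% 2L
    out <- m
    hi <- cs[(1L + 2L * h):depth, , drop = FALSE]
    lo <- rbind(rep(0, npix), cs[seq_len(depth - 2L * h - 1L), , drop = FALSE])
    out[(h + 1L):(depth - h), ] <- (hi - lo) / k
    out
  }
  ws <- mat
  if (lateral_box_px >= 1) {
    # separable (2b+1)^2 lateral box average of the depth profiles, done
    # with contiguous column shifts of the depth x npix matrix; borders use
    # truncated windows
    b <- as.integer(lateral_box_px)
    lat_row <- rep(seq_len(nr), times = nc)   # lateral row of matrix col p
    acc <- ws
    for (s in seq_len(b)) {                   # lateral-column pass
      sh <- s * nr
      if (sh >= npix) break
      acc[, (sh + 1):npix] <- acc[, (sh + 1):npix] + ws[, 1:(npix - sh)]
      acc[, 1:(npix - sh)] <- acc[, 1:(npix - sh)] + ws[, (sh + 1):npix]
    }
    acc2 <- acc
    for (s in seq_len(b)) {                   # lateral-row pass
      if (s >= nr) break
      right <- cbind(matrix(0, depth, s), acc[, 1:(npix - s), drop = FALSE])
      right[, lat_row <= s] <- 0
      left <- cbind(acc[, (s + 1):npix, drop = FALSE], matrix(0, depth, s))
      left[, lat_row > nr - s] <- 0
      acc2 <- acc2 + right + left
    }
    cnt_row <- pmin(seq_len(nr) + b, nr) - pmax(seq_len(nr) - b, 1L) + 1L
    cnt_col <- pmin(seq_len(nc) + b, nc) - pmax(seq_len(nc) - b, 1L) + 1L
    cnt_pix <- cnt_row[lat_row] * cnt_col[rep(seq_len(nc), each = nr)]
    ws <- acc2 * rep(1 / cnt_pix, each = depth)
  }

  # two smoothing scales: the band is *located* on a heavily smoothed
  # profile (robust against speckle pulling the argmax into the EZ band),
  # but its superficial edge is *placed* on a lightly smoothed profile so
  # the reported boundary is not biased upwards by the smoothing kernel
  ws_heavy <- axial_boxcar(ws, max(1L, round(smooth_um / ap)))
  ws_light <- axial_boxcar(ws, max(1L, round(10 / ap)))

  wt_h <- t(ws_heavy)  # npix x depth
  i0 <- max.col(wt_h, ties.method = "first")
  pix <- seq_len(npix)
  wpk_h <- wt_h[cbind(pix, i0)]
  wmin_h <- wt_h[cbind(pix, max.col(-wt_h, ties.method = "first"))]
  flagged <- (wpk_h - wmin_h) <= 0
  frac <- mean(flagged)
  if (frac > max_flagged_frac)
    stop(sprintf("segment_rpe: %.1f%% of A-scans have no intensity variation",
                 100 * frac))

  wt <- t(ws_light)
  wpk <- wt[cbind(pix, i0)]
  # the edge level is the midpoint between the band peak and the local
  # baseline just above the band (the hyporeflective gap between EZ and
  # RPE); a profile-derived baseline keeps the edge position invariant
  # under global affine intensity transforms, and the peak-to-gap midpoint
  # gives the largest decision margin against speckle
  base_idx <- pmax(1L, i0 - as.integer(ceiling(24 / ap)))
  vbase <- wt[cbind(pix, base_idx)]
  half <- 0.5 * (pmin(vbase, wpk) + wpk)
  K <- max(1L, as.integer(ceiling(top_search_um / ap)))
  top <- i0
  alive <- rep(TRUE, npix)
  for (s in seq_len(K)) {
    cand <- i0 - s
    ok <- alive & cand >= 1L
    v <- wt[cbind(pix, pmax(cand, 1L))]
    ok <- ok & v >= half
    top[ok] <- cand[ok]
    alive <- ok
  }
  z <- (top - 0.5) * ap
  zm <- matrix(z, nr, nc)
  if (any(flagged)) zm[matrix(flagged, nr, nc)] <- stats::median(z[!flagged])

  # replace residual speckle outliers (clusters of A-scans whose surface
  # deviates from a wide separable median by more than 1.5 voxels), then
  # apply a light lateral median filter
  med_ref <- function(m, k) {
    if (nrow(m) >= k) m <- apply(m, 2, function(v) stats::runmed(v, k))
    if (ncol(m) >= k) m <- t(apply(m, 1, function(v) stats::runmed(v, k)))
    m
  }
  for (pass in 1:6) {
    ref <- med_ref(zm, 9L)
    bad <- abs(zm - ref) > 1.5 * ap
    if (!any(bad)) break
    zm[bad] <- ref[bad]
  }
  if (nr >= 3L) zm <- apply(zm, 2, function(v) stats::runmed(v, 3))
  if (nc >= 3L) zm <- t(apply(zm, 1, function(v) stats::runmed(v, 3)))
  out <- oct_surface(zm)
  attr(out, "flagged_frac") <- frac
  out
}

#' Pathology-excluding floor fit of the RPE surface
#'
#' Fits a smooth low-order polynomial surface to the RPE, iteratively
#' discarding A-scans where the RPE lies *above* the current fit (towards the
#' vitreous) by more than `tol_um` -- those upward outliers are drusen -- and
#' refitting until the retained set is stable. The result approximates the
#' Bruch's-membrane-level "RPE fit" floor against which elevation is measured.
#'
#' @param rpe An [oct_surface()] from [segment_rpe()].
#' @param degree Total polynomial degree of the fitted surface (default 2).
#' @param tol_um Upward-elevation tolerance in um for outlier exclusion
#'   (default 10).
#' @param max_iter Maximum fit/exclude iterations (default 10).
#' @param min_retained_frac Declare the fit unreliable if fewer than this
#'   fraction of A-scans are retained (default 0.4).
#' @return An [oct_surface()] of the fitted floor; attribute `retained` holds
#'   the logical matrix of A-scans used in the final fit.
#' @export
fit_rpe_floor <- function(rpe, degree = 2, tol_um = 10, max_iter = 10,
                          min_retained_frac = 0.4) {
  stopifnot(inherits(rpe, "oct_surface"))
  z <- as.vector(rpe$z_um)
  nr <- nrow(rpe$z_um); nc <- ncol(rpe$z_um)
  x <- rep((seq_len(nc) - (nc + 1) / 2) / max(1, (nc - 1) / 2), each = nr)
  y <- rep((seq_len(nr) - (nr + 1) / 2) / max(1, (nr - 1) / 2), times = nc)
  terms <- list()
  for (i in 0:degree) for (j in 0:(degree - i))
    terms[[length(terms) + 1L]] <- x^i * y^j
  X <- do.call(cbind, terms)

  keep <- rep(TRUE, length(z))
  pred <- NULL
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(X[keep, , drop = FALSE], z[keep])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- as.vector(X %*% beta)
    newkeep <- (pred - z) <= tol_um  # RPE above floor by > tol => drusen
    if (mean(newkeep) < min_retained_frac)
      stop("fit_rpe_floor: unreliable fit (pathology over most of the surface)")
    if (identical(newkeep, keep)) break
    keep <- newkeep
  }
  out <- oct_surface(matrix(pmax(pred, 0), nr, nc))
  attr(out, "retained") <- matrix(keep, nr, nc)
  out
}
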