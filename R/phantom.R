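#' Phantom configuration
#'
#' Assembles and validates the configuration of the synthetic OCT/OCTA
#' phantom. Defaults emulate the acquisition geometry the pipeline targets: a
#' 6 x 6 mm macular field sampled on a 500 x 500 lateral grid (12 um/pixel),
#' with a layered retina (vitreous, RNFL, inner layers, EZ band, an
#' interdigitation gap, RPE, choroid) draped over a smooth quadratic
#' Bruch's-membrane floor. Drusen are flat-topped mounds with raised-cosine
#' shoulders that elevate the RPE and shadow deeper signal.
#'
#' @param grid_rows,grid_cols Lateral grid size in pixels.
#' @param lateral_pitch_um Lateral pitch, um/pixel (default 12 = 6000/500).
#' @param depth_voxels Axial samples per A-scan.
#' @param axial_pitch_um Axial pitch, um/voxel.
#' @param layers Named list of layer mean reflectivities (arbitrary intensity
#'   units) and thicknesses (um): `vitreous`, `rnfl = c(mean, thickness)`,
#'   `inner = c(mean, thickness)`, `ez_mean`, `os_mean`,
#'   `rpe = c(mean, thickness)`, `choroid`.
#' @param ez_offset_um,ez_thickness_um Position of the EZ band above the
#'   inner RPE boundary (defaults 45 and 21 um, matching the en-face slab).
#' @param bm_center_um,bm_tilt_um,bm_bow_um Quadratic Bruch's-membrane floor:
#'   nominal depth, linear tilt amplitudes `c(row, col)` and bow amplitude,
#'   all um.
#' @param drusen_spec `NULL`, or a data frame with columns `center_row`,
#'   `center_col` (pixels), `radius_um`, `peak_um` (peak height, <= 150 um).
#' @param drusen_plateau_frac Fraction of each dome radius occupied by the
#'   flat top (default 0.9); the shoulder is a raised cosine.
#' @param ez_attenuation Multiplicative EZ attenuation in (0, 1]: scalar or
#'   `grid_rows x grid_cols` matrix.
#' @param shadow_factor Multiplicative attenuation of sub-RPE signal under
#'   drusen, in (0, 1].
#' @param speckle_shape Gamma shape of the multiplicative volume speckle
#'   (mean 1); `Inf` disables noise.
#' @param fd_fraction Target flow-deficit area fraction in [0, 1).
#' @param fd_blob_scale_um Characteristic deficit diameter in um (>= 24).
#' @param cc_flow_level,cc_structure_level Background levels of the CC
#'   en-face flow and structure rasters on the [0, 1] intensity scale.
#' @param cc_deficit_frac Residual flow level inside deficits, as a fraction
#'   of the background level.
#' @param cc_speckle_shape Gamma shape of the multiplicative noise on the CC
#'   en-face rasters; `Inf` disables it.
#' @param seed Integer seed; identical (config, seed) gives bit-identical
#'   phantoms.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_rows = 500, grid_cols = 500,
                           lateral_pitch_um = 12,
                           depth_voxels = 160, axial_pitch_um = 4,
                           layers = list(vitreous = 4,
                                         rnfl = c(110, 40),
                                         inner = c(55, 140),
                                         ez_mean = 130,
                                         os_mean = 35,
                                         rpe = c(150, 25),
                                         choroid = 60),
                           ez_offset_um = 45, ez_thickness_um = 21,
                           bm_center_um = 440, bm_tilt_um = c(15, 8),
                           bm_bow_um = 10,
                           drusen_spec = NULL, drusen_plateau_frac = 0.9,
                           ez_attenuation = 1, shadow_factor = 0.6,
                           speckle_shape = 4,
                           fd_fraction = 0.2, fd_blob_scale_um = 40,
                           cc_flow_level = 0.6, cc_structure_level = 0.65,
                           cc_deficit_frac = 0.05, cc_speckle_shape = 50,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (grid_rows < 8 || grid_cols < 8) stop("grid too small")
    if (lateral_pitch_um <= 0 || axial_pitch_um <= 0)
      stop("pitches must be positive")
    if (ez_offset_um <= 0 || ez_thickness_um <= 0)
      stop("EZ band offsets must be positive")
    if (!is.null(drusen_spec)) {
      if (any(drusen_spec$peak_um < 0)) stop("drusen peak heights must be >= 0")
      if (any(drusen_spec$peak_um > 150)) stop("drusen peak heights must be <= 150 um")
      if (any(drusen_spec$radius_um <= 0)) stop("drusen radii must be positive")
    }
    if (fd_fraction < 0 || fd_fraction >= 1)
      stop("fd_fraction must lie in [0, 1)")
    if (fd_blob_scale_um < 24)
      stop("fd_blob_scale_um must be >= 24 (the small-deficit cutoff)")
    if (shadow_factor <= 0 || shadow_factor > 1)
      stop("shadow_factor must lie in (0, 1]")
    if (any(ez_attenuation <= 0) || any(ez_attenuation > 1))
      stop("ez_attenuation must lie in (0, 1]")
    if (speckle_shape <= 0 || cc_speckle_shape <= 0)
      stop("speckle shapes must be positive (Inf disables noise)")
    depth_extent <- depth_voxels * axial_pitch_um
    stack_um <- layers$rnfl[2] + layers$inner[2] + ez_offset_um +
      layers$rpe[2]
    peak_max <- if (is.null(drusen_spec)) 0 else max(drusen_spec$peak_um, 0)
    top_margin <- bm_center_um - sum(abs(bm_tilt_um)) - abs(bm_bow_um) -
      layers$rpe[2] - peak_max - ez_offset_um - layers$inner[2] - layers$rnfl[2]
    if (stack_um > depth_extent || top_margin < 4 * axial_pitch_um)
      stop("layer stack exceeds the volume depth (retina pushed out of frame)")
    if (bm_center_um + sum(abs(bm_tilt_um)) + abs(bm_bow_um) + 50 > depth_extent)
      stop("layer stack exceeds the volume depth (no room below Bruch's membrane)")
  })
  invisible(cfg)
}

# Quadratic Bruch's-membrane floor depth map (um).
bm_floor_field <- function(cfg) {
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  yn <- (seq_len(nr) - (nr + 1) / 2) / ((nr - 1) / 2)
  xn <- (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2)
  cfg$bm_center_um +
    outer(yn * cfg$bm_tilt_um[1], rep(1, nc)) +
    outer(rep(1, nr), xn * cfg$bm_tilt_um[2]) +
    cfg$bm_bow_um * (outer(yn^2, rep(1, nc)) + outer(rep(1, nr), xn^2) - 1)
}

#' Drusen elevation field
#'
#' Renders the planted drusen as an elevation map (um): each druse is a
#' flat-topped mound -- constant at its peak height inside
#' `plateau_frac * radius`, falling to zero along a raised-cosine shoulder.
#' Overlapping domes combine by pointwise maximum, so the analytic peak
#' height of every druse is preserved exactly.
#'
#' @param drusen_spec Data frame (`center_row`, `center_col`, `radius_um`,
#'   `peak_um`) or `NULL` for a drusen-free field.
#' @param shape `c(rows, cols)` of the lateral grid.
#' @param pitch_um Lateral pitch, um/pixel.
#' @param plateau_frac Flat-top fraction of the radius.
#' @return Numeric elevation matrix in um (>= 0).
#' @export
dome_field <- function(drusen_spec, shape, pitch_um, plateau_frac = 0.9) {
  elev <- matrix(0, shape[1], shape[2])
  if (is.null(drusen_spec) || nrow(drusen_spec) == 0L) return(elev)
  for (i in seq_len(nrow(drusen_spec))) {
    cr <- drusen_spec$center_row[i]; cc <- drusen_spec$center_col[i]
    R <- drusen_spec$radius_um[i] / pitch_um
    p <- drusen_spec$peak_um[i]
    rows <- max(1, floor(cr - R)):min(shape[1], ceiling(cr + R))
    cols <- max(1, floor(cc - R)):min(shape[2], ceiling(cc + R))
    r <- sqrt(outer((rows - cr)^2, (cols - cc)^2, "+")) / R
    h <- matrix(0, length(rows), length(cols))
    h[r <= plateau_frac] <- p
    sh <- r > plateau_frac & r < 1
    h[sh] <- p * 0.5 * (1 + cos(pi * (r[sh] - plateau_frac) / (1 - plateau_frac)))
    elev[rows, cols] <- pmax(elev[rows, cols], h)
  }
  elev
}

#' Generate a synthetic structural OCT volume with ground truth
#'
#' Builds the layered volume on the configured Bruch's-membrane floor:
#' the RPE band rests on the floor and is lifted by the planted drusen; the
#' EZ band tracks the RPE at the configured offset with its local mean equal
#' to the layer mean times the attenuation field; signal below the RPE is
#' attenuated by `shadow_factor` under drusen; multiplicative gamma speckle
#' (mean 1) is applied voxel-wise. Identical (config, seed) yields
#' bit-identical output. Layer membership and the slab extractors share one
#' axial quantization rule, so noiseless construction checks are exact.
#'
#' @param config A [phantom_config()].
#' @return List with `volume` (an [oct_volume()]) and `truth`, which carries
#'   `true_elevation`, `true_drusen_mask`, `true_rpe_surface` (inner RPE
#'   boundary), `true_bm_surface`, `true_ez_attenuation`, and
#'   `reference_bands` (`vitreous`, `rnfl`) for reflectivity normalization.
#' @export
generate_volume <- function(config) {
  cfg <- validate_phantom_config(config)
  nr <- cfg$grid_rows; nc <- cfg$grid_cols; npix <- nr * nc
  depth <- cfg$depth_voxels; ap <- cfg$axial_pitch_um
  L <- cfg$layers

  bm <- bm_floor_field(cfg)
  elev <- dome_field(cfg$drusen_spec, c(nr, nc), cfg$lateral_pitch_um,
                     cfg$drusen_plateau_frac)
  rpe_top <- bm - L$rpe[2] - elev           # inner RPE boundary (um)
  # snap the RPE reference to voxel centres so that every layer boundary
  # derived from it falls on the same axial quantization grid the slab
  # extractors use; the phantom is intrinsically voxelized, and this keeps
  # surface-relative slabs exactly aligned with the planted bands
  rpe_top <- (ceiling(rpe_top / ap + 0.5) - 0.5) * ap
  z_rpe_bot <- rpe_top + L$rpe[2]
  z_ez_top <- rpe_top - cfg$ez_offset_um
  z_ez_bot <- z_ez_top + cfg$ez_thickness_um
  z_inner_top <- z_ez_top - L$inner[2]
  z_rnfl_top <- z_inner_top - L$rnfl[2]

  # layer membership by voxel centre (first voxel with centre >= boundary);
  # the volume is built as per-column intensity steps + one cumulative sum
  first_vox <- function(zb)
    pmin(pmax(ceiling(as.vector(zb) / ap + 0.5), 1L), depth)
  i_rnfl <- first_vox(z_rnfl_top); i_inner <- first_vox(z_inner_top)
  i_ezt <- first_vox(z_ez_top);    i_ezb <- first_vox(z_ez_bot)
  i_rpe <- first_vox(rpe_top);     i_chor <- first_vox(z_rpe_bot)
  ints <- c(L$vitreous, L$rnfl[1], L$inner[1], L$ez_mean, L$os_mean,
            L$rpe[1], L$choroid)
  dm <- matrix(0, depth, npix)
  base <- (seq_len(npix) - 1L) * depth
  dm[(base + 1L)] <- ints[1]
  if (npix > 1L) dm[base[-1L] + 1L] <- dm[base[-1L] + 1L] - ints[7]
  steps <- diff(ints)
  idxs <- list(i_rnfl, i_inner, i_ezt, i_ezb, i_rpe, i_chor)
  for (k in 1:6) {
    at <- base + idxs[[k]]
    dm[at] <- dm[at] + steps[k]
  }
  vol <- matrix(cumsum(dm), depth, npix)

  att <- cfg$ez_attenuation
  if (length(att) == 1L) att <- matrix(att, nr, nc)
  if (any(att != 1) && max(i_ezb - i_ezt) >= 1L) {
    av <- as.vector(att)
    for (k in 0:(max(i_ezb - i_ezt) - 1L)) {
      sel <- which(i_ezt + k < i_ezb)
      at <- base[sel] + i_ezt[sel] + k
      vol[at] <- vol[at] * av[sel]
    }
  }
  shadowed <- which(as.vector(elev) > 0)
  if (cfg$shadow_factor < 1 && length(shadowed)) {
    for (k in 0:(depth - min(i_chor[shadowed]))) {
      sel <- shadowed[i_chor[shadowed] + k <= depth]
      if (!length(sel)) break
      at <- base[sel] + i_chor[sel] + k
      vol[at] <- vol[at] * cfg$shadow_factor
    }
  }
  if (is.finite(cfg$speckle_shape)) {
    set.seed(derive_seed(cfg$seed, 1L))
    vol <- vol * stats::rgamma(length(vol), shape = cfg$speckle_shape,
                               rate = cfg$speckle_shape)
  }

  vit_bottom <- max(3 * ap, min(z_rnfl_top) - 6)
  truth <- list(
    true_elevation = oct_raster(elev, cfg$lateral_pitch_um),
    true_drusen_mask = elev > 0,
    true_rpe_surface = oct_surface(rpe_top),
    true_bm_surface = oct_surface(bm),
    true_ez_attenuation = att,
    reference_bands = list(
      vitreous = list(z_top = 0, z_bottom = vit_bottom,
                      mask = matrix(TRUE, nr, nc)),
      rnfl = list(z_top = z_rnfl_top + 2,
                  z_bottom = z_rnfl_top + L$rnfl[2] - 2,
                  mask = matrix(TRUE, nr, nc))))
  list(volume = oct_volume(array(vol, c(depth, nr, nc)), ap,
                           cfg$lateral_pitch_um),
       truth = truth)
}

#' Generate a paired CC en-face flow/structure raster with planted deficits
#'
#' The flow raster is a bright speckled background into which dark
#' elliptical flow-deficit blobs are planted until they cover the target
#' area fraction; blobs lie wholly inside the grid and the *achieved*
#' fraction is recorded in the truth (the oracle for recovery tests). The
#' structure raster carries the same drusen shadow field but no deficits;
#' both rasters are attenuated by `shadow_factor` under the planted drusen
#' footprint, making structural compensation exactly recoverable.
#'
#' @param config A [phantom_config()].
#' @return List with `flow`, `structure` (both [oct_raster()] on the [0, 1]
#'   scale) and `truth` (`true_fd_mask`, `true_fd_fraction`,
#'   `true_drusen_mask`).
#' @export
generate_cc_pair <- function(config) {
  cfg <- validate_phantom_config(config)
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  set.seed(derive_seed(cfg$seed, 2L))

  mask <- matrix(FALSE, nr, nc)
  target <- round(cfg$fd_fraction * nr * nc)
  painted <- 0L
  iter <- 0L
  while (painted < target) {
    iter <- iter + 1L
    if (iter > 2e5) stop("generate_cc_pair: failed to reach target fraction")
    diam_px <- stats::runif(1, 1, 1.6) * cfg$fd_blob_scale_um / cfg$lateral_pitch_um
    aspect <- stats::runif(1, 0.75, 1.33)
    a <- max(0.5, diam_px / 2 * sqrt(aspect))   # row semi-axis, px
    b <- max(0.5, diam_px / 2 / sqrt(aspect))
    ia <- ceiling(a); ib <- ceiling(b)
    if (2 * ia + 2 >= nr || 2 * ib + 2 >= nc) next
    cr <- sample((ia + 1L):(nr - ia), 1L)
    cc <- sample((ib + 1L):(nc - ib), 1L)
    rows <- (cr - ia):(cr + ia); cols <- (cc - ib):(cc + ib)
    hit <- outer(((rows - cr) / a)^2, ((cols - cc) / b)^2, "+") <= 1
    new <- hit & !mask[rows, cols]
    mask[rows, cols] <- mask[rows, cols] | hit
    painted <- painted + sum(new)
  }

  n <- nr * nc
  gam <- function() {
    if (is.finite(cfg$cc_speckle_shape))
      matrix(stats::rgamma(n, cfg$cc_speckle_shape, rate = cfg$cc_speckle_shape),
             nr, nc)
    else matrix(1, nr, nc)
  }
  flow <- cfg$cc_flow_level * ifelse(mask, cfg$cc_deficit_frac, 1) * gam()
  structure <- cfg$cc_structure_level * gam()

  drusen <- dome_field(cfg$drusen_spec, c(nr, nc), cfg$lateral_pitch_um,
                       cfg$drusen_plateau_frac) > 0
  if (cfg$shadow_factor < 1 && any(drusen)) {
    flow[drusen] <- flow[drusen] * cfg$shadow_factor
    structure[drusen] <- structure[drusen] * cfg$shadow_factor
  }
  flow <- pmin(flow, 1)
  structure <- pmin(structure, 1)

  truth <- list(true_fd_mask = mask,
                true_fd_fraction = mean(mask),
                true_drusen_mask = drusen)
  list(flow = oct_raster(flow, cfg$lateral_pitch_um),
       structure = oct_raster(structure, cfg$lateral_pitch_um),
       truth = truth)
}

#' Random drusen layout inside the analysis circle
#'
#' @param n Number of drusen.
#' @param shape `c(rows, cols)` grid size in pixels.
#' @param pitch_um Lateral pitch, um/pixel.
#' @param roi_diameter_mm ROI diameter the drusen must fall inside.
#' @param radius_range_um,peak_range_um Uniform sampling ranges.
#' @return Data frame usable as `drusen_spec` in [phantom_config()].
#' @export
random_drusen_spec <- function(n, shape, pitch_um, roi_diameter_mm = 5,
                               radius_range_um = c(150, 350),
                               peak_range_um = c(30, 100)) {
  cr0 <- (shape[1] + 1) / 2; cc0 <- (shape[2] + 1) / 2
  radius_um <- stats::runif(n, radius_range_um[1], radius_range_um[2])
  peak_um <- stats::runif(n, peak_range_um[1], peak_range_um[2])
  rmax_px <- roi_diameter_mm * 1000 / 2 / pitch_um - radius_um / pitch_um - 2
  rmax_px <- pmax(rmax_px, 1)
  theta <- stats::runif(n, 0, 2 * pi)
  rad <- sqrt(stats::runif(n)) * rmax_px
  data.frame(center_row = cr0 + rad * sin(theta),
             center_col = cc0 + rad * cos(theta),
             radius_um = radius_um, peak_um = peak_um)
}

#' Generate a two-group phantom cohort specification
#'
#' Emits per-eye phantom configurations for an affected ("AMD") group and a
#' control group. Each eye draws a target normalized EZ reflectivity and a
#' flow-deficit fraction from group-specific normal distributions; within a
#' group the two draws are rank-coupled through a Gaussian copula calibrated
#' to the requested Spearman rho (`r_pearson = 2 sin(pi * rho / 6)`). The EZ
#' target is planted by converting it to the EZ attenuation factor that the
#' dual-reference normalization will recover. Affected eyes additionally
#' receive random drusen and an extra attenuation factor under the drusen
#' footprint.
#'
#' @param n_per_group Eyes per group (>= 2).
#' @param amd_effects,control_effects Lists with `ez_mean`, `ez_sd`,
#'   `fd_mean_pct`, `fd_sd_pct`, `rho`, `drusen` (logical), and optionally
#'   `drusen_ez_factor`. Defaults are the study conditions the generator
#'   emulates.
#' @param seed Integer cohort seed.
#' @param grid List overriding the per-eye phantom size and CC noise
#'   (`rows`, `cols`, `depth`, `axial_um`, `fd_blob_scale_um`,
#'   `cc_speckle_shape`); the default 96 x 96 x 90 keeps a full cohort
#'   tractable on one CPU. At this coarser pitch a single pixel already
#'   exceeds the 24-um speck cutoff, so the CC noise shape is raised to keep
#'   the false-deficit floor comparable to the native 500 x 500 geometry
#'   where the cutoff removes speckle specks.
#' @return Object of class `phantom_cohort`: list of per-eye specs, each with
#'   `eye_id`, `group`, `config`, and `planted` (`ez_target`, `fd_target`).
#' @export
generate_cohort <- function(n_per_group,
                            amd_effects = list(ez_mean = 0.76, ez_sd = 0.10,
                                               fd_mean_pct = 24.1,
                                               fd_sd_pct = 5.3,
                                               rho = -0.4, drusen = TRUE),
                            control_effects = list(ez_mean = 0.85,
                                                   ez_sd = 0.08,
                                                   fd_mean_pct = 19.2,
                                                   fd_sd_pct = 6.2,
                                                   rho = 0, drusen = FALSE),
                            seed = 1L,
                            grid = list(rows = 96, cols = 96, depth = 90,
                                        axial_um = 5,
                                        fd_blob_scale_um = 130,
                                        cc_speckle_shape = 150)) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  for (ef in list(amd_effects, control_effects)) {
    if (ef$ez_sd < 0 || ef$fd_sd_pct < 0) stop("degenerate SDs < 0")
  }
  pitch <- 6000 / grid$rows
  lay <- list(vitreous = 4, rnfl = c(110, 40), inner = c(55, 140),
              ez_mean = 130, os_mean = 35, rpe = c(150, 25), choroid = 60)
  eyes <- list()
  for (g in 1:2) {
    ef <- if (g == 1) amd_effects else control_effects
    r_pearson <- 2 * sin(pi * ef$rho / 6)
    for (i in seq_len(n_per_group)) {
      eseed <- derive_seed(seed, g * 100000L + i)
      set.seed(eseed)
      z1 <- stats::rnorm(1)
      z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * stats::rnorm(1)
      ez_target <- ef$ez_mean + ef$ez_sd * z1
      fd_target <- min(0.6, max(0.02, (ef$fd_mean_pct + ef$fd_sd_pct * z2) / 100))
      a <- (ez_target * (lay$rnfl[1] - lay$vitreous) + lay$vitreous) / lay$ez_mean
      a <- min(1, max(0.05, a))
      drusen_spec <- NULL
      att <- a
      if (isTRUE(ef$drusen)) {
        ndr <- sample(3:8, 1)
        drusen_spec <- random_drusen_spec(ndr, c(grid$rows, grid$cols), pitch,
                                          radius_range_um = c(150, 300),
                                          peak_range_um = c(30, 75))
        dfac <- if (is.null(ef$drusen_ez_factor)) 0.93 else ef$drusen_ez_factor
        foot <- dome_field(drusen_spec, c(grid$rows, grid$cols), pitch) > 0
        att <- a * ifelse(foot, dfac, 1)
      }
      cfg <- phantom_config(
        grid_rows = grid$rows, grid_cols = grid$cols,
        lateral_pitch_um = pitch,
        depth_voxels = grid$depth, axial_pitch_um = grid$axial_um,
        layers = lay, bm_center_um = 370, bm_tilt_um = c(10, 5),
        bm_bow_um = 6,
        drusen_spec = drusen_spec, ez_attenuation = att,
        fd_fraction = fd_target,
        fd_blob_scale_um = grid$fd_blob_scale_um,
        cc_speckle_shape = if (is.null(grid$cc_speckle_shape)) 50 else
          grid$cc_speckle_shape,
        seed = eseed)
      eyes[[length(eyes) + 1L]] <-
        list(eye_id = sprintf("%s_%02d", if (g == 1) "amd" else "ctl", i),
             group = if (g == 1) "AMD" else "control",
             config = cfg,
             planted = list(ez_target = ez_target, fd_target = fd_target,
                            attenuation = a))
    }
  }
  structure(list(eyes = eyes, seed = seed,
                 amd_effects = amd_effects,
                 control_effects = control_effects),
            class = "phantom_cohort")
}
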