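test_that("slab specifications reject non-positive extents", {
  expect_error(slab_spec(thickness_um = 0), "positive")
  expect_error(slab_spec(offset_above_rpe_um = -5), "positive")
})

test_that("noiseless EZ en-face equals the planted band mean", {
  gen <- generate_volume(tiny_noiseless_config())
  enface <- extract_ez_enface(gen$volume, gen$truth$true_rpe_surface)
  expect_lt(max(abs(enface$values - 130)), 130 * 1e-6)
})

test_that("EZ en-face tracks a planted attenuation field", {
  att <- matrix(1, 96, 96); att[, 1:48] <- 0.5
  ratios <- vapply(1:3, function(seed) {
    gen <- generate_volume(small_speckled_config(ez_attenuation = att,
                                                 seed = seed))
    enface <- extract_ez_enface(gen$volume, gen$truth$true_rpe_surface)
    mean(enface$values[, 1:40]) / mean(enface$values[, 57:96])
  }, numeric(1))
  expect_true(all(ratios > 0.45 & ratios < 0.55))
})

test_that("the slab must stay inside the volume", {
  gen <- generate_volume(tiny_noiseless_config())
  deep <- oct_surface(gen$truth$true_rpe_surface$z_um * 0 + 30)
  expect_error(extract_ez_enface(gen$volume, deep), "exits the volume")
})

test_that("reference sampling averages the requested band", {
  vol <- oct_volume(array(rep(1:50, 36), c(50, 6, 6)), 4, 12)
  # band [8, 20) um covers voxels 3..5 (centres 10, 14, 18)
  expect_equal(sample_reference(vol, list(z_top = 8, z_bottom = 20)), 4)
  one <- sample_reference(vol, list(z_top = 8, z_bottom = 12))
  expect_equal(one, 3)
  msk <- matrix(FALSE, 6, 6)
  expect_error(sample_reference(vol, list(z_top = 8, z_bottom = 20,
                                          mask = msk)), "empty")
})

test_that("phantom vitreous reference is darker than the RNFL reference", {
  gen <- generate_volume(small_speckled_config(seed = 4))
  mu_v <- sample_reference(gen$volume, gen$truth$reference_bands$vitreous)
  mu_r <- sample_reference(gen$volume, gen$truth$reference_bands$rnfl)
  expect_lt(mu_v, mu_r)
})

test_that("normalized reflectivity is the two-point linear rescaling", {
  expect_equal(normalize_reflectivity(10, 10, 110), 0)
  expect_equal(normalize_reflectivity(110, 10, 110), 1)
  expect_equal(normalize_reflectivity(86, 10, 110), 0.76)
  expect_error(normalize_reflectivity(50, 100, 90), "inverted")
})

test_that("regional reflectivity handles uniform images and vessel masks", {
  roi <- circular_roi_mask(c(60, 60), 100, 30.5, 30.5, 5)
  masks <- structure(list(roi = roi, drusen = matrix(FALSE, 60, 60),
                          drusen_free = roi, threshold = NA),
                     class = "region_masks")
  enface <- oct_raster(matrix(110, 60, 60), 100)
  r <- regional_reflectivity(enface, masks, 10, 110)
  expect_equal(r$ez_norm_whole, 1)
  expect_equal(r$ez_norm_drusen_free, 1)
  expect_true(is.na(r$ez_norm_drusen))  # empty drusen region
  allvessel <- matrix(TRUE, 60, 60)
  r2 <- regional_reflectivity(enface, masks, 10, 110, vessel_mask = allvessel)
  expect_true(is.na(r2$ez_norm_whole))
})

test_that("whole-ROI mean is the area-weighted mean of the region means", {
  set.seed(9)
  roi <- circular_roi_mask(c(60, 60), 100, 30.5, 30.5, 5)
  drusen <- roi & matrix(runif(3600) < 0.3, 60, 60)
  masks <- structure(list(roi = roi, drusen = drusen,
                          drusen_free = roi & !drusen, threshold = NA),
                     class = "region_masks")
  enface <- oct_raster(matrix(runif(3600, 20, 120), 60, 60), 100)
  r <- regional_reflectivity(enface, masks, 10, 110)
  w_dr <- sum(masks$drusen) / sum(roi)
  agg <- w_dr * r$ez_raw_drusen + (1 - w_dr) * r$ez_raw_drusen_free
  expect_equal(r$ez_raw_whole, agg, tolerance = 1e-12)
})

test_that("normalized reflectivity is invariant under affine intensity maps", {
  gen <- generate_volume(small_speckled_config(drusen_spec = two_domes(),
                                               seed = 6))
  measure <- function(vol) {
    rpe <- segment_rpe(vol)
    enface <- extract_ez_enface(vol, rpe)
    mu_v <- sample_reference(vol, gen$truth$reference_bands$vitreous)
    mu_r <- sample_reference(vol, gen$truth$reference_bands$rnfl)
    normalize_reflectivity(mean(enface$values), mu_v, mu_r)
  }
  v1 <- measure(gen$volume)
  vol2 <- oct_volume(3.7 * gen$volume$values + 21,
                     gen$volume$axial_pitch_um, gen$volume$lateral_pitch_um)
  v2 <- measure(vol2)
  expect_lt(abs(v1 - v2), 1e-9)
})

test_that("stronger planted attenuation strictly lowers the EZ readout", {
  vals <- vapply(c(0.9, 0.7, 0.5), function(a) {
    gen <- generate_volume(tiny_noiseless_config(ez_attenuation = a))
    enface <- extract_ez_enface(gen$volume, gen$truth$true_rpe_surface)
    mu_v <- sample_reference(gen$volume, gen$truth$reference_bands$vitreous)
    mu_r <- sample_reference(gen$volume, gen$truth$reference_bands$rnfl)
    normalize_reflectivity(mean(enface$values), mu_v, mu_r)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
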