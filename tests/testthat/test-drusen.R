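test_that("elevation map is the clamped floor-minus-RPE difference", {
  z <- matrix(300, 40, 40)
  em <- elevation_map(oct_surface(z), oct_surface(z), 12)
  expect_true(all(em$elevation$values == 0))
  expect_error(elevation_map(oct_surface(z), oct_surface(matrix(300, 30, 40)),
                             12), "same grid")
  dome <- dome_field(data.frame(center_row = 20, center_col = 20,
                                radius_um = 250, peak_um = 60), c(40, 40), 25)
  em2 <- elevation_map(oct_surface(z - dome), oct_surface(z), 25)
  expect_equal(max(em2$elevation$values), 60)
})

test_that("elevations above the ceiling render at the 8-bit maximum", {
  e <- matrix(0, 10, 10); e[5, 5] <- 150; e[2, 2] <- 50
  em <- structure(list(elevation = oct_raster(e, 12), render_clip_um = 100),
                  class = "elevation_map")
  r8 <- render_elevation_8bit(em)
  expect_equal(r8[5, 5], 255L)
  expect_equal(r8[2, 2], 128L)
  expect_equal(r8[1, 1], 0L)
})

test_that("drusen area and volume match an analytic cylinder", {
  nr <- 200; pitch <- 12
  d <- sqrt(outer((1:nr - 100.5)^2, (1:nr - 100.5)^2, "+")) * pitch
  e <- matrix(0, nr, nr); e[d <= 250] <- 50
  em <- structure(list(elevation = oct_raster(e, pitch), render_clip_um = 100),
                  class = "elevation_map")
  roi <- circular_roi_mask(c(nr, nr), pitch, 100.5, 100.5, 2)
  m <- drusen_area_volume(em, roi, 20)
  expect_equal(m$area_mm2, pi * 0.25^2, tolerance = 0.02)
  expect_equal(m$volume_mm3, pi * 0.25^2 * 0.05, tolerance = 0.02)
  none <- drusen_area_volume(em, roi, 60)
  expect_equal(none$area_mm2, 0)
  expect_equal(none$volume_mm3, 0)
  expect_equal(none$percent_of_roi, 0)
  expect_error(drusen_area_volume(em, roi, -1), ">= 0")
})

test_that("raising the elevation threshold never increases area or volume", {
  set.seed(42)
  e <- matrix(pmax(0, rnorm(2500, 20, 15)), 50, 50)
  em <- structure(list(elevation = oct_raster(e, 12), render_clip_um = 100),
                  class = "elevation_map")
  roi <- matrix(TRUE, 50, 50)
  res <- t(sapply(seq(0, 60, by = 5), function(th) {
    m <- drusen_area_volume(em, roi, th)
    c(m$area_mm2, m$volume_mm3)
  }))
  expect_true(all(diff(res[, 1]) <= 1e-12))
  expect_true(all(diff(res[, 2]) <= 1e-12))
})

test_that("maximum-entropy threshold separates a two-level image", {
  img <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  t0 <- max_entropy_threshold(img)
  expect_true(t0 >= 0 && t0 < 255)
  expect_true(all(img[img <= t0] == 0) && all(img[img > t0] == 255))
})

test_that("maximum-entropy threshold rejects constant images", {
  expect_error(max_entropy_threshold(matrix(7, 5, 5)), "constant")
})

test_that("maximum-entropy threshold equals the exhaustive entropy sweep", {
  set.seed(7)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = runif(256)^(i / 2)), 20, 20)
    expect_identical(as.integer(max_entropy_threshold(img)),
                     oracle_max_entropy(img))
  }
  # bimodal mixture, the regime the elevation maps produce
  img <- matrix(pmin(255, pmax(0, round(c(rnorm(600, 40, 12),
                                          rnorm(424, 180, 25))))), 32, 32)
  expect_identical(as.integer(max_entropy_threshold(img)),
                   oracle_max_entropy(img))
})

test_that("maximum-entropy threshold ignores pixel arrangement", {
  set.seed(8)
  img <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
  shuf <- matrix(sample(img), 30, 30)
  expect_identical(as.integer(max_entropy_threshold(img)),
                   as.integer(max_entropy_threshold(shuf)))
})

test_that("drusen masks partition the ROI exactly", {
  gen <- generate_volume(small_speckled_config(drusen_spec = two_domes(),
                                               seed = 2))
  rpe <- segment_rpe(gen$volume)
  fl <- fit_rpe_floor(rpe)
  em <- elevation_map(rpe, fl, 62.5)
  roi <- circular_roi_mask(c(96, 96), 62.5, 48.5, 48.5, 5)
  mk <- drusen_masks(em, roi)
  expect_identical(mk$drusen | mk$drusen_free, roi)
  expect_false(any(mk$drusen & mk$drusen_free))
  expect_equal(sum(mk$drusen) + sum(mk$drusen_free), sum(roi))
  expect_gt(sum(mk$drusen), 0)
})

test_that("flat elevation maps give an empty drusen mask with a warning", {
  em <- structure(list(elevation = oct_raster(matrix(0, 30, 30), 12),
                       render_clip_um = 100), class = "elevation_map")
  roi <- circular_roi_mask(c(30, 30), 200, 15.5, 15.5, 5)
  expect_warning(mk <- drusen_masks(em, roi), "healthy")
  expect_false(any(mk$drusen))
  expect_identical(mk$drusen_free, roi)
})
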