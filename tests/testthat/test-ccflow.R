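test_that("CC slab extraction reproduces a uniform sub-RPE band", {
  gen <- generate_volume(tiny_noiseless_config())
  rpe <- segment_rpe(gen$volume)
  fl <- fit_rpe_floor(rpe)
  slab <- extract_cc_slab(gen$volume, fl)
  # [floor + 29, floor + 49) lies wholly in the uniform choroid layer
  expect_lt(max(abs(slab$values - 60)), 60 * 1e-6)
  deep <- oct_surface(fl$z_um * 0 + 1000)
  expect_error(extract_cc_slab(gen$volume, deep), "exits the volume")
})

test_that("compensation by a uniform structure preserves rank order", {
  set.seed(3)
  flow <- oct_raster(matrix(runif(900, 0.2, 0.9), 30, 30), 20)
  structure_r <- oct_raster(matrix(0.7, 30, 30), 20)
  comp <- compensate_flow(flow, structure_r)
  expect_identical(order(comp$values), order(flow$values))
  expect_error(compensate_flow(flow, oct_raster(matrix(0, 30, 30), 20)),
               "identically zero")
})

test_that("compensation amplification is capped by the floor fraction", {
  set.seed(4)
  flow <- oct_raster(matrix(runif(1600, 0.3, 0.5), 40, 40), 20)
  s <- matrix(0.8, 40, 40); s[15:25, 15:25] <- 1e-6
  comp <- compensate_flow(flow, oct_raster(s, 20), floor_frac = 0.2,
                          sigma_um = 1e-9)
  # capped at 1/eps, then clipped to the input dynamic range
  expect_lte(max(comp$values / flow$values), 1 / 0.2 + 1e-9)
})

test_that("compensation recovers shadowed flow levels", {
  cfg <- phantom_config(grid_rows = 250, grid_cols = 250, lateral_pitch_um = 24,
                        fd_fraction = 0, shadow_factor = 0.5,
                        drusen_spec = data.frame(center_row = 125,
                                                 center_col = 125,
                                                 radius_um = 900,
                                                 peak_um = 80),
                        seed = 9)
  cc <- generate_cc_pair(cfg)
  comp <- compensate_flow(cc$flow, cc$structure)
  sh <- cc$truth$true_drusen_mask
  level_in <- mean(comp$values[sh])
  level_out <- mean(comp$values[!sh])
  expect_lt(abs(level_in / level_out - 1), 0.1)
})

test_that("Phansalkar threshold matches the closed form on flat images", {
  img <- matrix(0.5, 20, 20)
  mask <- phansalkar_binarize(img)
  thr <- attr(mask, "threshold")
  expect_equal(max(abs(thr - 0.5 * (1 + 2 * exp(-5) - 0.25))), 0,
               tolerance = 1e-12)
  expect_false(any(mask))

  all0 <- phansalkar_binarize(matrix(0, 15, 15))
  expect_true(all(all0))

  expect_error(phansalkar_binarize(matrix(7, 5, 5)), "degenerate")
})

test_that("Phansalkar output equals the per-pixel window oracle", {
  set.seed(12)
  img <- matrix(runif(24 * 24), 24, 24)
  got <- phansalkar_binarize(img)
  attr(got, "threshold") <- NULL
  expect_identical(got, oracle_phansalkar(img))
})

test_that("small-deficit removal applies the strict 24-um cutoff", {
  m <- matrix(FALSE, 30, 30)
  m[5, 5:6] <- TRUE                  # 2 px = 288 um^2, equiv diam 19.1 um
  m[20, 10:13] <- TRUE               # 4 px = 576 um^2, equiv diam 27.1 um
  out <- remove_small_deficits(m, 12)
  expect_false(any(out[5, ]))
  expect_identical(out[20, ], m[20, ])

  m3 <- matrix(FALSE, 10, 10); m3[3, 3:5] <- TRUE  # 3 px, 23.45 um
  expect_false(any(remove_small_deficits(m3, 12)))
})

test_that("small-deficit removal equals a brute-force area filter", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(400) < 0.25, 20, 20)
    got <- remove_small_deficits(m, 12, 24)
    lab <- oracle_label(m)
    keep_ids <- which(tabulate(lab[lab > 0]) * 144 >= pi * 12^2)
    want <- matrix(lab %in% keep_ids & m, 20, 20)
    expect_identical(got, want)
    expect_lte(sum(got), sum(m))
  }
})

test_that("flow-deficit metrics follow the bookkeeping arithmetic", {
  m <- matrix(FALSE, 40, 40)
  m[5:6, 5:6] <- TRUE          # 4 px in-mask
  m[20, 10:20] <- TRUE         # 11 px component, partially clipped below
  mask <- matrix(FALSE, 40, 40); mask[1:40, 1:15] <- TRUE
  r <- fd_metrics(m, mask, 12)
  expect_equal(r$fd_count, 2)
  expect_equal(r$fd_percent, 100 * (4 + 6) / sum(mask))
  expect_equal(r$fd_mean_size_um2, mean(c(4, 6)) * 144)

  r2 <- fd_metrics(matrix(FALSE, 40, 40), mask, 12)
  expect_equal(r2$fd_percent, 0)
  expect_equal(r2$fd_count, 0)
  expect_true(is.na(r2$fd_mean_size_um2))

  full <- fd_metrics(mask, mask, 12)
  expect_equal(full$fd_percent, 100)
  expect_error(fd_metrics(m, matrix(FALSE, 40, 40), 12), "empty")
})

test_that("two components of 5 and 10 pixels give mean size 1080 um^2", {
  m <- matrix(FALSE, 30, 30)
  m[5, 3:7] <- TRUE
  m[15:16, 20:24] <- TRUE
  mask <- matrix(TRUE, 30, 30)
  r <- fd_metrics(m, mask, 12)
  expect_equal(r$fd_percent, 100 * 15 / 900)
  expect_equal(r$fd_mean_size_um2, 7.5 * 144)
})

test_that("whole-ROI FD% is the area-weighted mean of the region values", {
  set.seed(5)
  roi <- circular_roi_mask(c(80, 80), 75, 40.5, 40.5, 5)
  drusen <- roi & matrix(runif(6400) < 0.2, 80, 80)
  df <- roi & !drusen
  deficits <- matrix(runif(6400) < 0.3, 80, 80)
  whole <- fd_metrics(deficits, roi, 75)$fd_percent
  a <- fd_metrics(deficits, drusen, 75)$fd_percent
  b <- fd_metrics(deficits, df, 75)$fd_percent
  agg <- (sum(drusen) * a + sum(df) * b) / sum(roi)
  expect_equal(whole, agg, tolerance = 1e-12)
})

test_that("vessel exclusion is pure area bookkeeping", {
  roi <- circular_roi_mask(c(60, 60), 100, 30.5, 30.5, 5)
  expect_identical(remove_projection_artifacts(roi, NULL), roi)
  vessels <- matrix(FALSE, 60, 60); vessels[, 28:33] <- TRUE
  excl <- remove_projection_artifacts(roi, vessels)
  expect_equal(sum(excl), sum(roi) - sum(roi & vessels))

  # FD% unchanged when the excluded band has the same deficit fraction
  deficits <- matrix(FALSE, 60, 60); deficits[seq(1, 60, 2), ] <- TRUE
  with_v <- fd_metrics(deficits, excl, 100)$fd_percent
  without <- fd_metrics(deficits, roi, 100)$fd_percent
  expect_equal(with_v, without, tolerance = 1e-9)
})
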