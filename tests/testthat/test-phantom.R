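test_that("identical (config, seed) gives bit-identical phantoms", {
  cfg <- small_speckled_config(drusen_spec = two_domes(), seed = 11)
  a <- generate_volume(cfg); b <- generate_volume(cfg)
  expect_identical(a$volume$values, b$volume$values)
  ca <- generate_cc_pair(cfg); cb <- generate_cc_pair(cfg)
  expect_identical(ca$flow$values, cb$flow$values)
  expect_identical(ca$truth$true_fd_mask, cb$truth$true_fd_mask)
})

test_that("planted truth rasters are constructed, not measured", {
  cfg <- tiny_noiseless_config()
  gen <- generate_volume(cfg)
  expect_true(all(gen$truth$true_elevation$values == 0))
  expect_false(any(gen$truth$true_drusen_mask))

  spec <- data.frame(center_row = 24, center_col = 24,
                     radius_um = 600, peak_um = 60)
  gen2 <- generate_volume(tiny_noiseless_config(drusen_spec = spec))
  expect_equal(max(gen2$truth$true_elevation$values), 60)
  expect_identical(gen2$truth$true_drusen_mask,
                   gen2$truth$true_elevation$values > 0)
})

test_that("noiseless EZ band carries the configured layer mean exactly", {
  gen <- generate_volume(tiny_noiseless_config())
  enface <- extract_ez_enface(gen$volume, gen$truth$true_rpe_surface)
  expect_lt(max(abs(enface$values / 130 - 1)), 1e-6)
})

test_that("volume rejects a layer stack that does not fit", {
  expect_error(phantom_config(grid_rows = 48, grid_cols = 48,
                              lateral_pitch_um = 125,
                              depth_voxels = 60, axial_pitch_um = 4),
               "exceeds the volume depth")
})

test_that("config validation enforces the documented invariants", {
  expect_error(tiny_noiseless_config(fd_fraction = 1), "fd_fraction")
  expect_error(tiny_noiseless_config(fd_blob_scale_um = 10), ">= 24")
  expect_error(tiny_noiseless_config(ez_attenuation = 1.2), "ez_attenuation")
  expect_error(tiny_noiseless_config(
    drusen_spec = data.frame(center_row = 24, center_col = 24,
                             radius_um = 300, peak_um = 200)), "<= 150")
})

test_that("planted CC deficits hit the target fraction and stay off borders", {
  cfg <- phantom_config(grid_rows = 250, grid_cols = 250, lateral_pitch_um = 24,
                        fd_fraction = 0.2, fd_blob_scale_um = 40, seed = 5)
  cc <- generate_cc_pair(cfg)
  expect_equal(cc$truth$true_fd_fraction, mean(cc$truth$true_fd_mask))
  expect_gt(cc$truth$true_fd_fraction, 0.18)
  expect_lt(cc$truth$true_fd_fraction, 0.22)
  expect_false(any(cc$truth$true_fd_mask[1, ]))
  expect_false(any(cc$truth$true_fd_mask[, 1]))
  expect_false(any(cc$truth$true_fd_mask[250, ]))
  expect_false(any(cc$truth$true_fd_mask[, 250]))
})

test_that("zero deficit fraction yields an empty deficit mask", {
  cc <- generate_cc_pair(tiny_noiseless_config(fd_fraction = 0))
  expect_false(any(cc$truth$true_fd_mask))
})

test_that("without shadowing, flow is flat outside the planted deficits", {
  cc <- generate_cc_pair(tiny_noiseless_config(fd_fraction = 0.1,
                                               shadow_factor = 1))
  outside <- cc$flow$values[!cc$truth$true_fd_mask]
  expect_equal(max(outside), min(outside))
  expect_equal(max(cc$structure$values), min(cc$structure$values))
})

test_that("uncoupled cohorts show near-zero planted rank correlation", {
  hits <- 0L
  for (seed in 1:60) {
    ch <- generate_cohort(35, amd_effects = list(
      ez_mean = 0.76, ez_sd = 0.10, fd_mean_pct = 24, fd_sd_pct = 6,
      rho = 0, drusen = FALSE), seed = seed)
    amd <- ch$eyes[vapply(ch$eyes, function(e) e$group == "AMD", logical(1))]
    ez <- vapply(amd, function(e) e$planted$ez_target, numeric(1))
    fd <- vapply(amd, function(e) e$planted$fd_target, numeric(1))
    if (abs(cor(ez, fd, method = "spearman")) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)
})

test_that("planted coupling approximates the target Spearman rho", {
  hits <- 0L
  for (seed in 1:60) {
    ch <- generate_cohort(35, seed = seed)  # default AMD rho = -0.4
    amd <- ch$eyes[vapply(ch$eyes, function(e) e$group == "AMD", logical(1))]
    ez <- vapply(amd, function(e) e$planted$ez_target, numeric(1))
    fd <- vapply(amd, function(e) e$planted$fd_target, numeric(1))
    if (abs(cor(ez, fd, method = "spearman") - (-0.4)) <= 0.25)
      hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.8)
})

test_that("identical group effects plant no group difference", {
  ef <- list(ez_mean = 0.8, ez_sd = 0.1, fd_mean_pct = 20, fd_sd_pct = 6,
             rho = 0, drusen = FALSE)
  ch <- generate_cohort(50, amd_effects = ef, control_effects = ef, seed = 3)
  ez <- vapply(ch$eyes, function(e) e$planted$ez_target, numeric(1))
  grp <- vapply(ch$eyes, function(e) e$group, character(1))
  expect_lt(abs(mean(ez[grp == "AMD"]) - mean(ez[grp == "control"])), 0.06)
})

test_that("degenerate cohort parameters are rejected", {
  expect_error(generate_cohort(1), ">= 2")
  expect_error(generate_cohort(5, amd_effects = list(
    ez_mean = 0.8, ez_sd = -0.1, fd_mean_pct = 20, fd_sd_pct = 6,
    rho = 0, drusen = FALSE)), "SD")
})
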