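# Small phantom configurations shared across test files.

tiny_noiseless_config <- function(..., seed = 1L) {
  phantom_config(grid_rows = 48, grid_cols = 48, lateral_pitch_um = 125,
                 depth_voxels = 140, axial_pitch_um = 4,
                 speckle_shape = Inf, cc_speckle_shape = Inf,
                 seed = seed, ...)
}

small_speckled_config <- function(..., seed = 1L) {
  phantom_config(grid_rows = 96, grid_cols = 96, lateral_pitch_um = 62.5,
                 depth_voxels = 100, axial_pitch_um = 5,
                 bm_center_um = 400, bm_tilt_um = c(10, 5), bm_bow_um = 6,
                 seed = seed, ...)
}

# drusen layout with two well-separated mounds inside the 5-mm circle
two_domes <- function(shape = c(96, 96), pitch = 62.5) {
  data.frame(center_row = c(0.35, 0.65) * shape[1],
             center_col = c(0.4, 0.62) * shape[2],
             radius_um = c(300, 250), peak_um = c(60, 90))
}
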