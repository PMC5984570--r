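# small shared fixtures, built once per test run

small_spec <- function(...) phantom_spec(grid_shape = c(32L, 32L, 28L), ...)

quiet_severity <- function(...) {
  severity_profile(texture_amplitude = 0, ...)
}

# resample `vol` so its NMI-optimal alignment to itself is `truth`
displaced_copy <- function(vol, truth) {
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- datradiomics:::voxel_to_world(idx, d, vol$spacing_mm)
  mv <- interpolate_trilinear(vol, transform_points(invert_transform(truth),
                                                    xyz))
  mv[is.na(mv)] <- 0
  vol3d(array(mv, d), vol$spacing_mm)
}
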