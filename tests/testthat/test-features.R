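test_that("the registry reproduces every structural count", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 92L)
  expect_identical(sum(reg$category == "first_order"), 13L)
  expect_identical(sum(reg$category == "morphological"), 22L)
  expect_identical(sum(reg$category == "textural"), 57L)
  expect_identical(as.integer(table(reg$subfamily)[c("GLCM", "GLSZM",
                                                     "GLRLM")]),
                   c(26L, 16L, 15L))
  expect_identical(sum(reg$uses_uptake), 75L)
  expect_identical(sum(!reg$uses_uptake), 17L)
  expect_identical(sum(reg$is_conventional), 4L)
  # CSV round trip (the shipped versioned registry)
  path <- withr::local_tempfile(fileext = ".csv")
  datradiomics:::write_feature_registry(path)
  expect_identical(feature_registry(path), reg)
})

test_that("discretization is uniform, constant-safe, and affine-invariant", {
  m <- array(TRUE, c(4, 1, 1))
  v <- array(c(0, 1, 2, 3), c(4, 1, 1))
  expect_identical(as.integer(discretize(v, m, 4)$levels), 1:4)
  const <- array(7, c(4, 1, 1))
  expect_true(all(discretize(const, m, 16)$levels == 1L))
  set.seed(2)
  x <- array(rnorm(60), c(5, 4, 3))
  msk <- array(runif(60) > 0.3, c(5, 4, 3))
  g1 <- discretize(x, msk, 8)
  g2 <- discretize(2.5 * x + 10, msk, 8)
  expect_identical(g1$levels, g2$levels)
})

test_that("GLCM matches hand counts on a 2-level toy and conventions on constants", {
  # constant region: single gray level
  glc <- gl_of(array(1, c(3, 3, 1)), 2)
  f <- glcm_features(glc)
  expect_equal(f[["glcm_diff_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  # hand-countable 2x2x1 toy: levels [1 2; 2 1] (column-major c(1,2,2,1))
  gl <- gl_of(array(c(1L, 2L, 2L, 1L), c(2, 2, 1)), 2)
  offs <- matrix(c(1L, 0L, 0L,  0L, 1L, 0L), 2, byrow = TRUE)
  M <- glcm_matrix(gl, offs)
  # 4 ordered pairs per axis direction, all discordant: p(1,2)=p(2,1)=1/2
  expect_equal(M / sum(M), matrix(c(0, .5, .5, 0), 2))
  f2 <- glcm_features(gl, offs)
  # p_(x-y): P(k=1) = 1 -> difference entropy 0; contrast = 1
  expect_equal(f2[["glcm_diff_entropy"]], 0)
  expect_equal(f2[["glcm_contrast"]], 1)
  # joint entropy of {1/2, 1/2} = 1 bit
  expect_equal(f2[["glcm_joint_entropy"]], 1)
})

test_that("checkerboard correlation is -1 for axis offsets", {
  d <- c(6, 6, 6)
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  lv <- array(1L + (rowSums(idx) %% 2L), dim = d)
  gl <- gl_of(lv, 2)
  axis_offs <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3, byrow = TRUE)
  f <- glcm_features(gl, axis_offs)
  expect_equal(f[["glcm_correlation"]], -1, tolerance = 1e-9)
})

test_that("GLSZM reproduces hand-built zone structures", {
  # constant region of n voxels: one zone, level 1 -> SZHGE = 1/n^2
  gl <- gl_of(array(1, c(3, 2, 1)), 2)
  f <- glszm_features(gl)
  expect_equal(f[["glszm_szhge"]], 1 / 36)
  expect_equal(f[["glszm_zone_percentage"]], 1 / 6)
  # zones {(level 2, size 1), (level 1, size 3)} -> SZHGE = (4 + 1/9)/2
  gl2 <- gl_of(array(c(2L, 1L, 1L, 1L), c(4, 1, 1)), 2)
  f2 <- glszm_features(gl2)
  expect_equal(f2[["glszm_szhge"]], (4 + 1 / 9) / 2, tolerance = 1e-9)
  expect_equal(f2[["glszm_lzlge"]], (1 / 4 + 9) / 2, tolerance = 1e-9)
})

test_that("gray-level reversal swaps high/low zone emphases", {
  for (seed in 1:5) {
    gl <- random_gl_toy(seed)
    rev_ <- gl
    rev_$levels <- gl$n_bins + 1L - gl$levels
    a <- glszm_features(gl)
    b <- glszm_features(rev_)
    # reversal maps level i -> Ng+1-i: zone sizes unchanged
    expect_equal(a[["glszm_zsn"]], b[["glszm_zsn"]])
    expect_equal(a[["glszm_zs_variance"]], b[["glszm_zs_variance"]])
    expect_equal(a[["glszm_gl_variance"]], b[["glszm_gl_variance"]])
  }
})

test_that("GLRLM handles degenerate runs and matches the brute-force oracle", {
  # constant 1D line, single axis direction: one run of length n, RP = 1/n
  gl <- gl_of(array(1L, c(5, 1, 1)), 2)
  ax <- matrix(c(1L, 0L, 0L), 1)
  f <- glrlm_features(gl, ax)
  expect_equal(f[["glrlm_rp"]], 1 / 5)
  expect_equal(f[["glrlm_lre"]], 25)
  # strictly alternating line: all runs length 1
  gl2 <- gl_of(array(rep(c(1L, 2L), 5), c(10, 1, 1)), 2)
  f2 <- glrlm_features(gl2, ax)
  expect_equal(f2[["glrlm_sre"]], 1)
  expect_equal(f2[["glrlm_lre"]], 1)
  # 100-voxel random 3-level toy equals the independent run enumerator
  gl3 <- withr::with_seed(31, gl_of(array(sample.int(3, 100, TRUE), c(5, 5, 4)), 3))
  expect_equal(glrlm_features(gl3), oracle_glrlm_features(gl3$levels,
                                                          unit_offsets_13()),
               tolerance = 1e-12)
})

test_that("first-order features match hand arithmetic and distributional oracles", {
  m <- array(TRUE, c(4, 1, 1))
  v <- array(c(1, 2, 3, 4), c(4, 1, 1))
  f <- first_order_features(v, m, spacing_mm = 1)
  expect_equal(f[["fo_suv_mean"]], 2.5)
  expect_equal(f[["fo_median"]], 2.5)
  expect_equal(f[["fo_sd"]], sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_equal(f[["fo_suv_max"]], 4)
  expect_equal(f[["fo_energy"]], 1 + 4 + 9 + 16)
  # constant region: max = mean = peak = median, SD = CoV = 0
  fc <- first_order_features(array(3, c(3, 3, 3)), array(TRUE, c(3, 3, 3)),
                             spacing_mm = 2)
  expect_equal(unname(fc[c("fo_suv_max", "fo_suv_mean", "fo_suv_peak",
                           "fo_median")]), rep(3, 4))
  expect_equal(unname(fc[c("fo_sd", "fo_cov")]), c(0, 0))
  # seeded Gaussian sample: skewness ~ 0, excess kurtosis ~ 0
  g <- withr::with_seed(7, array(rnorm(1000), c(10, 10, 10)))
  fg <- first_order_features(g, array(TRUE, c(10, 10, 10)), spacing_mm = 1)
  expect_lt(abs(fg[["fo_skewness"]]), 0.25)
  expect_lt(abs(fg[["fo_kurtosis"]]), 0.5)
})

test_that("morphology: digitized ball and cube benchmarks", {
  # ball r = 10 mm at 1 mm voxels
  d <- c(25, 25, 25)
  ctr <- (d + 1) / 2
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  ball <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 10, dim = d)
  f <- morphology_features(ball, array(1, dim = d), spacing_mm = 1)
  expect_gt(f[["morph_sphericity"]], 0.95)
  expect_lte(f[["morph_sphericity"]], 1.0)
  expect_lt(abs(f[["morph_volume_mm3"]] - 4188.8) / 4188.8, 0.05)
  # uptake constant -> intensity-weighted centroid displacement 0
  expect_equal(f[["morph_iw_centroid_shift_mm"]], 0)
  # 8-voxel cube at 2 mm spacing: exactly 64 mm^3
  cube <- array(FALSE, c(6, 6, 6)); cube[3:4, 3:4, 3:4] <- TRUE
  fc <- morphology_features(cube, array(1, c(6, 6, 6)), spacing_mm = 2)
  expect_equal(fc[["morph_volume_mm3"]], 64)
  expect_equal(fc[["morph_extent"]], 1)
})

test_that("uptake-volume asymmetry is signed and zero for identical sides", {
  d <- c(10, 6, 6)
  a <- array(FALSE, d); a[2:3, 2:4, 2:4] <- TRUE
  b <- array(FALSE, d); b[7:8, 2:4, 2:4] <- TRUE
  up <- array(1, d)
  up[b] <- c(rep(1, sum(b) - 4), rep(0.2, 4))  # shrink contralateral V50
  fa <- morphology_features(a, up, spacing_mm = 1, contralateral_mask = b)
  expect_gt(fa[["morph_uptake_asymmetry"]], 0)
  f0 <- morphology_features(a, array(1, d), spacing_mm = 1,
                            contralateral_mask = b)
  expect_equal(f0[["morph_uptake_asymmetry"]], 0)
})

test_that("normalization to the occipital reference is exact and guarded", {
  spec <- small_spec(psf_fwhm_mm = 0, noise_scale = 0)
  lab <- generate_label_volume(spec)
  sev <- severity_profile(ratios = c(caudate = 2.5, putamen = 2.0, vs = 2.2),
                          asymmetry_factor = 1, texture_amplitude = 0)
  up <- generate_uptake_volume(lab, sev, spec, seed = 1)
  up$data <- up$data * 3.7  # arbitrary scanner scale
  occ <- lab$data == label_codes()[["occipital"]]
  norm <- normalize_to_reference(up, occ)
  expect_equal(mean(norm$data[occ]), 1)
  put <- lab$data == label_codes()[["putamen_left"]]
  expect_equal(mean(norm$data[put]), 2.0)
  bad <- up; bad$data <- bad$data * 0
  expect_error(normalize_to_reference(bad, occ), "non-positive")
})

test_that("subject extraction yields 92 x 6 x 2 values, deterministic and translation-invariant", {
  spec <- small_spec()
  coh <- generate_cohort(2, spec, seed = 17)
  sides <- assign_affected_sides(coh$subjects[[1]]$spect_y0, coh$labels)
  ft <- extract_subject_features(coh$subjects[[1]], coh$labels, sides)
  expect_identical(nrow(ft), 92L * 6L * 2L)
  expect_identical(as.integer(table(ft$timepoint)), c(552L, 552L))
  # determinism: identical voxel data -> identical features
  ft2 <- extract_subject_features(coh$subjects[[1]], coh$labels, sides)
  expect_identical(ft, ft2)
  # translating SPECT and labels together (3 voxels along z, where every
  # mask keeps a margin) leaves every feature unchanged
  sh <- function(a) { out <- a * 0L; out[, , 4:dim(a)[3]] <-
    a[, , 1:(dim(a)[3] - 3)]; out }
  sub_t <- coh$subjects[[1]]
  sub_t$spect_y0 <- vol3d(sh(sub_t$spect_y0$data), spec$voxel_size_mm)
  sub_t$spect_y1 <- vol3d(sh(sub_t$spect_y1$data), spec$voxel_size_mm)
  lab_t <- vol3d(sh(coh$labels$data), spec$voxel_size_mm, "label")
  ft3 <- extract_subject_features(sub_t, lab_t, sides)
  expect_equal(ft3$value, ft$value, tolerance = 1e-9)
})

test_that("texture features respond monotonically to the texture amplitude", {
  spec <- small_spec(noise_scale = 0)
  lab <- generate_label_volume(spec)
  put <- lab$data == label_codes()[["putamen_left"]]
  amps <- seq(0.02, 0.40, length.out = 20)
  res <- vapply(amps, function(a) {
    sev <- severity_profile(texture_amplitude = a, asymmetry_factor = 1)
    up <- generate_uptake_volume(lab, sev, spec, seed = 99, texture_seed = 50)
    gl <- discretize(up, put, 16)
    c(contrast = glcm_features(gl)[["glcm_contrast"]],
      sd = first_order_features(up, put, spacing_mm = 2)[["fo_sd"]])
  }, c(contrast = 0, sd = 0))
  # undiscretized heterogeneity tracks the amplitude exactly
  expect_gt(cor(amps, res["sd", ], method = "spearman"), 0.99)
  # discretized contrast is a strictly monotone readout as well; under
  # min-max binning its direction is decreasing (the field's tails stretch
  # the range, squeezing typical neighbour differences)
  expect_gt(abs(cor(amps, res["contrast", ], method = "spearman")), 0.9)
})

test_that("feature tables round-trip through CSV with completeness validation", {
  coh <- generate_cohort(2, small_spec(), seed = 23)
  ft <- extract_cohort_features(coh)
  expect_identical(nrow(ft), 2L * 2L * 6L * 92L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$value, ft$value, tolerance = 1e-12)
  # hand-truncated file: reader names the missing rows
  trunc <- ft[-(3:7), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(trunc, path2)
  expect_error(read_feature_table(path2), "fo_suv_peak")
})
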