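#' Default striatal ROI geometry
#'
#' Ellipsoid centres/semi-axes (mm, volume-centred frame, x < 0 = left) for
#' the left-hemisphere caudate, putamen and ventral striatum, plus a
#' posterior occipital slab and a whole-brain ellipsoid whose unlabelled
#' interior becomes white matter. Right-hemisphere ROIs are exact mirrors
#' across the midsagittal plane x = 0.
#'
#' @return data.frame with columns `roi`, `kind`, `cx`, `cy`, `cz`,
#'   `ax`, `ay`, `az` (slab rows use half-widths of the box).
#' @export
default_roi_geometry <- function() {
  data.frame(
    roi  = c("caudate", "putamen", "vs", "occipital", "brain"),
    kind = c("ellipsoid", "ellipsoid", "ellipsoid", "slab", "ellipsoid"),
    cx   = c(-14, -26, -12,   0,  0),
    cy   = c( 12,   0,  14, -32,  0),
    cz   = c(  6,   0,  -8,   0,  2),
    ax   = c(  5,   6,   4,  28, 40),
    ay   = c(  9,  10,   5,   5, 42),
    az   = c(  6,   7,   4,  16, 30),
    stringsAsFactors = FALSE
  )
}

#' Phantom specification
#'
#' Defines the lattice and anatomy of the synthetic DAT-SPECT phantom: six
#' striatal ROIs (left/right caudate, putamen, ventral striatum), an
#' occipital reference slab, and a white-matter shell inside a brain
#' ellipsoid; plus the point-spread blur and noise level of the emulated
#' scanner.
#'
#' @param grid_shape integer length-3, voxels per axis of the SPECT lattice.
#' @param voxel_size_mm isotropic SPECT voxel size (mm).
#' @param t1_voxel_size_mm isotropic voxel size of the T1-like volume (mm).
#' @param roi_geometry per-ROI geometry table, see [default_roi_geometry()].
#' @param psf_fwhm_mm Gaussian post-smoothing FWHM (mm) applied to uptake
#'   volumes; emulates reconstructed SPECT resolution.
#' @param noise_scale log-sd of the multiplicative (log-normal) voxel noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 40L),
                         voxel_size_mm = 2,
                         t1_voxel_size_mm = 1,
                         roi_geometry = default_roi_geometry(),
                         psf_fwhm_mm = 6,
                         noise_scale = 0.05) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            voxel_size_mm > 0, t1_voxel_size_mm > 0,
            psf_fwhm_mm >= 0, noise_scale >= 0)
  need <- c("caudate", "putamen", "vs", "occipital", "brain")
  if (!all(need %in% roi_geometry$roi)) {
    stop("roi_geometry must define rows: ", paste(need, collapse = ", "))
  }
  if (any(roi_geometry[, c("ax", "ay", "az")] <= 0)) {
    stop("all ROI semi-axes must be positive")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 t1_voxel_size_mm = t1_voxel_size_mm,
                 roi_geometry = roi_geometry,
                 psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale),
            class = "phantom_spec")
}

#' Severity profile of one synthetic subject
#'
#' Latent generative parameters of striatal uptake: per-structure binding
#' ratios at year 0 (occipital reference = 1), the multiplicative reduction
#' on the more-affected side, a smooth multiplicative texture field
#' (correlation length + amplitude), and the fractional annual decline in
#' binding ratio.
#'
#' @param ratios named numeric: year-0 uptake-to-occipital ratio for
#'   `caudate`, `putamen`, `vs`.
#' @param asymmetry_factor multiplicative factor in (0, 1] applied to the
#'   more-affected side.
#' @param affected_side `"left"` or `"right"` — the more-affected hemisphere.
#' @param texture_amplitude sd of the multiplicative heterogeneity field.
#' @param texture_corr_mm correlation length (mm) of the field.
#' @param annual_decline fractional binding-ratio loss per year, in [0, 1).
#' @return object of class `severity_profile`.
#' @export
severity_profile <- function(ratios = c(caudate = 2.5, putamen = 1.8, vs = 2.2),
                             asymmetry_factor = 0.8,
                             affected_side = "left",
                             texture_amplitude = 0.15,
                             texture_corr_mm = 6,
                             annual_decline = 0.08) {
  stopifnot(all(c("caudate", "putamen", "vs") %in% names(ratios)),
            all(ratios >= 0),
            asymmetry_factor > 0, asymmetry_factor <= 1,
            affected_side %in% c("left", "right"),
            texture_amplitude >= 0, texture_corr_mm > 0,
            annual_decline >= 0, annual_decline < 1)
  structure(list(ratios = ratios, asymmetry_factor = asymmetry_factor,
                 affected_side = affected_side,
                 texture_amplitude = texture_amplitude,
                 texture_corr_mm = texture_corr_mm,
                 annual_decline = annual_decline),
            class = "severity_profile")
}

#' Outcome-model coefficients
#'
#' The year-4 UPDRS-III outcome of a synthetic subject is
#' `a0 + a1 * updrs3_y1 + a2 * (updrs3_y1 - updrs3_y0) +
#'  a3 * texture_amplitude + a4 * annual_decline + N(0, noise_sd)`,
#' clipped to the 0–132 scale. With `imaging_signal = FALSE` the imaging
#' latents carry no signal (a3 = a4 = 0) and the intercept is shifted so the
#' outcome scale is preserved — the "null cohort" used to check that the
#' model finds nothing when nothing is there.
#'
#' @param a0,a1,a2,a3,a4 model coefficients (see Details).
#' @param noise_sd Gaussian noise sd on the outcome scale.
#' @param imaging_signal logical; `FALSE` zeroes a3/a4 and re-centres a0.
#' @return object of class `outcome_coeffs`.
#' @export
outcome_coeffs <- function(a0 = -35, a1 = 0.7, a2 = 0.8, a3 = 140, a4 = 100,
                           noise_sd = 3, imaging_signal = TRUE) {
  if (!imaging_signal) {
    a0 <- a0 + a3 * 0.25 + a4 * 0.085  # keep E[outcome] at the default scale
    a3 <- 0
    a4 <- 0
  }
  co <- c(a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  stopifnot(all(is.finite(co)), is.finite(noise_sd), noise_sd >= 0)
  structure(list(a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4,
                 noise_sd = noise_sd), class = "outcome_coeffs")
}

#' @rdname severity_profile
#' @param seed integer seed.
#' @details `sample_severity_profile()` draws one subject's latents:
#' structure ratios jittered log-normally (sd 0.06) around the defaults,
#' asymmetry uniform on [0.7, 0.95], affected side a fair coin, texture
#' amplitude uniform on [0.05, 0.45], annual decline uniform on
#' [0.02, 0.15].
#' @export
sample_severity_profile <- function(seed) {
  withr::with_seed(seed, {
    base <- c(caudate = 2.5, putamen = 1.8, vs = 2.2)
    severity_profile(
      ratios = base * exp(stats::rnorm(3, 0, 0.06)),
      asymmetry_factor = stats::runif(1, 0.70, 0.95),
      affected_side = sample(c("left", "right"), 1),
      texture_amplitude = stats::runif(1, 0.05, 0.45),
      texture_corr_mm = 6,
      annual_decline = stats::runif(1, 0.02, 0.15)
    )
  })
}

#' Draw one subject's clinical record
#'
#' Marginals emulate an early PD cohort: age ~ N(61.9, 7.3) clipped to
#' [46, 78], P(male) = 38/64, short disease durations with symptom onset
#' preceding diagnosis, UPDRS-III(y0) ~ N(20, 9) clipped to [3, 60] with a
#' mean 3-point one-year worsening, MoCA near ceiling with slight decline.
#'
#' @param seed integer seed.
#' @return list of class `clinical_record` with fields `age`, `sex`,
#'   `dd_diag`, `dd_sympt`, `updrs3_y0`, `updrs3_y1`, `moca_y0`, `moca_y1`.
#' @export
sample_clinical_record <- function(seed) {
  withr::with_seed(seed, {
    age <- round(min(78, max(46, stats::rnorm(1, 61.9, 7.3))))
    sex <- sample(c("M", "F"), 1, prob = c(38, 26) / 64)
    dd_diag <- stats::rgamma(1, shape = 2, scale = 0.4)
    dd_sympt <- dd_diag + stats::rgamma(1, shape = 2, scale = 0.5)
    u0 <- round(min(60, max(3, stats::rnorm(1, 20, 9))))
    u1 <- round(min(80, max(0, u0 + stats::rnorm(1, 3, 5))))
    m0 <- round(min(30, max(15, stats::rnorm(1, 27, 2))))
    m1 <- round(min(30, max(10, m0 + stats::rnorm(1, -0.3, 1.5))))
    structure(list(age = age, sex = sex, dd_diag = dd_diag,
                   dd_sympt = dd_sympt, updrs3_y0 = u0, updrs3_y1 = u1,
                   moca_y0 = m0, moca_y1 = m1),
              class = "clinical_record")
  })
}

#' Label codes used by the phantom
#' @return named integer vector mapping region names to label values.
#' @export
label_codes <- function() {
  c(background = 0L, caudate_left = 1L, caudate_right = 2L,
    putamen_left = 3L, putamen_right = 4L, vs_left = 5L, vs_right = 6L,
    occipital = 7L, white_matter = 8L)
}

#' The six analysis structures
#' @keywords internal
striatal_structures <- function() c("caudate", "putamen", "vs")
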