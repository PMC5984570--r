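#' Generate the phantom label volume
#'
#' Rasterises the spec's ROI geometry onto the SPECT lattice (or the T1
#' lattice with `lattice = "t1"`): six striatal ellipsoids (left and their
#' exact mirror images on the right), an occipital slab, and a white-matter
#' fill of the remaining brain-ellipsoid interior. Rejects geometries whose
#' ROIs collide on the lattice, naming the colliding pair.
#'
#' @param spec a [phantom_spec()].
#' @param lattice `"spect"` (default) or `"t1"`.
#' @return a label [vol3d()] using the codes of [label_codes()].
#' @export
generate_label_volume <- function(spec, lattice = c("spect", "t1")) {
  lattice <- match.arg(lattice)
  if (lattice == "spect") {
    d <- spec$grid_shape
    sp <- rep(spec$voxel_size_mm, 3)
  } else {
    extent <- spec$grid_shape * spec$voxel_size_mm
    d <- as.integer(round(extent / spec$t1_voxel_size_mm))
    sp <- rep(spec$t1_voxel_size_mm, 3)
  }
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]

  geom <- spec$roi_geometry
  row_of <- function(r) geom[geom$roi == r, , drop = FALSE]
  inside <- function(g, mirror_x = FALSE) {
    s <- if (mirror_x) -1 else 1
    X <- (cx - s * g$cx) / g$ax
    Y <- (cy - g$cy) / g$ay
    Z <- (cz - g$cz) / g$az
    if (g$kind == "ellipsoid") {
      outer(outer(X^2, Y^2, "+"), Z^2, "+") <= 1
    } else { # slab: axis-aligned box with half-widths ax/ay/az
      outer(outer(abs(X) <= 1, abs(Y) <= 1, "&"), abs(Z) <= 1, "&")
    }
  }

  codes <- label_codes()
  lab <- array(0L, dim = d)
  owner <- character(0)
  paint <- function(lab, mask, code, name) {
    clash <- lab[mask] != 0L
    if (any(clash)) {
      hit <- names(codes)[match(unique(lab[mask][clash]), codes)]
      stop(sprintf("ROI geometry overlap: '%s' collides with %s on the lattice",
                   name, paste(sQuote(hit), collapse = ", ")))
    }
    lab[mask] <- code
    lab
  }
  for (r in striatal_structures()) {
    g <- row_of(r)
    lab <- paint(lab, inside(g, FALSE), codes[[paste0(r, "_left")]],
                 paste0(r, "_left"))
    lab <- paint(lab, inside(g, TRUE), codes[[paste0(r, "_right")]],
                 paste0(r, "_right"))
  }
  lab <- paint(lab, inside(row_of("occipital")), codes[["occipital"]],
               "occipital")
  brain <- inside(row_of("brain"))
  lab[brain & lab == 0L] <- codes[["white_matter"]]
  vol3d(lab, sp, "label")
}

#' Smooth multiplicative texture field
#'
#' White Gaussian noise filtered at the stated correlation length and
#' rescaled to unit standard deviation over the lattice, then multiplied by
#' the amplitude. Emulates spatial heterogeneity of tracer binding that
#' survives the scanner blur.
#'
#' @param dim integer length-3 lattice size.
#' @param spacing_mm voxel spacing (mm).
#' @param corr_mm correlation length (Gaussian FWHM of the filter, mm).
#' @param amplitude field standard deviation.
#' @param seed integer seed.
#' @param norm_mask optional logical array: the field is centred and scaled
#'   to zero mean / unit sd over these voxels (the striatum, in cohort
#'   generation) rather than the whole lattice, so `amplitude` is the
#'   realized heterogeneity of the tissue of interest, not a lattice-wide
#'   nominal value.
#' @return 3D array of multiplicative deviations (mean ~ 0, sd = amplitude).
#' @export
generate_texture_field <- function(dim, spacing_mm, corr_mm, amplitude, seed,
                                   norm_mask = NULL) {
  if (amplitude <= 0) return(array(0, dim = dim))
  withr::with_seed(seed, {
    w <- array(stats::rnorm(prod(dim)), dim = dim)
    f <- gaussian_blur3(w, corr_mm, spacing_mm = spacing_mm)
    ref <- if (is.null(norm_mask)) f else f[norm_mask]
    f <- (f - mean(ref)) / stats::sd(ref)
    pmax(f * amplitude, -0.9)  # keep uptake positive
  })
}

#' Generate one uptake (SPECT-like) volume
#'
#' Composes the noiseless phantom — occipital and white matter at exactly 1,
#' striatal ROIs at `ratio * side_factor * (1 + texture)` — then applies the
#' spec's Gaussian point-spread blur and multiplicative log-normal noise.
#' Deterministic for a fixed seed.
#'
#' @param labels label [vol3d()] from [generate_label_volume()].
#' @param severity a [severity_profile()].
#' @param spec the [phantom_spec()] (supplies blur and noise level).
#' @param seed integer seed (texture and noise).
#' @param year scan year; binding ratios decay as
#'   `(1 - annual_decline)^year`. The texture field is the subject's own
#'   (seeded by `texture_seed`) and is shared across years.
#' @param texture_seed seed of the subject-level texture field (default
#'   `seed`).
#' @return a scalar [vol3d()].
#' @export
generate_uptake_volume <- function(labels, severity, spec, seed, year = 0,
                                   texture_seed = seed) {
  stopifnot(inherits(labels, "vol3d"), labels$kind == "label",
            inherits(severity, "severity_profile"))
  codes <- label_codes()
  lab <- labels$data
  up <- array(0, dim = dim(lab))
  up[lab == codes[["occipital"]] | lab == codes[["white_matter"]]] <- 1
  striatum <- lab %in% codes[c("caudate_left", "caudate_right",
                               "putamen_left", "putamen_right",
                               "vs_left", "vs_right")]
  tex <- generate_texture_field(dim(lab), labels$spacing_mm,
                                severity$texture_corr_mm,
                                severity$texture_amplitude, texture_seed,
                                norm_mask = striatum)
  decay <- (1 - severity$annual_decline)^year
  for (r in striatal_structures()) {
    for (side in c("left", "right")) {
      fac <- if (side == severity$affected_side) severity$asymmetry_factor else 1
      m <- lab == codes[[paste0(r, "_", side)]]
      up[m] <- severity$ratios[[r]] * fac * decay * (1 + tex[m])
    }
  }
  vol <- vol3d(up, labels$spacing_mm, "scalar")
  vol <- gaussian_blur3(vol, spec$psf_fwhm_mm)
  if (spec$noise_scale > 0) {
    withr::with_seed(seed + 1L, {
      vol$data <- vol$data *
        exp(stats::rnorm(length(vol$data), 0, spec$noise_scale))
    })
  }
  vol
}

#' Generate a T1-weighted-like volume on the 1 mm lattice
#'
#' Distinct tissue intensities (white matter ~ 250, striatal/occipital grey
#' ~ 150, background ~ 10) with mild blur and additive noise, so that
#' white-matter rescaling and striatum remapping have real work to do.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param labels optional precomputed T1-lattice label volume.
#' @return list with `t1w` (scalar [vol3d()]) and `labels` (label vol3d on
#'   the T1 lattice).
#' @export
generate_t1_volume <- function(spec, seed, labels = NULL) {
  if (is.null(labels)) labels <- generate_label_volume(spec, "t1")
  codes <- label_codes()
  lab <- labels$data
  t1 <- array(10, dim = dim(lab))
  t1[lab == codes[["white_matter"]]] <- 250
  gm <- lab %in% codes[c("caudate_left", "caudate_right", "putamen_left",
                         "putamen_right", "vs_left", "vs_right", "occipital")]
  t1[gm] <- 150
  vol <- vol3d(t1, labels$spacing_mm, "scalar")
  vol <- gaussian_blur3(vol, 2)
  withr::with_seed(seed, {
    vol$data <- vol$data + stats::rnorm(length(vol$data), 0, 4)
  })
  list(t1w = vol, labels = labels)
}

#' Generate the year-4 motor outcome of one subject
#'
#' Linear model in the year-1 motor score, its one-year change, and the two
#' imaging latents (texture amplitude, annual decline), plus Gaussian
#' noise, clipped to the 0–132 MDS-UPDRS-III scale. See [outcome_coeffs()].
#'
#' @param clinical a `clinical_record`.
#' @param latent a [severity_profile()].
#' @param coeffs an [outcome_coeffs()].
#' @param seed integer seed for the noise draw.
#' @return numeric score in [0, 132].
#' @export
generate_outcome <- function(clinical, latent, coeffs, seed) {
  stopifnot(inherits(coeffs, "outcome_coeffs"))
  mu <- coeffs$a0 +
    coeffs$a1 * clinical$updrs3_y1 +
    coeffs$a2 * (clinical$updrs3_y1 - clinical$updrs3_y0) +
    coeffs$a3 * latent$texture_amplitude +
    coeffs$a4 * latent$annual_decline
  eps <- if (coeffs$noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(1, 0, coeffs$noise_sd))
  } else 0
  min(132, max(0, mu + eps))
}

#' Generate a synthetic cohort
#'
#' Each subject carries a clinical record, latent severity profile, year-0
#' and year-1 SPECT volumes on one shared lattice (year-1 binding reduced by
#' the subject's annual decline, same texture field, fresh noise), and a
#' year-4 outcome. All randomness flows from `seed`.
#'
#' @param n cohort size (>= 2; leave-one-out evaluation is undefined below
#'   that).
#' @param spec a [phantom_spec()].
#' @param coeffs an [outcome_coeffs()].
#' @param seed integer master seed.
#' @param images generate SPECT volumes (`TRUE`) or latents/clinical only.
#' @param include_t1 also generate the per-cohort T1-like volume and its
#'   1 mm labels (shared anatomy, one volume for the cohort).
#' @return object of class `phantom_cohort`: list with `subjects` (list of
#'   `synthetic_subject`), `labels` (shared SPECT-lattice label volume),
#'   `spec`, `coeffs`, `seed`, and optionally `t1`.
#' @export
generate_cohort <- function(n, spec = phantom_spec(),
                            coeffs = outcome_coeffs(), seed = 1,
                            images = TRUE, include_t1 = FALSE) {
  if (n < 2) stop("n must be >= 2 (LOOCV undefined otherwise)")
  labels <- generate_label_volume(spec)
  sub_seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 10L, 4L * n), ncol = 4L))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- sample_clinical_record(sub_seeds[i, 1])
    sev <- sample_severity_profile(sub_seeds[i, 2])
    y0 <- y1 <- NULL
    if (images) {
      y0 <- generate_uptake_volume(labels, sev, spec, seed = sub_seeds[i, 3],
                                   year = 0, texture_seed = sub_seeds[i, 2])
      y1 <- generate_uptake_volume(labels, sev, spec,
                                   seed = sub_seeds[i, 3] + 7L,
                                   year = 1, texture_seed = sub_seeds[i, 2])
    }
    out <- generate_outcome(cl, sev, coeffs, sub_seeds[i, 4])
    subjects[[i]] <- structure(
      list(id = sprintf("S%03d", i), clinical = cl, latent = sev,
           spect_y0 = y0, spect_y1 = y1, outcome_updrs3_y4 = out),
      class = "synthetic_subject")
  }
  cohort <- structure(list(subjects = subjects, labels = labels, spec = spec,
                           coeffs = coeffs, seed = seed),
                      class = "phantom_cohort")
  if (include_t1) cohort$t1 <- generate_t1_volume(spec, seed + 1L)
  cohort
}

#' Redraw cohort outcomes under new coefficients or a new noise seed
#'
#' The images and clinical records are untouched; only the year-4 outcome
#' is regenerated. Used to study signal-on vs signal-off configurations and
#' outcome-noise replicates on one set of images.
#'
#' @param cohort a `phantom_cohort`.
#' @param coeffs an [outcome_coeffs()].
#' @param seed integer seed for the new noise draws.
#' @return the cohort with updated outcomes (and `coeffs`).
#' @export
regenerate_outcomes <- function(cohort, coeffs, seed) {
  eps_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 10L,
                                                 length(cohort$subjects)))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    cohort$subjects[[i]]$outcome_updrs3_y4 <-
      generate_outcome(s$clinical, s$latent, coeffs, eps_seeds[i])
  }
  cohort$coeffs <- coeffs
  cohort
}

#' Clinical + latent + outcome table of a cohort
#'
#' @param cohort a `phantom_cohort`.
#' @return data.frame, one row per subject.
#' @export
cohort_clinical_table <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject = s$id, age = s$clinical$age, sex = s$clinical$sex,
               dd_diag = s$clinical$dd_diag, dd_sympt = s$clinical$dd_sympt,
               updrs3_y0 = s$clinical$updrs3_y0,
               updrs3_y1 = s$clinical$updrs3_y1,
               moca_y0 = s$clinical$moca_y0, moca_y1 = s$clinical$moca_y1,
               affected_side = s$latent$affected_side,
               texture_amplitude = s$latent$texture_amplitude,
               annual_decline = s$latent$annual_decline,
               outcome_updrs3_y4 = s$outcome_updrs3_y4,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to disk (NIfTI volumes + CSV tables + manifest)
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(cohort$labels, file.path(dir, "labels.nii.gz"))
  rows <- lapply(cohort$subjects, function(s) {
    p0 <- file.path(dir, paste0(s$id, "_spect_y0.nii.gz"))
    p1 <- file.path(dir, paste0(s$id, "_spect_y1.nii.gz"))
    if (!is.null(s$spect_y0)) write_volume(s$spect_y0, p0)
    if (!is.null(s$spect_y1)) write_volume(s$spect_y1, p1)
    data.frame(subject = s$id, spect_y0 = basename(p0), spect_y1 = basename(p1),
               labels = "labels.nii.gz", stringsAsFactors = FALSE)
  })
  utils::write.csv(cohort_clinical_table(cohort),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
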