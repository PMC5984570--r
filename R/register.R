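#' Rigid transform (3 Euler angles + translation about a centre)
#'
#' Maps world-frame points of the fixed image into the moving image's world
#' frame: `x' = R (x - c) + c + t`, with `R = Rz(rz) Ry(ry) Rx(rx)`.
#'
#' @param angles rotation angles (radians) about x, y, z.
#' @param translation_mm translation (mm).
#' @param center_mm rotation centre (mm); by convention the fixed-image
#'   centroid, which in the package's volume-centred frame is the origin.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, length(translation_mm) == 3,
            length(center_mm) == 3,
            all(is.finite(c(angles, translation_mm, center_mm))))
  structure(list(angles = as.numeric(angles),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid> rot (deg): %s  trans (mm): %s  centre: %s\n",
              paste(format(x$angles * 180 / pi, digits = 3), collapse = ", "),
              paste(format(x$translation_mm, digits = 3), collapse = ", "),
              paste(format(x$center_mm, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#' @param tf a [rigid_transform()].
#' @return 3x3 orthonormal matrix.
#' @export
rotation_matrix <- function(tf) {
  a <- tf$angles
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 matrix.
#' @export
transform_points <- function(tf, pts) {
  R <- rotation_matrix(tf)
  ctr <- matrix(tf$center_mm, nrow(pts), 3, byrow = TRUE)
  (pts - ctr) %*% t(R) + ctr +
    matrix(tf$translation_mm, nrow(pts), 3, byrow = TRUE)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform` (same centre).
#' @export
invert_transform <- function(tf) {
  R <- rotation_matrix(tf)
  Ri <- t(R)
  # x = Ri (x' - c - t) + c  =>  angles from Ri, translation -Ri t
  ang <- euler_from_matrix(Ri)
  rigid_transform(ang, as.numeric(-Ri %*% tf$translation_mm), tf$center_mm)
}

# extract ZYX-convention Euler angles from an orthonormal matrix
euler_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

#' 4x4 homogeneous matrix rendering of a rigid transform
#' @param tf a [rigid_transform()].
#' @return 4x4 matrix.
#' @export
transform_matrix4 <- function(tf) {
  R <- rotation_matrix(tf)
  ctr <- tf$center_mm
  off <- as.numeric(ctr - R %*% ctr + tf$translation_mm)
  rbind(cbind(R, off), c(0, 0, 0, 1))
}

#' Serialize / deserialize a rigid transform as plain text
#'
#' Six parameters plus rotation centre, followed by the 4x4 matrix rendering
#' for interoperability.
#'
#' @param tf a [rigid_transform()].
#' @param path output/input path.
#' @return `write_transform`: `path` invisibly; `read_transform`: the
#'   transform.
#' @export
write_transform <- function(tf, path) {
  m4 <- transform_matrix4(tf)
  lines <- c("# rigid transform: angles (rad, x y z), translation (mm), centre (mm)",
             paste("angles:", paste(format(tf$angles, digits = 17), collapse = " ")),
             paste("translation_mm:", paste(format(tf$translation_mm, digits = 17), collapse = " ")),
             paste("center_mm:", paste(format(tf$center_mm, digits = 17), collapse = " ")),
             "# 4x4 homogeneous matrix (row-major)",
             apply(m4, 1, function(r) paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    as.numeric(strsplit(sub(paste0(key, ": *"), "", ln), " +")[[1]])
  }
  rigid_transform(get("angles"), get("translation_mm"), get("center_mm"))
}

#' Registration settings
#'
#' @param smoothing_fwhm_mm Gaussian smoothing applied to both images at
#'   every level (mm, default 7).
#' @param sampling_spacings_mm strictly decreasing coarse-to-fine average
#'   sample spacings (mm, default `c(4, 2)`).
#' @param histogram_bins joint-histogram bins per axis (default 64, min 8;
#'   coarser binning measurably biases small-rotation recovery).
#' @param max_iter maximum pattern-search sweeps per level.
#' @param step_mm,step_deg initial search steps (translation mm / rotation
#'   degrees).
#' @param tol_mm,tol_deg convergence steps below which the search stops.
#' @return object of class `registration_settings`.
#' @export
registration_settings <- function(smoothing_fwhm_mm = 7,
                                  sampling_spacings_mm = c(4, 2),
                                  histogram_bins = 64L,
                                  max_iter = 60L,
                                  step_mm = 4, step_deg = 4,
                                  tol_mm = 0.1, tol_deg = 0.1) {
  stopifnot(histogram_bins >= 8L,
            all(diff(sampling_spacings_mm) < 0),
            all(sampling_spacings_mm > 0))
  structure(list(smoothing_fwhm_mm = smoothing_fwhm_mm,
                 sampling_spacings_mm = sampling_spacings_mm,
                 histogram_bins = as.integer(histogram_bins),
                 max_iter = as.integer(max_iter),
                 step_mm = step_mm, step_deg = step_deg,
                 tol_mm = tol_mm, tol_deg = tol_deg),
            class = "registration_settings")
}

#' Trilinear interpolation of a volume at world-frame points
#' @param vol a scalar [vol3d()].
#' @param xyz n x 3 matrix of mm coordinates (volume-centred frame).
#' @return numeric vector; NA outside the grid.
#' @export
interpolate_trilinear <- function(vol, xyz) {
  d <- dim(vol$data)
  v <- world_to_voxel(xyz, d, vol$spacing_mm)
  i0 <- pmax(pmin(floor(v[, 1]), d[1] - 1L), 1L)
  j0 <- pmax(pmin(floor(v[, 2]), d[2] - 1L), 1L)
  k0 <- pmax(pmin(floor(v[, 3]), d[3] - 1L), 1L)
  fx <- v[, 1] - i0; fy <- v[, 2] - j0; fz <- v[, 3] - k0
  eps <- 1e-9
  ok <- v[, 1] >= 1 - eps & v[, 1] <= d[1] + eps &
    v[, 2] >= 1 - eps & v[, 2] <= d[2] + eps &
    v[, 3] >= 1 - eps & v[, 3] <= d[3] + eps
  out <- rep(NA_real_, nrow(xyz))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  at <- function(di, dj, dk) { # upper index clamped; its weight is 0 there
    vol$data[cbind(pmin(i0 + di, d[1]), pmin(j0 + dj, d[2]),
                   pmin(k0 + dk, d[3]))]
  }
  out[ok] <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out
}

# strided voxel-centre sample of the fixed grid at ~spacing_mm
sample_fixed_points <- function(fixed, spacing_mm) {
  d <- dim(fixed$data)
  stride <- pmax(1L, as.integer(round(spacing_mm / fixed$spacing_mm)))
  ii <- seq(1L, d[1], by = stride[1])
  jj <- seq(1L, d[2], by = stride[2])
  kk <- seq(1L, d[3], by = stride[3])
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  list(idx = idx,
       xyz = voxel_to_world(idx, d, fixed$spacing_mm),
       values = fixed$data[idx])
}

#' Normalized mutual information between two volumes under a transform
#'
#' Studholme's overlap-invariant form `NMI = (H(F) + H(M)) / H(F, M)`,
#' computed from a joint histogram over fixed-grid points sampled at the
#' requested spacing and mapped into the moving volume; range [1, 2].
#' A degenerate histogram (a single occupied bin in either marginal) yields
#' 1 with a warning.
#'
#' @param fixed,moving scalar [vol3d()] volumes.
#' @param transform a [rigid_transform()] mapping fixed-frame mm coordinates
#'   into the moving frame.
#' @param settings a [registration_settings()].
#' @param sampling_mm sample spacing (mm); default the finest level.
#' @param .sample optional precomputed fixed sample (internal reuse).
#' @return NMI value in [1, 2].
#' @export
normalized_mutual_information <- function(fixed, moving,
                                          transform = rigid_transform(),
                                          settings = registration_settings(),
                                          sampling_mm = min(settings$sampling_spacings_mm),
                                          .sample = NULL) {
  smp <- if (is.null(.sample)) sample_fixed_points(fixed, sampling_mm) else .sample
  mv <- interpolate_trilinear(moving, transform_points(transform, smp$xyz))
  ok <- !is.na(mv)
  if (sum(ok) < 4L) stop("transform leaves (almost) no overlap between volumes")
  nmi_from_samples(smp$values[ok], mv[ok], settings$histogram_bins)
}

nmi_from_samples <- function(a, b, bins) {
  cut_levels <- function(x) {
    r <- range(x)
    if (r[2] - r[1] <= 0) return(rep(1L, length(x)))
    pmin(bins, as.integer((x - r[1]) / (r[2] - r[1]) * bins) + 1L)
  }
  ia <- cut_levels(a); ib <- cut_levels(b)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint[joint > 0] / sum(joint)
  pj <- matrix(joint, bins, bins)  # rows: b, cols: a
  pa <- colSums(pj); pb <- rowSums(pj)
  if (sum(pa > 0) < 2L || sum(pb > 0) < 2L) {
    warning("degenerate histogram: NMI defined as 1")
    return(1)
  }
  ent <- function(q) { q <- q[q > 0] / sum(q); -sum(q * log2(q)) }
  (ent(pa) + ent(pb)) / ent(p)
}

#' Rigid registration by coarse-to-fine NMI maximization
#'
#' Gradient-free (pattern/coordinate search) maximization of normalized
#' mutual information. Both images are pre-smoothed with the settings'
#' Gaussian; the search runs at each sampling spacing from coarse to fine,
#' warm-starting each level with the previous optimum. Deterministic given
#' `init` and `settings`.
#'
#' @param fixed,moving scalar [vol3d()] volumes; the returned transform maps
#'   fixed-frame coordinates into the moving frame (i.e. resamples `moving`
#'   onto `fixed`).
#' @param settings a [registration_settings()].
#' @param init initial [rigid_transform()].
#' @return a `rigid_transform` with attributes `nmi` (final value),
#'   `converged` (logical), and `nmi_trace` (per-level optima).
#' @export
register_rigid <- function(fixed, moving, settings = registration_settings(),
                           init = rigid_transform()) {
  fs <- gaussian_blur3(fixed, settings$smoothing_fwhm_mm)
  ms <- gaussian_blur3(moving, settings$smoothing_fwhm_mm)
  par <- c(init$translation_mm, init$angles)
  ctr <- init$center_mm
  tf_of <- function(p) rigid_transform(p[4:6], p[1:3], ctr)
  converged <- TRUE
  trace <- numeric(0)
  sp_max <- max(settings$sampling_spacings_mm)
  for (sp in settings$sampling_spacings_mm) {
    smp <- sample_fixed_points(fs, sp)
    obj <- function(p) {
      tryCatch(normalized_mutual_information(fs, ms, tf_of(p), settings,
                                             .sample = smp),
               warning = function(w) 1, error = function(e) -Inf)
    }
    lev <- sp / sp_max  # finer levels start with proportionally finer steps
    res <- pattern_search(obj, par,
                          step = lev * c(rep(settings$step_mm, 3),
                                         rep(settings$step_deg * pi / 180, 3)),
                          tol = c(rep(settings$tol_mm, 3),
                                  rep(settings$tol_deg * pi / 180, 3)),
                          max_iter = settings$max_iter)
    par <- res$par
    converged <- converged && res$converged
    trace <- c(trace, res$value)
  }
  out <- tf_of(par)
  attr(out, "nmi") <- trace[length(trace)]
  attr(out, "converged") <- converged
  attr(out, "nmi_trace") <- trace
  out
}

# deterministic coordinate/pattern search maximizer with shrinking steps
pattern_search <- function(f, par, step, tol, max_iter) {
  best <- f(par)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (j in seq_along(par)) {
      for (s in c(step[j], -step[j])) {
        cand <- par
        cand[j] <- cand[j] + s
        v <- f(cand)
        if (v > best + 1e-10) {
          best <- v
          par <- cand
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) {
      if (all(step <= tol)) {
        return(list(par = par, value = best, converged = TRUE))
      }
      step <- step / 2
    }
  }
  list(par = par, value = best, converged = all(step <= tol))
}

#' Remap T1 intensities to weight striatal structures for registration
#'
#' Scales the T1 volume so that mean white-matter intensity equals 100,
#' then overwrites caudate + ventral-striatum voxels with 4000 and putamen
#' voxels with 1000, forcing the hyperintense SPECT striatum to align to
#' those structures.
#'
#' @param t1w scalar [vol3d()].
#' @param labels label [vol3d()] on the same lattice.
#' @return remapped scalar [vol3d()].
#' @export
remap_t1_intensities <- function(t1w, labels) {
  stopifnot_same_lattice(t1w, labels)
  codes <- label_codes()
  wm <- labels$data == codes[["white_matter"]]
  if (!any(wm)) stop("white-matter label is empty: intensity scale undefined")
  out <- t1w
  out$data <- t1w$data * (100 / mean(t1w$data[wm]))
  cvs <- labels$data %in% codes[c("caudate_left", "caudate_right",
                                  "vs_left", "vs_right")]
  put <- labels$data %in% codes[c("putamen_left", "putamen_right")]
  out$data[cvs] <- 4000
  out$data[put] <- 1000
  out
}

#' Two-stage SPECT-to-MRI registration
#'
#' Stage one registers the SPECT to the plain T1; stage two re-registers
#' against the striatum-remapped T1 (see [remap_t1_intensities()]), warm
#' started from stage one. Both stage transforms and their NMI values are
#' returned.
#'
#' @param spect moving SPECT scalar [vol3d()].
#' @param t1w fixed T1 scalar [vol3d()].
#' @param labels label [vol3d()] on the T1 lattice.
#' @param settings a [registration_settings()].
#' @param init initial transform for stage one.
#' @return list with `stage1`, `stage2` (rigid transforms), `nmi1`, `nmi2`
#'   (NMI against the remapped target under each transform), and `transform`
#'   (= stage2).
#' @export
two_stage_register <- function(spect, t1w, labels,
                               settings = registration_settings(),
                               init = rigid_transform()) {
  stage1 <- register_rigid(t1w, spect, settings, init)
  remapped <- remap_t1_intensities(t1w, labels)
  stage2 <- register_rigid(remapped, spect, settings, stage1)
  rs <- gaussian_blur3(remapped, settings$smoothing_fwhm_mm)
  ss <- gaussian_blur3(spect, settings$smoothing_fwhm_mm)
  list(stage1 = stage1, stage2 = stage2,
       nmi1 = normalized_mutual_information(rs, ss, stage1, settings),
       nmi2 = normalized_mutual_information(rs, ss, stage2, settings),
       transform = stage2)
}

#' Propagate labels onto a target lattice
#'
#' Nearest-neighbour resampling: each target voxel centre is mapped through
#' `transform` into the label volume's frame and takes the nearest label
#' (0 outside). Never invents a label; rejects if any ROI present in the
#' input maps entirely outside the target grid.
#'
#' @param labels label [vol3d()].
#' @param transform [rigid_transform()] mapping target-frame mm coordinates
#'   into the label volume's frame.
#' @param target [vol3d()] defining the output lattice.
#' @return label [vol3d()] on the target lattice.
#' @export
propagate_labels <- function(labels, transform, target) {
  d <- dim(target$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- transform_points(transform, voxel_to_world(idx, d, target$spacing_mm))
  v <- round(world_to_voxel(xyz, dim(labels$data), labels$spacing_mm))
  ld <- dim(labels$data)
  ok <- v[, 1] >= 1 & v[, 1] <= ld[1] & v[, 2] >= 1 & v[, 2] <= ld[2] &
    v[, 3] >= 1 & v[, 3] <= ld[3]
  out <- integer(nrow(idx))
  out[ok] <- labels$data[v[ok, , drop = FALSE]]
  res <- vol3d(array(out, dim = d), target$spacing_mm, "label")
  lost <- setdiff(unique(as.integer(labels$data)), unique(out))
  lost <- setdiff(lost, 0L)
  if (length(lost)) {
    nm <- names(label_codes())[match(lost, label_codes())]
    stop("ROI(s) mapped entirely outside the target grid: ",
         paste(nm, collapse = ", "))
  }
  res
}

#' Assign more/less-affected sides from putaminal uptake
#'
#' The hemisphere with the lower mean putaminal uptake is tagged (m)
#' more-affected — for the putamen, caudate and ventral striatum alike (the
#' putamen decides globally). Exact ties break to left = (m) with a warning.
#'
#' @param spect scalar [vol3d()] (SPECT lattice).
#' @param labels label [vol3d()] on the same lattice.
#' @return object of class `side_assignment`: named list per structure with
#'   `m` and `l` in `{left, right}`, plus attribute `putamen_means`.
#' @export
assign_affected_sides <- function(spect, labels) {
  stopifnot_same_lattice(spect, labels)
  codes <- label_codes()
  lm <- labels$data == codes[["putamen_left"]]
  rm_ <- labels$data == codes[["putamen_right"]]
  if (!any(lm) || !any(rm_)) stop("empty putamen mask on the SPECT lattice")
  mu_l <- mean(spect$data[lm])
  mu_r <- mean(spect$data[rm_])
  if (mu_l == mu_r) {
    warning("putaminal means exactly equal; tie broken to left = (m)")
    m_side <- "left"
  } else {
    m_side <- if (mu_l < mu_r) "left" else "right"
  }
  l_side <- setdiff(c("left", "right"), m_side)
  out <- stats::setNames(
    lapply(striatal_structures(), function(s) list(m = m_side, l = l_side)),
    striatal_structures())
  attr(out, "putamen_means") <- c(left = mu_l, right = mu_r)
  class(out) <- "side_assignment"
  out
}
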