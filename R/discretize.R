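#' Normalize an uptake volume to the occipital reference
#'
#' Divides every voxel by the mean uptake inside the occipital mask, so ROI
#' means become binding-ratio-like quantities (occipital = 1).
#'
#' @param spect scalar [vol3d()].
#' @param occipital_mask logical 3D array on the same lattice.
#' @return normalized scalar [vol3d()].
#' @export
normalize_to_reference <- function(spect, occipital_mask) {
  stopifnot(identical(dim(spect$data), dim(occipital_mask)))
  mu <- mean(spect$data[occipital_mask])
  if (!is.finite(mu) || mu <= 0) {
    stop("occipital reference mean is non-positive; cannot normalize")
  }
  out <- spect
  out$data <- spect$data / mu
  out
}

#' Fixed-bin-count gray-level discretization
#'
#' Quantizes in-mask intensities into `n_bins` equal-width levels between
#' the in-mask minimum and maximum (level `b` covers
#' `[min + (b-1) w, min + b w)`, the top edge closed). A constant region
#' maps entirely to level 1. By construction the result is invariant under
#' monotone affine rescaling of the input intensities.
#'
#' @param volume scalar [vol3d()] or 3D array.
#' @param mask logical 3D array.
#' @param n_bins number of gray levels (>= 2).
#' @return object of class `graylevel_volume`: list with `levels` (integer
#'   3D array, NA outside the mask), `n_bins`, `range` (in-mask min/max).
#' @export
discretize <- function(volume, mask, n_bins = 64L) {
  arr <- if (inherits(volume, "vol3d")) volume$data else volume
  stopifnot(identical(dim(arr), dim(mask)), n_bins >= 2L)
  if (!any(mask)) stop("mask is empty")
  v <- arr[mask]
  r <- range(v)
  lv <- array(NA_integer_, dim = dim(arr))
  if (r[2] - r[1] <= 0) {
    lv[mask] <- 1L
  } else {
    lv[mask] <- pmin(as.integer(n_bins),
                     as.integer((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L)
  }
  structure(list(levels = lv, n_bins = as.integer(n_bins), range = r),
            class = "graylevel_volume")
}

#' The 13 unique 3D unit-distance offset directions
#' @return 13 x 3 integer matrix (one of each +/- pair).
#' @export
unit_offsets_13 <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}

# 26-connectivity neighbourhood offsets
offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
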