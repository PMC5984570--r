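#' First-order intensity features
#'
#' 13 features of the in-mask intensity distribution. "SUV" nomenclature is
#' retained from PET/SPECT convention but on occipital-normalized input the
#' values are uptake ratios, not true standardized uptake values. SUVpeak is
#' the mean over the 1 cm^3-equivalent spherical neighbourhood (radius
#' ~6.2 mm) centred on the hottest voxel, restricted to the in-mask voxels
#' available there. Skewness and kurtosis use population moments, kurtosis
#' is excess.
#'
#' @param volume scalar [vol3d()] or 3D array.
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing (taken from `volume` when it is a
#'   [vol3d()]).
#' @param n_bins histogram bins for the intensity-entropy feature.
#' @return named numeric vector of 13 values.
#' @export
first_order_features <- function(volume, mask, spacing_mm = NULL,
                                 n_bins = 64L) {
  arr <- if (inherits(volume, "vol3d")) volume$data else volume
  sp <- if (inherits(volume, "vol3d")) volume$spacing_mm else
    rep(as.numeric(spacing_mm), length.out = 3)
  stopifnot(identical(dim(arr), dim(mask)))
  if (!any(mask)) stop("mask is empty")
  v <- arr[mask]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 - 3 else 0
  gl <- discretize(arr, mask, n_bins)
  p <- tabulate(gl$levels[mask], nbins = n_bins)
  p <- p / sum(p)
  c(fo_suv_max = max(v),
    fo_suv_mean = mu,
    fo_suv_peak = suv_peak(arr, mask, sp),
    fo_min = min(v),
    fo_median = stats::median(v),
    fo_sd = sdv,
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_energy = sum(v^2),
    fo_entropy = ent2(p),
    fo_cov = if (mu != 0) sdv / mu else 0,
    fo_p10 = unname(stats::quantile(v, 0.10)),
    fo_p90 = unname(stats::quantile(v, 0.90)))
}

suv_peak <- function(arr, mask, spacing_mm) {
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)  # 1 cm^3-equivalent sphere radius
  idx <- which(mask)
  hot <- idx[which.max(arr[idx])]
  d <- dim(arr)
  hotc <- arrayInd(hot, d)[1, ]
  rad <- pmin(ceiling(r_mm / spacing_mm), d - 1)
  rng <- lapply(1:3, function(a) {
    max(1L, hotc[a] - rad[a]):min(d[a], hotc[a] + rad[a])
  })
  sub <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  dist2 <- ((sub[, 1] - hotc[1]) * spacing_mm[1])^2 +
    ((sub[, 2] - hotc[2]) * spacing_mm[2])^2 +
    ((sub[, 3] - hotc[3]) * spacing_mm[3])^2
  sub <- sub[dist2 <= r_mm^2, , drop = FALSE]
  inmask <- mask[sub]
  mean(arr[sub[inmask, , drop = FALSE]])
}
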