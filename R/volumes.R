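#' 3D scalar or label volume
#'
#' Lightweight container for a 3D image: a numeric (scalar) or integer
#' (label) array plus isotropic-or-anisotropic voxel spacing in mm and an
#' anatomical orientation tag. All package geometry is expressed in a
#' volume-centred "world" frame: voxel centre i (1-based) along an axis of
#' n voxels with spacing d sits at (i - (n + 1) / 2) * d mm, so the origin
#' is the grid centre and the midsagittal plane is x = 0.
#'
#' @param data 3D array.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param kind `"scalar"` or `"label"`. Label volumes are stored as integer.
#' @param orientation orientation tag (default `"RAS"`; informational).
#' @return an object of class `vol3d`.
#' @export
vol3d <- function(data, spacing_mm, kind = c("scalar", "label"),
                  orientation = "RAS") {
  kind <- match.arg(kind)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 positive finite values")
  }
  if (kind == "label") storage.mode(data) <- "integer"
  structure(list(data = data, spacing_mm = spacing_mm, kind = kind,
                 orientation = orientation),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d %s> %s voxels @ %s mm [%s]\n", x$kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' World coordinates of voxel centres along each axis
#'
#' @param vol a [vol3d()].
#' @return list of three numeric vectors (mm, volume-centred frame).
#' @keywords internal
axis_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) (seq_len(d[a]) - (d[a] + 1) / 2) * vol$spacing_mm[a])
}

#' Voxel index grid -> world mm coordinates (n x 3 matrix)
#' @keywords internal
voxel_to_world <- function(idx, dim, spacing_mm) {
  sweep(sweep(idx, 2, (dim + 1) / 2, "-"), 2, spacing_mm, "*")
}

#' World mm -> fractional voxel index
#' @keywords internal
world_to_voxel <- function(xyz, dim, spacing_mm) {
  sweep(sweep(xyz, 2, spacing_mm, "/"), 2, (dim + 1) / 2, "+")
}

stopifnot_same_lattice <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9) {
    stop("volumes are not on the same lattice (dims/spacing differ)")
  }
  invisible(TRUE)
}

#' Separable 3D Gaussian blur
#'
#' Applies an FWHM-specified Gaussian along each axis (kernel truncated at
#' 4 sigma, renormalised; edges use zero padding implicit in truncated
#' renormalised rows so mass is preserved at boundaries).
#'
#' @param vol a scalar [vol3d()] or plain 3D array (then `spacing_mm` is
#'   required).
#' @param fwhm_mm Gaussian full-width-at-half-maximum in mm; 0 is a no-op.
#' @param spacing_mm voxel spacing when `vol` is a bare array.
#' @return same type as the input.
#' @export
gaussian_blur3 <- function(vol, fwhm_mm, spacing_mm = NULL) {
  is_vol <- inherits(vol, "vol3d")
  arr <- if (is_vol) vol$data else vol
  sp <- if (is_vol) vol$spacing_mm else rep(as.numeric(spacing_mm), length.out = 3)
  if (fwhm_mm <= 0) return(vol)
  sigma_vox <- (fwhm_mm / 2.3548) / sp
  d <- dim(arr)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 1e-6) next
    K <- blur_band_matrix(d[a], s)
    arr <- apply_along_axis(arr, a, K)
  }
  if (is_vol) vol3d(arr, sp, "scalar", vol$orientation) else arr
}

# dense n x n convolution matrix with truncated, row-renormalised Gaussian
blur_band_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  idx <- seq_len(n)
  D <- outer(idx, idx, "-")
  K <- exp(-D^2 / (2 * sigma_vox^2))
  K[abs(D) > r] <- 0
  K / rowSums(K)
}

# multiply matrix K along axis a of 3D array
apply_along_axis <- function(arr, a, K) {
  d <- dim(arr)
  perm <- c(a, setdiff(1:3, a))
  m <- matrix(aperm(arr, perm), nrow = d[a])
  m <- K %*% m
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind `"scalar"` or `"label"`; label data are rounded to integer.
#' @return a [vol3d()].
#' @export
read_volume <- function(path, kind = c("scalar", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("expected a 3D volume in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (kind == "label") arr <- round(arr)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop RNifti attributes
  vol3d(arr, sp, kind)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [vol3d()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol3d"))
  dat <- vol$data
  if (vol$kind == "label") storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Mask statistics helper
#' @keywords internal
mask_mean <- function(vol, mask) mean(vol$data[mask])
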