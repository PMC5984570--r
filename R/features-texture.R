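# Texture-matrix feature families: GLCM, GLSZM, GLRLM.
# Conventions used throughout: gray levels are 1..Ng (Ng = bin count of the
# discretization), entropies are base 2 with 0 log 0 = 0, and GLCM/GLRLM
# counts are pooled (symmetrised) over the 13 unique unit offset directions
# before normalization.

ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' Gray-level co-occurrence matrix
#'
#' Counts of level pairs at the given voxel offsets, restricted to in-mask
#' voxels, symmetrised (each pair counted in both orders) and pooled over
#' all offsets.
#'
#' @param gl a [discretize()] result.
#' @param offsets integer matrix of voxel offsets (rows), default the 13
#'   unique 3D unit directions.
#' @return Ng x Ng count matrix (Ng = levels actually indexable, `n_bins`).
#' @export
glcm_matrix <- function(gl, offsets = unit_offsets_13()) {
  lv <- gl$levels
  ng <- gl$n_bins
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    lo <- pmax(1L, 1L - o)
    hi <- pmin(d, d - o)
    if (any(hi < lo)) next
    sr <- lapply(1:3, function(a) lo[a]:hi[a])
    A <- lv[sr[[1]], sr[[2]], sr[[3]], drop = FALSE]
    B <- lv[sr[[1]] + o[1], sr[[2]] + o[2], sr[[3]] + o[3], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    tab <- tabulate((A[ok] - 1L) * ng + B[ok], nbins = ng * ng)
    Mo <- matrix(tab, ng, ng)  # row = B level, col = A level
    M <- M + Mo + t(Mo)
  }
  M
}

#' GLCM (Haralick-family) features
#'
#' 26 features from the pooled, symmetric, normalized co-occurrence matrix,
#' including difference entropy (the entropy of the |i - j| marginal),
#' contrast, correlation, the information measures of correlation, and the
#' maximal correlation coefficient. Degenerate conventions: a single
#' occupied gray level gives zero contrast/entropies, correlation 0 and
#' MCC 1.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 26 values.
#' @export
glcm_features <- function(gl, offsets = unit_offsets_13()) {
  if (sum(!is.na(gl$levels)) < 2L) {
    # single-voxel mask: defined-by-convention values
    warning("GLCM on a <2-voxel mask: features defined by convention")
    M <- matrix(0, gl$n_bins, gl$n_bins)
    M[gl$levels[!is.na(gl$levels)][1], gl$levels[!is.na(gl$levels)][1]] <- 1
  } else {
    M <- glcm_matrix(gl, offsets)
  }
  glcm_features_from_matrix(M)
}

#' @rdname glcm_features
#' @param M a (possibly unnormalized) symmetric GLCM count matrix.
#' @export
glcm_features_from_matrix <- function(M) {
  if (sum(M) == 0) M[1, 1] <- 1
  P <- M / sum(M)
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  da <- sum(k_diff * p_diff)
  sa <- sum(k_sum * p_sum)
  hxy <- ent2(P)
  hx <- ent2(px); hy <- ent2(py)
  pxpy <- outer(px, py)
  nz <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[nz] * log2(pxpy[nz]))
  nz2 <- pxpy > 0
  hxy2 <- -sum(pxpy[nz2] * log2(pxpy[nz2]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sdx > 0 && sdy > 0) {
    (sum(i * j * P) - mux * muy) / (sdx * sdy)
  } else 0
  c(
    glcm_joint_max = max(P),
    glcm_joint_average = mux,
    glcm_joint_variance = sum((i - mux)^2 * P),
    glcm_joint_entropy = hxy,
    glcm_diff_average = da,
    glcm_diff_variance = sum((k_diff - da)^2 * p_diff),
    glcm_diff_entropy = ent2(p_diff),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((k_sum - sa)^2 * p_sum),
    glcm_sum_entropy = ent2(p_sum),
    glcm_energy = sum(P^2),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_inverse_difference = sum(P / (1 + abs(i - j))),
    glcm_inverse_difference_norm = sum(P / (1 + abs(i - j) / ng)),
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idm_norm = sum(P / (1 + ((i - j) / ng)^2)),
    glcm_inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_tendency = sum((i + j - mux - muy)^2 * P),
    glcm_cluster_shade = sum((i + j - mux - muy)^3 * P),
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * P),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_mcc = glcm_mcc(P, px, py)
  )
}

glcm_mcc <- function(P, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  Pk <- P[keep, keep, drop = FALSE]
  pxk <- px[keep]; pyk <- py[keep]
  # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
  W <- sweep(Pk, 2, pyk, "/")
  Q <- sweep(Pk %*% t(W), 1, pxk, "/")
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(min(1, max(0, ev[2])))
}

# --- GLSZM ---------------------------------------------------------------

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level within the mask.
#'
#' @param gl a [discretize()] result.
#' @return list with `counts` (data.frame level, size, n) and `n_zones`.
#' @export
glszm_matrix <- function(gl) {
  lv <- gl$levels
  d <- dim(lv)
  idx <- which(!is.na(lv))
  visited <- array(FALSE, dim = d)
  offs <- offsets_26()
  zones_level <- integer(0)
  zones_size <- integer(0)
  ijk <- arrayInd(idx, d)
  pos_of <- array(NA_integer_, dim = d)
  pos_of[idx] <- seq_along(idx)
  for (p in seq_along(idx)) {
    v <- idx[p]
    if (visited[v]) next
    level <- lv[v]
    stack <- p
    visited[v] <- TRUE
    size <- 0L
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      base <- ijk[q, ]
      nb <- sweep(offs, 2, base, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      cand <- lin[!visited[lin] & !is.na(lv[lin]) & lv[lin] == level]
      if (length(cand)) {
        visited[cand] <- TRUE
        stack <- c(stack, pos_of[cand])
      }
    }
    zones_level <- c(zones_level, level)
    zones_size <- c(zones_size, size)
  }
  counts <- stats::aggregate(n ~ level + size,
                             data = data.frame(level = zones_level,
                                               size = zones_size, n = 1L),
                             FUN = sum)
  list(counts = counts, n_zones = length(zones_level),
       n_voxels = length(idx))
}

#' GLSZM features
#'
#' 16 zone features, including small-zone high-gray-level emphasis
#' `SZHGE = (1/Nz) sum n(i,j) i^2 / j^2` and large-zone low-gray-level
#' emphasis `LZLGE = (1/Nz) sum n(i,j) j^2 / i^2` (i = gray level, j = zone
#' size, Nz = number of zones).
#'
#' @param gl a [discretize()] result.
#' @return named numeric vector of 16 values.
#' @export
glszm_features <- function(gl) {
  z <- glszm_matrix(gl)
  szm_style_features(z$counts$level, z$counts$size, z$counts$n,
                     z$n_zones, z$n_voxels, prefix = "glszm",
                     size_name = "zs", pct_name = "glszm_zone_percentage",
                     pct_denom = z$n_voxels)
}

# shared formula engine for zone (GLSZM) and run (GLRLM) matrices:
# rows (i = level, j = size-or-length, n = count), N = total zones/runs
szm_style_features <- function(i, j, n, N, n_vox, prefix, size_name,
                               pct_name, pct_denom) {
  p <- n / N
  pg <- tapply(n, i, sum)      # per-level totals
  ps <- tapply(n, j, sum)      # per-size totals
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  out <- c(
    sum(n / j^2) / N,                       # small emphasis
    sum(n * j^2) / N,                       # large emphasis
    sum(pg^2) / N,                          # gray-level nonuniformity
    sum(pg^2) / N^2,                        # ... normalized
    sum(ps^2) / N,                          # size nonuniformity
    sum(ps^2) / N^2,                        # ... normalized
    N / pct_denom,                          # zone/run percentage
    sum(n / i^2) / N,                       # low gray emphasis
    sum(n * i^2) / N,                       # high gray emphasis
    sum(n / (i^2 * j^2)) / N,               # small + low
    sum(n * i^2 / j^2) / N,                 # small + high (SZHGE)
    sum(n * j^2 / i^2) / N,                 # large + low (LZLGE)
    sum(n * i^2 * j^2) / N,                 # large + high
    sum(p * (i - mu_i)^2),                  # gray-level variance
    sum(p * (j - mu_j)^2),                  # size variance
    ent2(p)                                 # size-zone entropy
  )
  names(out) <- c(paste0(prefix, c("_sze", "_lze", "_gln", "_gln_norm",
                                   paste0("_", size_name, "n"),
                                   paste0("_", size_name, "n_norm"))),
                  pct_name,
                  paste0(prefix, c("_lgze", "_hgze", "_szlge", "_szhge",
                                   "_lzlge", "_lzhge", "_gl_variance",
                                   paste0("_", size_name, "_variance"),
                                   paste0("_", size_name, "_entropy"))))
  out
}

# --- GLRLM ---------------------------------------------------------------

#' Gray-level run-length matrix
#'
#' Maximal collinear same-level runs within the mask, pooled over the 13
#' unique 3D unit directions (runs break at mask holes).
#'
#' @param gl a [discretize()] result.
#' @param directions integer matrix of directions, default
#'   [unit_offsets_13()].
#' @return list with `counts` (data.frame level, length, n), `n_runs`,
#'   `n_voxels`, `n_directions`.
#' @export
glrlm_matrix <- function(gl, directions = unit_offsets_13()) {
  lv <- gl$levels
  d <- dim(lv)
  idx <- which(!is.na(lv))
  ijk <- arrayInd(idx, d)
  run_level <- integer(0)
  run_len <- integer(0)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    prev <- sweep(ijk, 2, o, "-")
    inb <- prev[, 1] >= 1 & prev[, 1] <= d[1] & prev[, 2] >= 1 &
      prev[, 2] <= d[2] & prev[, 3] >= 1 & prev[, 3] <= d[3]
    lin_prev <- prev[, 1] + (prev[, 2] - 1L) * d[1] +
      (prev[, 3] - 1L) * d[1] * d[2]
    is_start <- !inb
    is_start[inb] <- is.na(lv[lin_prev[inb]])
    starts <- ijk[is_start, , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      cur <- starts[s, ]
      seqlv <- integer(0)
      repeat {
        if (any(cur < 1) || any(cur > d)) break
        val <- lv[cur[1], cur[2], cur[3]]
        if (is.na(val)) break
        seqlv <- c(seqlv, val)
        cur <- cur + o
      }
      rl <- rle(seqlv)
      run_level <- c(run_level, rl$values)
      run_len <- c(run_len, rl$lengths)
    }
  }
  counts <- stats::aggregate(n ~ level + length,
                             data = data.frame(level = run_level,
                                               length = run_len, n = 1L),
                             FUN = sum)
  list(counts = counts, n_runs = sum(counts$n), n_voxels = length(idx),
       n_directions = nrow(directions))
}

#' GLRLM features
#'
#' 15 run-length features (short/long run emphasis, gray-level and
#' run-length nonuniformity, run percentage, the gray-level-weighted
#' emphases, variances, run entropy) from runs pooled over the 13
#' directions. Run percentage divides by `voxels x directions` so a single
#' axis-direction call on an n-voxel line gives `1/n`.
#'
#' @inheritParams glrlm_matrix
#' @return named numeric vector of 15 values.
#' @export
glrlm_features <- function(gl, directions = unit_offsets_13()) {
  m <- glrlm_matrix(gl, directions)
  x <- szm_style_features(m$counts$level, m$counts$length, m$counts$n,
                          m$n_runs, m$n_voxels, prefix = "glrlm",
                          size_name = "rl", pct_name = "glrlm_rp",
                          pct_denom = m$n_voxels * m$n_directions)
  # rename to run-length vocabulary and drop the GLSZM-specific aliases
  names(x) <- c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_gln_norm",
                "glrlm_rln", "glrlm_rln_norm", "glrlm_rp", "glrlm_lgre",
                "glrlm_hgre", "glrlm_srlge", "glrlm_srhge", "glrlm_lrlge",
                "glrlm_lrhge", "glrlm_gl_variance", "glrlm_rl_variance",
                "glrlm_run_entropy")
  # registry keeps 15 run-length features: gln_norm is not part of the set
  x[c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_rln_norm",
      "glrlm_rp", "glrlm_lgre", "glrlm_hgre", "glrlm_srlge", "glrlm_srhge",
      "glrlm_lrlge", "glrlm_lrhge", "glrlm_gl_variance",
      "glrlm_rl_variance", "glrlm_run_entropy")]
}
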