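# Independent brute-force enumerators for the texture families.
# These deliberately share no code with the package implementation: pairs,
# zones and runs are enumerated voxel by voxel with plain loops, and the
# feature formulas are written out directly from their definitions.

o_ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

oracle_glcm_matrix <- function(levels, ng, offsets) {
  d <- dim(levels)
  M <- matrix(0, ng, ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      a <- levels[i, j, k]
      if (is.na(a)) next
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      b <- levels[ii, jj, kk]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M
}

oracle_glcm_features <- function(levels, ng, offsets) {
  M <- oracle_glcm_matrix(levels, ng, offsets)
  if (sum(M) == 0) M[1, 1] <- 1
  P <- M / sum(M)
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)  # |i-j| in 0..ng-1, i+j in 2..2ng
  s <- list(jmax = 0, jvar = 0, jent = 0, asm = 0, contrast = 0, dissim = 0,
            id = 0, idn = 0, idm = 0, idmn = 0, invvar = 0, autoc = 0,
            ct = 0, cs = 0, cp = 0, sumij = 0)
  for (i in lev) for (j in lev) {
    p <- P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j - 1] <- ps[i + j - 1] + p
    s$jvar <- s$jvar + (i - mux)^2 * p
    s$asm <- s$asm + p^2
    s$contrast <- s$contrast + (i - j)^2 * p
    s$dissim <- s$dissim + abs(i - j) * p
    s$id <- s$id + p / (1 + abs(i - j))
    s$idn <- s$idn + p / (1 + abs(i - j) / ng)
    s$idm <- s$idm + p / (1 + (i - j)^2)
    s$idmn <- s$idmn + p / (1 + ((i - j) / ng)^2)
    if (i != j) s$invvar <- s$invvar + p / (i - j)^2
    s$autoc <- s$autoc + i * j * p
    s$ct <- s$ct + (i + j - mux - muy)^2 * p
    s$cs <- s$cs + (i + j - mux - muy)^3 * p
    s$cp <- s$cp + (i + j - mux - muy)^4 * p
    s$sumij <- s$sumij + i * j * p
  }
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  da <- sum(kd * pd); sa <- sum(ks * ps)
  hxy <- o_ent(P); hx <- o_ent(px); hy <- o_ent(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in lev) for (j in lev) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  keep <- which(px > 0)
  mcc <- if (length(keep) < 2) 1 else {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      Q[a, b] <- sum(P[keep[a], keep] * P[keep[b], keep] /
                       (px[keep[a]] * py[keep]))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(1, max(0, ev[2])))
  }
  c(glcm_joint_max = max(P),
    glcm_joint_average = mux,
    glcm_joint_variance = s$jvar,
    glcm_joint_entropy = hxy,
    glcm_diff_average = da,
    glcm_diff_variance = sum((kd - da)^2 * pd),
    glcm_diff_entropy = o_ent(pd),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((ks - sa)^2 * ps),
    glcm_sum_entropy = o_ent(ps),
    glcm_energy = s$asm,
    glcm_contrast = s$contrast,
    glcm_dissimilarity = s$dissim,
    glcm_inverse_difference = s$id,
    glcm_inverse_difference_norm = s$idn,
    glcm_idm = s$idm,
    glcm_idm_norm = s$idmn,
    glcm_inverse_variance = s$invvar,
    glcm_correlation = if (sdx > 0 && sdy > 0)
      (s$sumij - mux * muy) / (sdx * sdy) else 0,
    glcm_autocorrelation = s$autoc,
    glcm_cluster_tendency = s$ct,
    glcm_cluster_shade = s$cs,
    glcm_cluster_prominence = s$cp,
    glcm_imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    glcm_imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    glcm_mcc = mcc)
}

# zones by breadth-first flood fill over 26-neighbourhoods
oracle_zones <- function(levels) {
  d <- dim(levels)
  zone <- array(NA_integer_, dim = d)
  nz <- 0L
  coords <- which(!is.na(levels), arr.ind = TRUE)
  for (row in seq_len(nrow(coords))) {
    v <- coords[row, ]
    if (!is.na(zone[v[1], v[2], v[3]])) next
    nz <- nz + 1L
    frontier <- list(v)
    zone[v[1], v[2], v[3]] <- nz
    lev <- levels[v[1], v[2], v[3]]
    while (length(frontier)) {
      nxt <- list()
      for (p in frontier) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          q <- p + c(dx, dy, dz)
          if (any(q < 1) || any(q > d)) next
          if (is.na(levels[q[1], q[2], q[3]])) next
          if (levels[q[1], q[2], q[3]] != lev) next
          if (!is.na(zone[q[1], q[2], q[3]])) next
          zone[q[1], q[2], q[3]] <- nz
          nxt[[length(nxt) + 1L]] <- q
        }
      }
      frontier <- nxt
    }
  }
  sizes <- tabulate(zone[!is.na(zone)], nbins = nz)
  lv <- vapply(seq_len(nz), function(z) levels[which(zone == z)[1]], 1L)
  data.frame(level = lv, size = sizes)
}

# zone/run feature formulas written out directly; i = level, j = size/length
oracle_ij_features <- function(i, j, N, n_vox, pct_denom) {
  pg <- tapply(rep(1, length(i)), i, sum)
  psz <- tapply(rep(1, length(j)), j, sum)
  mu_i <- mean(i); mu_j <- mean(j)
  c(small = mean(1 / j^2),
    large = mean(j^2),
    gln = sum(pg^2) / N,
    gln_norm = sum(pg^2) / N^2,
    szn = sum(psz^2) / N,
    szn_norm = sum(psz^2) / N^2,
    pct = N / pct_denom,
    low = mean(1 / i^2),
    high = mean(i^2),
    small_low = mean(1 / (i^2 * j^2)),
    small_high = mean(i^2 / j^2),
    large_low = mean(j^2 / i^2),
    large_high = mean(i^2 * j^2),
    gl_var = mean((i - mu_i)^2),
    sz_var = mean((j - mu_j)^2),
    ent = {
      tab <- table(paste(i, j))
      o_ent(as.numeric(tab) / N)
    })
}

oracle_glszm_features <- function(levels) {
  z <- oracle_zones(levels)
  x <- oracle_ij_features(z$level, z$size, nrow(z), sum(!is.na(levels)),
                          pct_denom = sum(!is.na(levels)))
  stats::setNames(
    x[c("small", "large", "gln", "gln_norm", "szn", "szn_norm", "pct",
        "low", "high", "small_low", "small_high", "large_low",
        "large_high", "gl_var", "sz_var", "ent")],
    c("glszm_sze", "glszm_lze", "glszm_gln", "glszm_gln_norm", "glszm_zsn",
      "glszm_zsn_norm", "glszm_zone_percentage", "glszm_lgze", "glszm_hgze",
      "glszm_szlge", "glszm_szhge", "glszm_lzlge", "glszm_lzhge",
      "glszm_gl_variance", "glszm_zs_variance", "glszm_zs_entropy"))
}

# plain run enumeration: walk every maximal line in every direction
oracle_runs <- function(levels, directions) {
  d <- dim(levels)
  out_level <- integer(0)
  out_len <- integer(0)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (is.na(levels[i, j, k])) next
      p <- c(i, j, k) - o
      started <- any(p < 1) || any(p > d) || is.na(levels[p[1], p[2], p[3]])
      if (!started) next
      cur <- c(i, j, k)
      seqlv <- integer(0)
      while (all(cur >= 1) && all(cur <= d) &&
             !is.na(levels[cur[1], cur[2], cur[3]])) {
        seqlv <- c(seqlv, levels[cur[1], cur[2], cur[3]])
        cur <- cur + o
      }
      rl <- rle(seqlv)
      out_level <- c(out_level, rl$values)
      out_len <- c(out_len, rl$lengths)
    }
  }
  data.frame(level = out_level, length = out_len)
}

oracle_glrlm_features <- function(levels, directions) {
  runs <- oracle_runs(levels, directions)
  x <- oracle_ij_features(runs$level, runs$length, nrow(runs),
                          sum(!is.na(levels)),
                          pct_denom = sum(!is.na(levels)) * nrow(directions))
  stats::setNames(
    x[c("small", "large", "gln", "szn", "szn_norm", "pct", "low", "high",
        "small_low", "small_high", "large_low", "large_high", "gl_var",
        "sz_var", "ent")],
    c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_rln_norm",
      "glrlm_rp", "glrlm_lgre", "glrlm_hgre", "glrlm_srlge", "glrlm_srhge",
      "glrlm_lrlge", "glrlm_lrhge", "glrlm_gl_variance",
      "glrlm_rl_variance", "glrlm_run_entropy"))
}

# random small gray-level toy: array of levels with NA holes
random_gl_toy <- function(seed, max_dim = 6L, ng = 4L) {
  withr::with_seed(seed, {
    d <- sample(2:max_dim, 3, replace = TRUE)
    lv <- array(sample.int(ng, prod(d), replace = TRUE), dim = d)
    holes <- stats::runif(prod(d)) < 0.2
    lv[holes] <- NA_integer_
    if (all(is.na(lv))) lv[1] <- 1L
    structure(list(levels = lv, n_bins = as.integer(ng), range = c(0, 1)),
              class = "graylevel_volume")
  })
}

# tiny helper used by several suites: a graylevel_volume from an array
gl_of <- function(arr, ng) {
  structure(list(levels = array(as.integer(arr), dim = dim(arr)),
                 n_bins = as.integer(ng), range = c(0, 1)),
            class = "graylevel_volume")
}
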