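# Gray-level texture matrices and their features, computed on the
# discretized (resegmented) lesion. Conventions: co-occurrence and runs use
# the 13 unique 3D directions at distance 1 voxel with unweighted averaging
# of the per-direction feature values; zones, dependence and gray-tone
# differences use the 26-neighborhood. Texture neighborhoods ignore voxel
# anisotropy (grid-step neighbors), per common practice when features are
# computed at the original voxel sizes.

# ---------------------------------------------------------------- GLCM --

#' @noRd
glcm_matrix <- function(levels, d, n_levels) {
  i <- levels
  j <- shift_array(levels, d)
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) return(NULL)
  counts <- matrix(
    tabulate((j[ok] - 1L) * n_levels + i[ok], nbins = n_levels^2),
    n_levels, n_levels
  )
  sym <- counts + t(counts)
  sym / sum(sym)
}

#' @noRd
glcm_features_from_matrix <- function(P, n_levels) {
  Ng <- n_levels
  iv <- seq_len(Ng)
  I <- matrix(iv, Ng, Ng)
  J <- t(I)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(px * iv)
  muy <- sum(py * iv)
  sigx <- sqrt(sum(px * (iv - mux)^2))
  sigy <- sqrt(sum(py * (iv - muy)^2))

  # diagonal-band distributions
  dif <- abs(I - J)
  pxy_diff <- vapply(0:(Ng - 1), function(k) sum(P[dif == k]), numeric(1))
  sm <- I + J
  pxy_sum <- vapply(2:(2 * Ng), function(k) sum(P[sm == k]), numeric(1))
  kd <- 0:(Ng - 1)
  ks <- 2:(2 * Ng)

  auto <- sum(P * I * J)
  contrast <- sum(P * (I - J)^2)
  corr <- if (sigx * sigy > 0) (auto - mux * muy) / (sigx * sigy) else 1
  da <- sum(kd * pxy_diff)
  HXY <- -sum(P * log2e(P))
  HX <- -sum(px * log2e(px))
  HY <- -sum(py * log2e(py))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * log2e(pxpy))
  HXY2 <- -sum(pxpy * log2e(pxpy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))

  # maximal correlation coefficient: sqrt of the second-largest eigenvalue
  # of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), on present levels
  pres <- which(px > 0)
  mcc <- if (length(pres) < 2) {
    1
  } else {
    Pp <- P[pres, pres, drop = FALSE]
    A <- sweep(Pp, 1, px[pres], "/")
    B <- sweep(Pp, 2, py[pres], "/")
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }

  offdiag <- dif > 0
  c(
    glcm_Autocorrelation = auto,
    glcm_JointAverage = mux,
    glcm_ClusterProminence = sum(P * (I + J - mux - muy)^4),
    glcm_ClusterShade = sum(P * (I + J - mux - muy)^3),
    glcm_ClusterTendency = sum(P * (I + J - mux - muy)^2),
    glcm_Contrast = contrast,
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pxy_diff * log2e(pxy_diff)),
    glcm_DifferenceVariance = sum((kd - da)^2 * pxy_diff),
    glcm_Id = sum(P / (1 + dif)),
    glcm_Idm = sum(P / (1 + dif^2)),
    glcm_Idmn = sum(P / (1 + dif^2 / Ng^2)),
    glcm_Idn = sum(P / (1 + dif / Ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(P[offdiag] / dif[offdiag]^2),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = HXY,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(ks * pxy_sum),
    glcm_SumEntropy = -sum(pxy_sum * log2e(pxy_sum)),
    glcm_SumSquares = sum(P * (I - mux)^2)
  )
}

#' Gray-level co-occurrence features
#'
#' Symmetric co-occurrence matrices at distance 1 for the 13 unique 3D
#' directions; each is normalized and the 24 features are computed per
#' direction and averaged (unweighted). Includes IDMN (a normalized local
#' homogeneity) and difference entropy (randomness of neighboring
#' gray-level differences); all entropies in bits.
#'
#' @param levels Integer gray-level array (NA outside the mask), as
#'   produced by [discretize()].
#' @param n_levels Number of gray levels.
#' @return Named numeric vector of 24 features.
#' @export
compute_glcm_features <- function(levels, n_levels) {
  dirs <- unique_directions()
  acc <- NULL
  nd <- 0
  for (r in seq_len(nrow(dirs))) {
    P <- glcm_matrix(levels, dirs[r, ], n_levels)
    if (is.null(P)) next
    f <- glcm_features_from_matrix(P, n_levels)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) stop("no voxel pairs available for GLCM (mask too small)")
  acc / nd
}

# --------------------------------------------------------------- GLRLM --

# Enumerate gray-level runs along direction d: (level, length) pairs.
#' @noRd
runs_along <- function(levels, d) {
  dm <- dim(levels)
  prev <- shift_array(levels, -d)
  start <- !is.na(levels) & (is.na(prev) | prev != levels)
  if (!any(start)) return(NULL)
  pos <- which(start, arr.ind = TRUE)
  lev0 <- levels[start]
  len <- rep(1L, nrow(pos))
  active <- seq_len(nrow(pos))
  cur <- pos
  while (length(active)) {
    cur <- cur + matrix(d, nrow(cur), 3, byrow = TRUE)
    inb <- cur[, 1] >= 1 & cur[, 1] <= dm[1] &
      cur[, 2] >= 1 & cur[, 2] <= dm[2] &
      cur[, 3] >= 1 & cur[, 3] <= dm[3]
    val <- rep(NA_integer_, nrow(cur))
    if (any(inb)) val[inb] <- levels[cur[inb, , drop = FALSE]]
    cont <- !is.na(val) & val == lev0[active]
    len[active[cont]] <- len[active[cont]] + 1L
    active <- active[cont]
    cur <- cur[cont, , drop = FALSE]
  }
  cbind(level = lev0, length = len)
}

# Shared feature set for run-length (j = run length) and size-zone
# (j = zone size) matrices; `kind` picks the conventional names.
#' @noRd
rl_sz_features <- function(P, n_levels, n_voxels, kind = c("glrlm", "glszm")) {
  kind <- match.arg(kind)
  Nr <- sum(P)
  iv <- seq_len(nrow(P))
  jv <- seq_len(ncol(P))
  I <- matrix(iv, nrow(P), ncol(P))
  J <- t(matrix(jv, ncol(P), nrow(P)))
  pg <- rowSums(P)
  pr <- colSums(P)
  p <- P / Nr
  mu_i <- sum(p * I)
  mu_j <- sum(p * J)

  vals <- c(
    sum(P / J^2) / Nr,                 # short / small emphasis
    sum(P * J^2) / Nr,                 # long / large emphasis
    sum(pg^2) / Nr,                    # gray-level non-uniformity
    sum(pg^2) / Nr^2,                  # ... normalized
    sum(pr^2) / Nr,                    # run/zone non-uniformity
    sum(pr^2) / Nr^2,                  # ... normalized
    Nr / n_voxels,                     # run/zone percentage
    sum(p * (I - mu_i)^2),             # gray-level variance
    sum(p * (J - mu_j)^2),             # run/zone variance
    -sum(p[p > 0] * log2e(p[p > 0])),  # run/zone entropy
    sum(P / I^2) / Nr,                 # low gray-level emphasis
    sum(P * I^2) / Nr,                 # high gray-level emphasis
    sum(P / (I^2 * J^2)) / Nr,
    sum(P * I^2 / J^2) / Nr,
    sum(P * J^2 / I^2) / Nr,
    sum(P * I^2 * J^2) / Nr
  )
  nm <- if (kind == "glrlm") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  }
  stats::setNames(vals, paste(kind, nm, sep = "_"))
}

#' Gray-level run length features
#'
#' Runs of consecutive equal gray levels along each of the 13 unique 3D
#' directions; the 16 features are computed per direction and averaged.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of 16 features.
#' @export
compute_glrlm_features <- function(levels, n_levels) {
  n_voxels <- sum(!is.na(levels))
  if (n_voxels < 1) stop("empty mask")
  dirs <- unique_directions()
  acc <- NULL
  nd <- 0
  for (r in seq_len(nrow(dirs))) {
    runs <- runs_along(levels, dirs[r, ])
    if (is.null(runs)) next
    max_len <- max(runs[, "length"])
    P <- matrix(
      tabulate((runs[, "length"] - 1L) * n_levels + runs[, "level"],
               nbins = n_levels * max_len),
      n_levels, max_len
    )
    f <- rl_sz_features(P, n_levels, n_voxels, "glrlm")
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# --------------------------------------------------------------- GLSZM --

# Connected zones of equal gray level under 26-connectivity:
# (level, size) per zone.
#' @noRd
zone_list <- function(levels) {
  dm <- dim(levels)
  vox <- which(!is.na(levels))
  vid <- integer(prod(dm))
  vid[vox] <- seq_along(vox)
  edges <- list()
  dirs <- unique_directions()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    nb <- shift_array(levels, d)
    ok <- which(!is.na(levels) & !is.na(nb) & levels == nb)
    if (!length(ok)) next
    off <- d[1] + d[2] * dm[1] + d[3] * dm[1] * dm[2]
    edges[[length(edges) + 1]] <- cbind(vid[ok], vid[ok + off])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  first <- match(seq_len(comp$no), comp$membership)
  cbind(level = levels[vox][first], size = comp$csize)
}

#' Gray-level size zone features
#'
#' Zones are 26-connected components of equal gray level; the matrix is
#' direction-independent. 16 features.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of 16 features.
#' @export
compute_glszm_features <- function(levels, n_levels) {
  n_voxels <- sum(!is.na(levels))
  if (n_voxels < 1) stop("empty mask")
  z <- zone_list(levels)
  max_size <- max(z[, "size"])
  P <- matrix(
    tabulate((z[, "size"] - 1L) * n_levels + z[, "level"],
             nbins = n_levels * max_size),
    n_levels, max_size
  )
  rl_sz_features(P, n_levels, n_voxels, "glszm")
}

# ---------------------------------------------------------------- GLDM --

#' Gray-level dependence features
#'
#' The dependence of a voxel is 1 (itself) plus the number of
#' 26-neighborhood voxels inside the mask with the same gray level
#' (dependence tolerance 0). 14 features from the (gray level, dependence)
#' matrix.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of 14 features.
#' @export
compute_gldm_features <- function(levels, n_levels) {
  n_voxels <- sum(!is.na(levels))
  if (n_voxels < 1) stop("empty mask")
  dep <- array(1L, dim(levels))
  offs <- neighborhood_offsets()
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(levels, offs[r, ])
    dep <- dep + as.integer(!is.na(nb) & !is.na(levels) & nb == levels)
  }
  lev <- levels[!is.na(levels)]
  dpv <- dep[!is.na(levels)]
  max_dep <- max(dpv)
  P <- matrix(
    tabulate((dpv - 1L) * n_levels + lev, nbins = n_levels * max_dep),
    n_levels, max_dep
  )
  Nz <- sum(P)
  iv <- seq_len(n_levels)
  jv <- seq_len(max_dep)
  I <- matrix(iv, n_levels, max_dep)
  J <- t(matrix(jv, max_dep, n_levels))
  pg <- rowSums(P)
  pd <- colSums(P)
  p <- P / Nz
  mu_i <- sum(p * I)
  mu_j <- sum(p * J)
  c(
    gldm_SmallDependenceEmphasis = sum(P / J^2) / Nz,
    gldm_LargeDependenceEmphasis = sum(P * J^2) / Nz,
    gldm_GrayLevelNonUniformity = sum(pg^2) / Nz,
    gldm_DependenceNonUniformity = sum(pd^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    gldm_GrayLevelVariance = sum(p * (I - mu_i)^2),
    gldm_DependenceVariance = sum(p * (J - mu_j)^2),
    gldm_DependenceEntropy = -sum(p[p > 0] * log2e(p[p > 0])),
    gldm_LowGrayLevelEmphasis = sum(P / I^2) / Nz,
    gldm_HighGrayLevelEmphasis = sum(P * I^2) / Nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (I^2 * J^2)) / Nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * I^2 / J^2) / Nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * J^2 / I^2) / Nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * I^2 * J^2) / Nz
  )
}

# --------------------------------------------------------------- NGTDM --

#' Neighboring gray tone difference features
#'
#' For each voxel with at least one in-mask 26-neighbor, the absolute
#' difference between its gray level and the mean level of those neighbors
#' is accumulated per gray level. 5 features: coarseness, contrast,
#' busyness, complexity, strength.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of 5 features.
#' @export
compute_ngtdm_features <- function(levels, n_levels) {
  if (sum(!is.na(levels)) < 1) stop("empty mask")
  offs <- neighborhood_offsets()
  nb_sum <- array(0, dim(levels))
  nb_cnt <- array(0L, dim(levels))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(levels, offs[r, ])
    has <- !is.na(nb) & !is.na(levels)
    nb_sum[has] <- nb_sum[has] + nb[has]
    nb_cnt <- nb_cnt + as.integer(has)
  }
  use <- !is.na(levels) & nb_cnt > 0
  Nvp <- sum(use)
  if (Nvp == 0) stop("no voxel has in-mask neighbors")
  A <- nb_sum[use] / nb_cnt[use]
  lev <- levels[use]
  n_i <- tabulate(lev, nbins = n_levels)
  s_i <- vapply(seq_len(n_levels), function(i) {
    sel <- lev == i
    if (any(sel)) sum(abs(i - A[sel])) else 0
  }, numeric(1))
  p_i <- n_i / Nvp
  pres <- which(p_i > 0)
  Ngp <- length(pres)
  iv <- seq_len(n_levels)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    sum(outer(p_i[pres], p_i[pres]) *
          outer(iv[pres], iv[pres], "-")^2) / (Ngp * (Ngp - 1)) *
      sum(s_i) / Nvp
  } else 0
  busy_den <- sum(abs(outer(iv[pres] * p_i[pres], iv[pres] * p_i[pres], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  pi_m <- outer(p_i[pres], p_i[pres], "+")
  dif_m <- abs(outer(iv[pres], iv[pres], "-"))
  psi <- outer(p_i[pres] * s_i[pres], p_i[pres] * s_i[pres], "+")
  complexity <- sum(dif_m * psi / pi_m) / Nvp
  strength <- if (sum(s_i) > 0) sum(pi_m * dif_m^2) / sum(s_i) else 0
  c(
    ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength
  )
}
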