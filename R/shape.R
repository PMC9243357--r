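# 3D shape features from the binary lesion mask: iso-surface mesh
# (marching tetrahedra at the 0.5 level, edge-midpoint crossings),
# principal-axis lengths from the physical-coordinate covariance, and
# maximum 3D / per-plane 2D diameters over surface vertices.

# Cube corner offsets (0-based), standard ordering; each of the six
# tetrahedra contains the main diagonal corner pair (1, 7).
.CUBE_CORNERS <- matrix(c(
  0, 0, 0,
  1, 0, 0,
  1, 1, 0,
  0, 1, 0,
  0, 0, 1,
  1, 0, 1,
  1, 1, 1,
  0, 1, 1
), ncol = 3, byrow = TRUE)

.CUBE_TETS <- matrix(c(
  1, 2, 3, 7,
  1, 3, 4, 7,
  1, 4, 8, 7,
  1, 8, 5, 7,
  1, 5, 6, 7,
  1, 6, 2, 7
), ncol = 4, byrow = TRUE)

#' Iso-surface triangulation of a binary mask
#'
#' Builds a closed triangle mesh of the 0.5-level surface of a binary mask
#' by marching tetrahedra: each surface-crossing grid cell is split into six
#' tetrahedra and the crossing points are edge midpoints (corner values are
#' 0/1). The mask is zero-padded so lesions touching the grid border still
#' produce a closed surface. Triangles are oriented with outward normals so
#' the signed volume sums to the enclosed volume.
#'
#' @param mask Binary 3D array.
#' @param spacing Voxel spacing in mm.
#' @return A list with `v1`, `v2`, `v3` (n_triangles x 3 matrices of vertex
#'   coordinates in mm), `volume` (enclosed volume, mm^3) and `area`
#'   (surface area, mm^2).
#' @keywords internal
#' @export
mask_mesh <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  pad <- array(0L, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- as.integer(mask != 0)
  pdm <- dim(pad)

  # candidate cells: base corner index b such that the 8 corners differ
  ncell <- pdm - 1L
  csum <- array(0L, ncell)
  for (k in 1:8) {
    off <- .CUBE_CORNERS[k, ]
    csum <- csum + pad[(1:ncell[1]) + off[1],
                       (1:ncell[2]) + off[2],
                       (1:ncell[3]) + off[3]]
  }
  mixed <- which(csum > 0L & csum < 8L)
  if (length(mixed) == 0) {
    return(list(v1 = matrix(0, 0, 3), v2 = matrix(0, 0, 3),
                v3 = matrix(0, 0, 3), volume = 0, area = 0))
  }
  base <- arrayInd(mixed, ncell)  # m x 3, padded-grid corner index

  # corner coordinates (mm) and inside flags per cell: m x 8
  m <- nrow(base)
  inside <- matrix(FALSE, m, 8)
  ccoord <- vector("list", 8)
  for (k in 1:8) {
    idx <- sweep(base, 2, .CUBE_CORNERS[k, ], "+")
    inside[, k] <- pad[idx] != 0L
    ccoord[[k]] <- sweep(idx, 2, spacing, "*")
  }

  tris_v1 <- tris_v2 <- tris_v3 <- list()
  refs <- list()  # an inside-corner coordinate per triangle, for orientation
  emit <- function(v1, v2, v3, ref) {
    n <- length(tris_v1)
    tris_v1[[n + 1]] <<- v1
    tris_v2[[n + 1]] <<- v2
    tris_v3[[n + 1]] <<- v3
    refs[[n + 1]] <<- ref
  }
  mid <- function(a, b, rows) (a[rows, , drop = FALSE] + b[rows, , drop = FALSE]) / 2

  for (t in seq_len(nrow(.CUBE_TETS))) {
    tet <- .CUBE_TETS[t, ]
    fl <- inside[, tet, drop = FALSE]
    s <- rowSums(fl)
    co <- ccoord[tet]
    # one corner on its own side of the surface: one triangle
    for (a in 1:4) {
      others <- setdiff(1:4, a)
      lone_in <- which(s == 1 & fl[, a])
      lone_out <- which(s == 3 & !fl[, a])
      for (rows in list(lone_in, lone_out)) {
        if (length(rows) == 0) next
        v1 <- mid(co[[a]], co[[others[1]]], rows)
        v2 <- mid(co[[a]], co[[others[2]]], rows)
        v3 <- mid(co[[a]], co[[others[3]]], rows)
        ref_corner <- if (identical(rows, lone_in)) a else others[1]
        emit(v1, v2, v3, co[[ref_corner]][rows, , drop = FALSE])
      }
    }
    # two-in / two-out: quad split into two triangles
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pi in seq_len(nrow(pairs))) {
      ab <- pairs[pi, ]
      cd <- setdiff(1:4, ab)
      rows <- which(s == 2 & fl[, ab[1]] & fl[, ab[2]])
      if (length(rows) == 0) next
      q1 <- mid(co[[ab[1]]], co[[cd[1]]], rows)
      q2 <- mid(co[[ab[1]]], co[[cd[2]]], rows)
      q3 <- mid(co[[ab[2]]], co[[cd[2]]], rows)
      q4 <- mid(co[[ab[2]]], co[[cd[1]]], rows)
      ref <- co[[ab[1]]][rows, , drop = FALSE]
      emit(q1, q2, q3, ref)
      emit(q1, q3, q4, ref)
    }
  }

  v1 <- do.call(rbind, tris_v1)
  v2 <- do.call(rbind, tris_v2)
  v3 <- do.call(rbind, tris_v3)
  ref <- do.call(rbind, refs)

  # orient outward: the normal must point away from the inside reference
  e1 <- v2 - v1
  e2 <- v3 - v1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  cen <- (v1 + v2 + v3) / 3
  dir <- cen - ref
  flip <- nx * dir[, 1] + ny * dir[, 2] + nz * dir[, 3] < 0
  if (any(flip)) {
    tmp <- v2[flip, , drop = FALSE]
    v2[flip, ] <- v3[flip, , drop = FALSE]
    v3[flip, ] <- tmp
    e1 <- v2 - v1
    e2 <- v3 - v1
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  }

  area <- sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
  # divergence theorem with outward orientation
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
             v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
             v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  list(v1 = v1, v2 = v2, v3 = v3, volume = abs(vol), area = area)
}

#' @noRd
mesh_vertices <- function(mesh) {
  v <- rbind(mesh$v1, mesh$v2, mesh$v3)
  unique(round(v, 6))
}

# Largest pairwise Euclidean distance, computed block-wise to bound memory.
#' @noRd
max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(i0 + step - 1L, n)
    g <- pts[ii, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[ii], rep(1, n)) + outer(rep(1, length(ii)), sq) - 2 * g
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# Maximum in-plane diameter: vertex pairs sharing the coordinate along
# `fixed_axis`, distance measured in the remaining two axes.
#' @noRd
max_plane_diameter <- function(pts, fixed_axis, spacing) {
  key <- round(pts[, fixed_axis] / (spacing[fixed_axis] / 2))
  other <- setdiff(1:3, fixed_axis)
  best <- 0
  for (g in split(seq_len(nrow(pts)), key)) {
    if (length(g) < 2) next
    best <- max(best, max_pairwise_distance(pts[g, other, drop = FALSE]))
  }
  best
}

#' 3D shape features of a lesion mask
#'
#' Computes the 14 shape descriptors of a binary lesion: mesh and voxel
#' volume, surface area, surface-to-volume ratio, sphericity, maximum 3D
#' diameter, the three maximum 2D diameters (slice / row / column planes),
#' the three principal axis lengths, elongation and flatness. Shape depends
#' only on the mask and voxel spacing, never on intensities.
#'
#' Principal axis lengths are `4 * sqrt(lambda)` for the eigenvalues
#' `lambda1 >= lambda2 >= lambda3` of the (sample) covariance of the
#' physical coordinates of mask voxel centers; elongation is
#' `sqrt(lambda2 / lambda1)` and flatness `sqrt(lambda3 / lambda1)`, both
#' equal to 1 for an equant (sphere-like) lesion and smaller for elongated
#' or flat ones. The named 2D diameter planes follow the (slice, row,
#' column) axis convention of [ct_volume()]: e.g. the "column" diameter
#' lies in the plane spanned by the slice and row axes.
#'
#' @param mask Binary 3D array with at least one foreground voxel.
#' @param spacing Voxel spacing in mm.
#' @return Named numeric vector of 14 features (lengths in mm, areas in
#'   mm^2, volumes in mm^3).
#' @examples
#' sph <- ellipsoid_mask(c(21, 21, 21), c(1, 1, 1), c(8, 8, 8))
#' compute_shape_features(sph, c(1, 1, 1))[c("shape_Elongation", "shape_Flatness")]
#' @export
compute_shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (sum(mask != 0) < 1) stop("mask is empty")
  spacing <- as.numeric(spacing)
  n_vox <- sum(mask != 0)
  voxel_volume <- n_vox * prod(spacing)

  mesh <- mask_mesh(mask, spacing)
  verts <- mesh_vertices(mesh)

  idx <- which(mask != 0, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, "*")
  if (n_vox >= 2) {
    ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else {
    warning("single-voxel mask: degenerate principal axes reported as 0")
    ev <- c(0, 0, 0)
  }
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  vol <- mesh$volume
  area <- mesh$area
  c(
    shape_MeshVolume = vol,
    shape_VoxelVolume = voxel_volume,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = if (vol > 0) area / vol else NA_real_,
    shape_Sphericity = if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else NA_real_,
    shape_Maximum3DDiameter = max_pairwise_distance(verts),
    shape_Maximum2DDiameterSlice = max_plane_diameter(verts, 1, spacing),
    shape_Maximum2DDiameterRow = max_plane_diameter(verts, 2, spacing),
    shape_Maximum2DDiameterColumn = max_plane_diameter(verts, 3, spacing),
    shape_MajorAxisLength = axis_len[1],
    shape_MinorAxisLength = axis_len[2],
    shape_LeastAxisLength = axis_len[3],
    shape_Elongation = elong,
    shape_Flatness = flat
  )
}
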