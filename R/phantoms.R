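# Synthetic lesion phantoms: ellipsoidal masks filled with a spatially
# correlated HU texture plus hypodense / hyperdense inclusions, emulating
# the appearance of omental tumor deposits (soft tissue with fatty or
# cystic/necrotic and calcified components) on contrast-enhanced CT.

#' Ellipsoidal binary mask
#'
#' Voxel centers inside the ellipsoid with given semi-axes (mm), centered
#' in the grid, are foreground.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param spacing Voxel spacing in mm.
#' @param semi_axes Ellipsoid semi-axes in mm (slice, row, column order).
#' @param center Optional ellipsoid center in voxel index units (1-based);
#'   defaults to the grid center.
#' @return Binary integer array.
#' @export
ellipsoid_mask <- function(grid_shape, spacing, semi_axes, center = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (is.null(center)) center <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(a) {
    ((seq_len(grid_shape[a]) - center[a]) * spacing[a] / semi_axes[a])^2
  })
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  array(as.integer(d2 <= 1), grid_shape)
}

#' Phantom specification
#'
#' Parameters of a synthetic lesion phantom. The soft-tissue mean must lie
#' inside the default resegmentation range `[-100, 400]` HU; hypodense and
#' hyperdense inclusion means must lie below and above it, respectively, so
#' that sub-segmentation and resegmentation have signal to act on. The
#' background defaults to -90 HU (fat-like omental tissue).
#'
#' @param grid_shape Voxel counts per axis.
#' @param spacing Voxel spacing in mm.
#' @param semi_axes Lesion ellipsoid semi-axes in mm.
#' @param soft_tissue_hu_mean,soft_tissue_hu_std Mean and SD (HU) of the
#'   soft-tissue texture.
#' @param hypodense_fraction,hyperdense_fraction Target volume fractions of
#'   the two inclusion types (each in `[0, 0.9)`, summing to < 0.9).
#' @param hypodense_hu,hyperdense_hu Mean HU of the inclusions.
#' @param texture_correlation_length_mm Gaussian correlation length of the
#'   soft-tissue texture (0 = white noise).
#' @param background_hu HU outside the lesion.
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 40),
                         spacing = c(1.5, 1, 1),
                         semi_axes = c(18, 14, 12),
                         soft_tissue_hu_mean = 60,
                         soft_tissue_hu_std = 20,
                         hypodense_fraction = 0.08,
                         hyperdense_fraction = 0.04,
                         hypodense_hu = -160,
                         hyperdense_hu = 600,
                         texture_correlation_length_mm = 3,
                         background_hu = -90,
                         seed = 1L) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (any(2 * semi_axes >= grid_shape * spacing)) {
    stop("lesion does not fit inside the grid")
  }
  if (hypodense_fraction < 0 || hyperdense_fraction < 0 ||
      hypodense_fraction + hyperdense_fraction > 0.9) {
    stop("inclusion fractions must be nonnegative and sum to at most 0.9")
  }
  if (soft_tissue_hu_mean < -100 || soft_tissue_hu_mean > 400) {
    stop("soft-tissue mean must lie inside the resegmentation range [-100, 400] HU")
  }
  if (hypodense_hu >= -100) stop("hypodense mean must be below -100 HU")
  if (hyperdense_hu <= 400) stop("hyperdense mean must be above 400 HU")
  structure(as.list(environment()), class = "phantom_spec")
}

# Separable Gaussian smoothing of a 3D array (sigma per axis, voxels).
#' @noRd
gauss_smooth3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dm <- dim(ap)
    m <- matrix(ap, nrow = dm[1])
    # reflect-pad along the filtered axis
    padm <- rbind(m[r:1, , drop = FALSE], m, m[dm[1]:(dm[1] - r + 1), , drop = FALSE])
    out <- matrix(0, dm[1], ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padm[(j - 1) + seq_len(dm[1]), , drop = FALSE]
    }
    a <- aperm(array(out, dm), order(perm))
  }
  a
}

#' Generate a lesion phantom
#'
#' Builds an ellipsoidal lesion mask and an HU volume: background outside
#' the mask; inside, a stationary spatially correlated Gaussian random
#' field (white noise smoothed with a Gaussian kernel of width
#' `texture_correlation_length_mm`, rescaled to the requested mean/SD) with
#' compact hypodense and hyperdense inclusions occupying the requested
#' volume fractions to within 2 percentage points.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [ct_volume]), `mask` (binary array), and
#'   `tissue_truth` (integer array: 1 hypodense, 2 soft tissue,
#'   3 hyperdense inside the mask).
#' @export
generate_lesion_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$grid_shape
  mask <- ellipsoid_mask(dm, spec$spacing, spec$semi_axes)
  n_in <- sum(mask)

  field <- array(stats::rnorm(prod(dm)), dm)
  sigma_vox <- spec$texture_correlation_length_mm / spec$spacing
  if (any(sigma_vox > 0) && spec$soft_tissue_hu_std > 0) {
    field <- gauss_smooth3(field, sigma_vox)
  }
  sd_in <- stats::sd(field[mask == 1])
  if (is.na(sd_in) || sd_in == 0) sd_in <- 1
  hu <- spec$soft_tissue_hu_mean +
    spec$soft_tissue_hu_std * (field - mean(field[mask == 1])) / sd_in

  tissue <- array(0L, dm)
  tissue[mask == 1] <- 2L
  tissue <- place_inclusions(tissue, mask, spec$hypodense_fraction, 1L)
  tissue <- place_inclusions(tissue, mask, spec$hyperdense_fraction, 3L)
  incl_sd <- min(15, spec$soft_tissue_hu_std)
  n_hypo <- sum(tissue == 1L)
  n_hyper <- sum(tissue == 3L)
  if (n_hypo > 0) {
    hu[tissue == 1L] <- spec$hypodense_hu + stats::rnorm(n_hypo, sd = incl_sd)
    hu[tissue == 1L] <- pmin(hu[tissue == 1L], -101)
  }
  if (n_hyper > 0) {
    hu[tissue == 3L] <- spec$hyperdense_hu + stats::rnorm(n_hyper, sd = incl_sd)
    hu[tissue == 3L] <- pmax(hu[tissue == 3L], 401)
  }
  hu[mask == 0] <- spec$background_hu

  list(volume = ct_volume(hu, spec$spacing), mask = mask,
       tissue_truth = tissue)
}

# Paint compact spherical blobs of `label` into soft-tissue voxels until
# the target fraction of the mask is reached (trimmed to land within it).
#' @noRd
place_inclusions <- function(tissue, mask, fraction, label) {
  target <- round(fraction * sum(mask == 1))
  if (target <= 0) return(tissue)
  dm <- dim(tissue)
  avail <- which(tissue == 2L)
  guard <- 0L
  while (sum(tissue == label) < target && guard < 500L) {
    guard <- guard + 1L
    avail <- which(tissue == 2L)
    if (length(avail) == 0) break
    c0 <- arrayInd(sample(avail, 1), dm)
    r <- stats::runif(1, 1.5, 3.5)
    lo <- pmax(c0 - ceiling(r), 1)
    hi <- pmin(c0 + ceiling(r), dm)
    sub <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    d2 <- rowSums(sweep(sub, 2, as.numeric(c0))^2)
    sub <- sub[d2 <= r^2, , drop = FALSE]
    d2 <- d2[d2 <= r^2]
    lin <- sub[, 1] + (sub[, 2] - 1) * dm[1] + (sub[, 3] - 1) * dm[1] * dm[2]
    ok <- tissue[lin] == 2L
    lin <- lin[ok]
    d2 <- d2[ok]
    need <- target - sum(tissue == label)
    if (length(lin) > need) {
      lin <- lin[order(d2)][seq_len(need)]
    }
    tissue[lin] <- label
  }
  tissue
}

#' Generate an imaging cohort of labelled phantoms
#'
#' Draws per-patient phantom parameters from label-conditional
#' distributions at the requested prevalence of complete response
#' (label 1). `responder_shift` is a named list of multiplicative shifts
#' applied to phantom parameters of label-1 patients; the default encodes
#' the direction seen in responders (more elongated lesions with a smaller
#' least axis, smaller volume): the third semi-axis is shrunk.
#'
#' @param n Number of patients.
#' @param prevalence Probability of label 1.
#' @param responder_shift Named list of multipliers for label-1 patients;
#'   supported names: `semi_axes` (length 3), `soft_tissue_hu_std`,
#'   `texture_correlation_length_mm`.
#' @param seed Integer seed.
#' @param base_spec Template [phantom_spec()] providing the non-shifted
#'   parameters.
#' @return List of per-patient lists `(volume, mask, label, spec)`.
#' @export
generate_imaging_cohort <- function(n, prevalence = 0.41,
                                    responder_shift = list(semi_axes = c(1, 1, 0.6)),
                                    seed = 1L,
                                    base_spec = phantom_spec()) {
  stopifnot(n >= 1, prevalence > 0, prevalence < 1)
  set.seed(derive_seed(seed, "imaging_cohort"))
  labels <- stats::rbinom(n, 1, prevalence)
  lapply(seq_len(n), function(i) {
    jitter <- stats::runif(3, 0.8, 1.2)
    semi <- base_spec$semi_axes * jitter
    st_std <- base_spec$soft_tissue_hu_std
    tcl <- base_spec$texture_correlation_length_mm
    if (labels[i] == 1) {
      if (!is.null(responder_shift$semi_axes)) {
        semi <- semi * responder_shift$semi_axes
      }
      if (!is.null(responder_shift$soft_tissue_hu_std)) {
        st_std <- st_std * responder_shift$soft_tissue_hu_std
      }
      if (!is.null(responder_shift$texture_correlation_length_mm)) {
        tcl <- tcl * responder_shift$texture_correlation_length_mm
      }
    }
    sp <- phantom_spec(
      grid_shape = base_spec$grid_shape,
      spacing = base_spec$spacing,
      semi_axes = pmin(semi, (base_spec$grid_shape * base_spec$spacing) / 2 - 1),
      soft_tissue_hu_mean = base_spec$soft_tissue_hu_mean,
      soft_tissue_hu_std = st_std,
      hypodense_fraction = base_spec$hypodense_fraction,
      hyperdense_fraction = base_spec$hyperdense_fraction,
      hypodense_hu = base_spec$hypodense_hu,
      hyperdense_hu = base_spec$hyperdense_hu,
      texture_correlation_length_mm = tcl,
      background_hu = base_spec$background_hu,
      seed = derive_seed(seed, "phantom", i)
    )
    ph <- generate_lesion_phantom(sp)
    list(volume = ph$volume, mask = ph$mask, label = labels[i], spec = sp)
  })
}

#' Write an imaging cohort to NIfTI files with a CSV manifest
#'
#' @param cohort Result of [generate_imaging_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame
#'   (patient_id, volume_file, mask_file, label).
#' @export
write_imaging_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    id <- sprintf("P%03d", i)
    vf <- file.path(dir, paste0(id, "_ct.nii.gz"))
    mf <- file.path(dir, paste0(id, "_mask.nii.gz"))
    write_ct_nifti(cohort[[i]]$volume, vf)
    write_mask_nifti(cohort[[i]]$mask, cohort[[i]]$volume$spacing, mf)
    data.frame(patient_id = id, volume_file = vf, mask_file = mf,
               label = cohort[[i]]$label)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
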