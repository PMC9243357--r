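#' CT volume container
#'
#' Bundles a 3D grid of intensities in Hounsfield units (HU) with its voxel
#' spacing. The axis order convention is (slice, row, column): the first
#' array dimension runs in the supero-inferior (slice) direction and the
#' third in the left-right (column) direction. Shape features that refer to
#' a named plane (e.g. the "column" maximum 2D diameter, measured in the
#' plane spanned by the slice and row axes) rely on this convention.
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing Numeric length-3 vector of voxel spacing in mm,
#'   one entry per array dimension. All entries must be positive.
#' @return An object of class `ct_volume`: a list with elements
#'   `intensities` and `spacing`.
#' @examples
#' vol <- ct_volume(array(40, c(4, 4, 4)), spacing = c(1, 1, 1))
#' @export
ct_volume <- function(intensities, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3) {
    stop("`intensities` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive numbers (mm)")
  }
  if (any(!is.finite(intensities))) {
    stop("`intensities` must be finite")
  }
  structure(
    list(intensities = intensities, spacing = spacing),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$intensities), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, HU range [", signif(min(x$intensities), 4), ", ",
      signif(max(x$intensities), 4), "]\n", sep = "")
  invisible(x)
}

#' @noRd
check_mask <- function(volume, mask, require_nonempty = TRUE) {
  if (!identical(dim(volume$intensities), dim(mask))) {
    stop("mask and volume must share the same grid")
  }
  if (!is_binary_mask(mask)) stop("mask must be binary")
  if (require_nonempty && sum(mask != 0) < 1) {
    stop("mask is empty: at least one foreground voxel is required")
  }
  invisible(TRUE)
}

#' Read / write NIfTI volume-mask pairs
#'
#' Thin wrappers around RNifti. `read_ct_nifti` returns a [ct_volume] with
#' the spacing taken from the NIfTI header (pixdim); `read_mask_nifti`
#' returns a binary integer array (any nonzero voxel is foreground).
#'
#' @param path Path to a NIfTI file (`.nii` or `.nii.gz`).
#' @return `read_ct_nifti`: a [ct_volume]; `read_mask_nifti`: an integer
#'   array of 0/1.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)), spacing = RNifti::pixdim(img))
}

#' @rdname read_ct_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.integer(as.numeric(img) != 0), dim(img))
}

#' @rdname read_ct_nifti
#' @param volume A [ct_volume] to write.
#' @export
write_ct_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ct_nifti
#' @param mask Binary 3D array to write.
#' @param spacing Voxel spacing in mm for the mask header.
#' @export
write_mask_nifti <- function(mask, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(mask != 0), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Tissue sub-segmentation of a lesion by HU thresholds
#'
#' Partitions the lesion into hypodense (fatty or cystic/necrotic),
#' soft-tissue, and hyperdense (calcified) components by simple Hounsfield
#' thresholding. Voxels below `lower_hu` are hypodense, above `upper_hu`
#' hyperdense, and the closed interval in between is soft tissue. The
#' default thresholds equal the resegmentation range used for texture
#' analysis, so that "intermediately dense" coincides with the voxels that
#' survive resegmentation.
#'
#' @param volume A [ct_volume].
#' @param mask Binary lesion mask aligned to `volume`.
#' @param lower_hu,upper_hu Soft-tissue interval bounds in HU
#'   (`lower_hu < upper_hu`).
#' @return Integer array of the same shape with labels 0 = background
#'   (outside mask), 1 = hypodense, 2 = soft tissue, 3 = hyperdense.
#' @examples
#' vol <- ct_volume(array(40, c(4, 4, 4)))
#' mask <- array(1L, c(4, 4, 4))
#' table(subsegment_tissue(vol, mask))
#' @export
subsegment_tissue <- function(volume, mask, lower_hu = -100, upper_hu = 400) {
  if (!(lower_hu < upper_hu)) stop("lower_hu must be below upper_hu")
  check_mask(volume, mask)
  hu <- volume$intensities
  lab <- array(0L, dim(hu))
  inside <- mask != 0
  lab[inside] <- 2L
  lab[inside & hu < lower_hu] <- 1L
  lab[inside & hu > upper_hu] <- 3L
  lab
}

#' Resegment a lesion mask to an HU range
#'
#' Removes from the mask the voxels whose intensity lies outside the closed
#' HU range, prior to intensity and texture feature computation. Shape
#' features are always computed on the original mask; first-order and
#' texture features on the resegmented one.
#'
#' @inheritParams subsegment_tissue
#' @param range_hu Closed HU interval, default `c(-100, 400)`.
#' @return Binary integer array: `mask` AND intensity within `range_hu`.
#' @export
resegment <- function(volume, mask, range_hu = c(-100, 400)) {
  if (length(range_hu) != 2 || !(range_hu[1] < range_hu[2])) {
    stop("range_hu must be an increasing length-2 interval")
  }
  check_mask(volume, mask)
  hu <- volume$intensities
  out <- array(
    as.integer(mask != 0 & hu >= range_hu[1] & hu <= range_hu[2]),
    dim(mask)
  )
  if (sum(out) == 0) {
    stop("resegmentation removed every voxel; widen `range_hu`")
  }
  out
}

#' Freedman-Diaconis bin width
#'
#' Bin width for gray-level quantization, `2 * IQR * n^(-1/3)`. The IQR is
#' computed with the default (type 7) quantile convention. When the IQR is
#' zero (near-constant input) the rule degenerates and a fixed fallback
#' width is returned instead.
#'
#' @param values Numeric vector of at least 2 HU values.
#' @param fallback_width Width in HU used when IQR = 0 (default 25).
#' @return A positive scalar bin width in HU.
#' @examples
#' fd_bin_width(c(0, 1, 1, 2, 2, 3, 3, 4))
#' @export
fd_bin_width <- function(values, fallback_width = 25) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values for a bin width")
  iqr <- unname(diff(stats::quantile(values, c(0.25, 0.75), names = FALSE)))
  if (iqr <= 0) {
    return(fallback_width)
  }
  2 * iqr * length(values)^(-1 / 3)
}

#' Gray-level discretization of lesion intensities
#'
#' Maps each in-mask intensity to an integer gray level
#' `floor((v - min) / width) + 1`, capped at `n_levels`, where
#' `n_levels = ceiling((max - min) / width)` (at least 1) and `min`/`max`
#' are taken over the (resegmented) lesion voxels. Bins are anchored at the
#' per-lesion minimum, following the per-sample nature of the
#' Freedman-Diaconis rule.
#'
#' @inheritParams subsegment_tissue
#' @param bin_width Bin width in HU; when `NULL`, derived from the in-mask
#'   intensities with [fd_bin_width()].
#' @param fallback_width Passed to [fd_bin_width()].
#' @return A list with `levels` (integer array, NA outside the mask),
#'   `n_levels`, and `bin_width`.
#' @export
discretize <- function(volume, mask, bin_width = NULL, fallback_width = 25) {
  check_mask(volume, mask)
  inside <- mask != 0
  vals <- volume$intensities[inside]
  if (is.null(bin_width)) {
    bin_width <- if (length(vals) >= 2) {
      fd_bin_width(vals, fallback_width = fallback_width)
    } else {
      fallback_width
    }
  }
  if (bin_width <= 0) stop("bin_width must be positive")
  vmin <- min(vals)
  n_levels <- max(1L, as.integer(ceiling((max(vals) - vmin) / bin_width)))
  lev <- pmin(floor((vals - vmin) / bin_width) + 1, n_levels)
  out <- array(NA_integer_, dim(mask))
  out[inside] <- as.integer(lev)
  list(levels = out, n_levels = n_levels, bin_width = bin_width)
}

#' Lesion volumetry
#'
#' `lesion_volume` is the whole-lesion volume in cm^3 (voxel count times
#' voxel volume); `percentage_change` is the relative volume change between
#' two time points in percent, `100 * (post - pre) / pre`.
#'
#' @param mask Binary 3D lesion mask.
#' @param spacing Voxel spacing in mm.
#' @return `lesion_volume`: volume in cm^3.
#' @examples
#' lesion_volume(array(1L, c(10, 10, 10)), c(1, 1, 1)) # 1 cm^3
#' percentage_change(10, 1.85)                         # -81.5
#' @export
lesion_volume <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(mask != 0) * prod(spacing) / 1000
}

#' @rdname lesion_volume
#' @param pre_vol,post_vol Volumes (same units) at the two time points;
#'   `pre_vol` must be positive.
#' @export
percentage_change <- function(pre_vol, post_vol) {
  if (any(pre_vol <= 0)) stop("pre-treatment volume must be positive")
  100 * (post_vol - pre_vol) / pre_vol
}
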