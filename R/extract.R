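# Full-feature extraction: 107 features in seven classes, with shape
# computed on the original mask and intensity/texture features on the
# resegmented, Freedman-Diaconis-discretized lesion at original voxel
# sizes (no resampling).

#' Extraction configuration
#'
#' @param resegment_range_hu Closed HU interval retained for intensity and
#'   texture features (default `c(-100, 400)`).
#' @param bin_width Fixed gray-level bin width in HU, or `NULL` to derive
#'   it per lesion with the Freedman-Diaconis rule.
#' @param fallback_bin_width Bin width used when the FD rule degenerates
#'   (IQR = 0).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(resegment_range_hu = c(-100, 400),
                              bin_width = NULL,
                              fallback_bin_width = 25) {
  structure(list(resegment_range_hu = resegment_range_hu,
                 bin_width = bin_width,
                 fallback_bin_width = fallback_bin_width),
            class = "extraction_config")
}

#' Names of the full radiomic feature set
#'
#' @return Character vector of the 107 feature names in canonical order
#'   (shape 14, first-order 18, GLCM 24, GLRLM 16, GLSZM 16, GLDM 14,
#'   NGTDM 5), each prefixed with its class.
#' @export
radiomic_feature_names <- function() {
  dummy_lv <- array(c(1L, 1L, 2L, 1L, 2L, 2L, 1L, 2L), c(2, 2, 2))
  c(
    names(compute_shape_features(array(1L, c(2, 2, 2)))),
    names(compute_first_order(ct_volume(array(c(1, 2), c(2, 2, 2))),
                              array(1L, c(2, 2, 2)))),
    names(glcm_features_from_matrix(matrix(0.25, 2, 2), 2)),
    names(rl_sz_features(matrix(1, 2, 2), 2, 8, "glrlm")),
    names(rl_sz_features(matrix(1, 2, 2), 2, 8, "glszm")),
    names(compute_gldm_features(dummy_lv, 2L)),
    names(compute_ngtdm_features(dummy_lv, 2L))
  )
}

#' Extract the full radiomic feature set from a lesion
#'
#' Computes all 107 features: 14 shape features from the original mask and
#' voxel spacing; 18 first-order and 93 texture-class features (GLCM 24,
#' GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5) from the resegmented lesion after
#' gray-level discretization. Deterministic: the same input always yields
#' a bit-identical vector.
#'
#' @param volume A [ct_volume].
#' @param mask Binary lesion mask aligned to `volume`.
#' @param config An [extraction_config()].
#' @return Named numeric vector of 107 features.
#' @examples
#' ph <- generate_lesion_phantom(phantom_spec(seed = 7))
#' length(extract_all(ph$volume, ph$mask))  # 107
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  check_mask(volume, mask)
  shp <- compute_shape_features(mask, volume$spacing)
  rmask <- resegment(volume, mask, config$resegment_range_hu)
  disc <- discretize(volume, rmask, bin_width = config$bin_width,
                     fallback_width = config$fallback_bin_width)
  fo <- compute_first_order(volume, rmask, discretization = disc)
  lv <- disc$levels
  ng <- disc$n_levels
  out <- c(
    shp, fo,
    compute_glcm_features(lv, ng),
    compute_glrlm_features(lv, ng),
    compute_glszm_features(lv, ng),
    compute_gldm_features(lv, ng),
    compute_ngtdm_features(lv, ng)
  )
  stopifnot(length(out) == 107)
  out
}

#' Six-term interpretable radiomic signature
#'
#' The compact signature of a lesion: maximum 2D diameter in the
#' column-named (coronal) plane, least axis length, elongation, GLCM IDMN,
#' GLCM difference entropy, and whole-lesion volume in cm^3. The first
#' five are exactly the corresponding entries of [extract_all()].
#'
#' @inheritParams extract_all
#' @return Named numeric vector of 6 values.
#' @export
compute_signature <- function(volume, mask, config = extraction_config()) {
  feats <- extract_all(volume, mask, config)
  c(
    feats[c("shape_Maximum2DDiameterColumn", "shape_LeastAxisLength",
            "shape_Elongation", "glcm_Idmn", "glcm_DifferenceEntropy")],
    volume_cm3 = lesion_volume(mask, volume$spacing)
  )
}

#' Extract features for a whole imaging cohort
#'
#' @param cohort A list of per-patient lists with elements `volume`,
#'   `mask`, and optionally `label` (as produced by
#'   [generate_imaging_cohort()]).
#' @param config An [extraction_config()].
#' @return A [feature_table] whose columns are the 107 features plus
#'   `volume_cm3`; labels are taken from the cohort (or all 0 when absent).
#' @export
extract_cohort <- function(cohort, config = extraction_config()) {
  rows <- lapply(cohort, function(pt) {
    c(extract_all(pt$volume, pt$mask, config),
      volume_cm3 = lesion_volume(pt$mask, pt$volume$spacing))
  })
  X <- do.call(rbind, rows)
  labels <- vapply(cohort, function(pt) as.integer(pt$label %||% 0L), integer(1))
  feature_table(X, labels)
}
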