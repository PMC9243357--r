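# Feature-table hygiene: orientation-corrected univariate AUC, the
# supervised Spearman redundancy filter (embedded in the inner CV loop by
# the modeling pipeline), an ICC-based robustness filter, and train-only
# z-score standardization.

#' Univariate discrimination AUC of a single feature
#'
#' AUC of the univariate logistic score for the binary labels. Because the
#' logistic link is monotone, this equals the rank (Mann-Whitney) AUC of
#' the raw feature; ties count 1/2. The value is orientation-corrected:
#' features predictive in either direction score above 0.5
#' (`max(auc, 1 - auc)`), matching the AUC of the fitted univariate model
#' score.
#'
#' @param x Numeric feature values.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in `[0.5, 1]`.
#' @export
univariate_auc <- function(x, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(x)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}

#' Supervised redundancy filter
#'
#' Iteratively removes redundant features: compute all pairwise absolute
#' Spearman correlations; while any pair reaches the threshold, take the
#' pair with the largest |rho| (ties broken by lexicographic feature-name
#' order) and drop the member with the lower univariate AUC (ties: drop
#' the alphabetically later name); recompute over the survivors.
#'
#' This operation is supervised (it reads the labels), so the modeling
#' pipeline only ever calls it on training partitions, never on held-out
#' rows.
#'
#' @param X Numeric matrix with named columns (training rows only).
#' @param labels Binary labels for the same rows.
#' @param rho_threshold Redundancy threshold on |Spearman rho|
#'   (default 0.90).
#' @return Character vector of retained feature names, in original column
#'   order. The result contains no pair at or above the threshold.
#' @export
redundancy_filter <- function(X, labels, rho_threshold = 0.90) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  keep <- colnames(X)
  if (length(keep) < 2) return(keep)
  aucs <- vapply(keep, function(f) univariate_auc(X[, f], labels), numeric(1))
  rho <- abs(stats::cor(X[, keep, drop = FALSE], method = "spearman"))
  diag(rho) <- 0
  while (TRUE) {
    mx <- max(rho)
    if (mx < rho_threshold || length(keep) < 2) break
    hits <- which(rho == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_names <- cbind(rownames(rho)[hits[, 1]], colnames(rho)[hits[, 2]])
    ord <- order(pair_names[, 1], pair_names[, 2])
    a <- pair_names[ord[1], 1]
    b <- pair_names[ord[1], 2]
    drop <- if (aucs[a] < aucs[b]) a
            else if (aucs[b] < aucs[a]) b
            else max(a, b)
    keep <- setdiff(keep, drop)
    rho <- rho[keep, keep, drop = FALSE]
    if (length(keep) < 2) break
  }
  colnames(X)[colnames(X) %in% keep]
}

# Two-way agreement ICC, single rater/measurement (absolute agreement),
# from the two-way ANOVA mean squares of an n x 2 measurement matrix.
#' @noRd
icc_agreement <- function(m1, m2) {
  Y <- cbind(m1, m2)
  n <- nrow(Y)
  k <- 2
  mu <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  msc <- n * sum((col_m - mu)^2) / (k - 1)
  mse <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + mu)^2) / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den <= 0) return(0)
  (msr - mse) / den
}

#' Robustness filter against mask perturbation
#'
#' Retains features whose two-way agreement intraclass correlation
#' coefficient between the original feature table and a table extracted
#' from perturbed segmentations (e.g. 1-voxel erosion/dilation of the
#' masks) reaches the threshold. This is a configurable stand-in for a
#' feature-robustness calibration step; it is off by default in the
#' pipeline.
#'
#' @param X_original,X_perturbed Numeric matrices with identical row
#'   (patient) and column (feature) sets.
#' @param icc_threshold Minimum ICC to retain a feature (default 0.75).
#' @return Character vector of retained feature names.
#' @export
robustness_filter <- function(X_original, X_perturbed, icc_threshold = 0.75) {
  X_original <- as.matrix(X_original)
  X_perturbed <- as.matrix(X_perturbed)
  if (!identical(dim(X_original), dim(X_perturbed)) ||
      !identical(colnames(X_original), colnames(X_perturbed))) {
    stop("original and perturbed tables must have matching patients and features")
  }
  icc <- vapply(colnames(X_original), function(f) {
    icc_agreement(X_original[, f], X_perturbed[, f])
  }, numeric(1))
  names(icc)[icc >= icc_threshold]
}

#' Train-only z-score standardization
#'
#' `zscore_fit` computes per-feature means and sample (n-1) standard
#' deviations on training rows; `zscore_apply` standardizes any matrix
#' with those training parameters, so held-out rows never contribute to
#' the location/scale estimates. Zero-variance training columns are
#' dropped with a warning.
#'
#' @param X_train Numeric training matrix with named columns.
#' @return `zscore_fit`: a `zscore_params` list with `mean`, `sd`, and
#'   `features`.
#' @export
zscore_fit <- function(X_train) {
  X_train <- as.matrix(X_train)
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, stats::sd)
  bad <- !is.finite(sdv) | sdv <= 0
  if (any(bad)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X_train)[bad], collapse = ", "))
  }
  structure(list(mean = mu[!bad], sd = sdv[!bad],
                 features = colnames(X_train)[!bad]),
            class = "zscore_params")
}

#' @rdname zscore_fit
#' @param X Matrix to standardize (training or held-out rows).
#' @param params A `zscore_params` object from `zscore_fit`.
#' @export
zscore_apply <- function(X, params) {
  X <- as.matrix(X)
  missing_f <- setdiff(params$features, colnames(X))
  if (length(missing_f)) {
    stop("matrix lacks feature(s): ", paste(missing_f, collapse = ", "))
  }
  Xs <- X[, params$features, drop = FALSE]
  sweep(sweep(Xs, 2, params$mean, "-"), 2, params$sd, "/")
}
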