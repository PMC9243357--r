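# First-order intensity histogram statistics on the resegmented lesion.

#' First-order intensity features
#'
#' The 18 first-order statistics of the in-mask (resegmented) intensities.
#' Histogram-based entries (entropy, uniformity) use the same
#' Freedman-Diaconis gray-level discretization as the texture features;
#' entropy is in bits. Moment-based statistics (variance, skewness,
#' kurtosis) use population moments; kurtosis is not excess-corrected
#' (a Gaussian scores about 3).
#'
#' @param volume A [ct_volume].
#' @param mask Binary (resegmented) mask aligned to `volume`.
#' @param discretization Optional result of [discretize()] computed on the
#'   same volume/mask; derived internally when `NULL`.
#' @return Named numeric vector of 18 features.
#' @export
compute_first_order <- function(volume, mask, discretization = NULL) {
  check_mask(volume, mask)
  x <- volume$intensities[mask != 0]
  n <- length(x)
  if (is.null(discretization)) discretization <- discretize(volume, mask)
  lev <- discretization$levels[mask != 0]
  p <- tabulate(lev, nbins = discretization$n_levels) / n
  p <- p[p > 0]

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  core <- x[x >= q[1] & x <= q[5]]
  voxel_vol <- prod(volume$spacing)

  c(
    firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = voxel_vol * sum(x^2),
    firstorder_Entropy = -sum(p * log2e(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(core)) mean(abs(core - mean(core))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2)
  )
}
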