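# Majority-voting ensemble for external testing, the imbalance-aware
# metric panel (AUC, accuracy, sensitivity, specificity, G-mean, PPV,
# NPV), the volumetric baseline, and non-parametric distribution
# comparisons with Bonferroni-Holm adjustment.

#' Majority vote
#'
#' @param votes Binary vector with an odd number of entries (ties are
#'   impossible by construction).
#' @return 0 or 1, the class with more votes.
#' @export
majority_vote <- function(votes) {
  votes <- as.integer(votes)
  if (length(votes) %% 2 == 0) {
    stop("an odd number of votes is required (ties must be impossible)")
  }
  as.integer(sum(votes) > length(votes) / 2)
}

#' Build an ensemble from cross-validated models
#'
#' The deployed ensemble is the `k_outer` models of one designated
#' repetition of a nested CV run (default: the first), each carrying its
#' own retained features, standardization parameters, coefficients and
#' optimized decision threshold.
#'
#' @param run A `repetition_results` from [repeat_nested_cv()], or a list
#'   of `fitted_crs_model`s.
#' @param repetition Which repetition's outer-fold models to deploy.
#' @return An `ensemble_model` (list of member models).
#' @export
ensemble_model <- function(run, repetition = 1L) {
  members <- if (inherits(run, "repetition_results")) {
    run$runs[[repetition]]$models
  } else {
    run
  }
  if (length(members) %% 2 == 0) {
    stop("the ensemble needs an odd number of members")
  }
  structure(list(members = members), class = "ensemble_model")
}

#' Ensemble prediction by majority voting
#'
#' Each member standardizes the external table with its own training
#' parameters, scores it, and votes with its own optimized threshold; the
#' predicted class is the majority vote. The continuous ensemble score
#' (used for AUC) is the mean of the member probabilities by default, or
#' the vote fraction when `score_type = "vote_fraction"`.
#'
#' @param ensemble An [ensemble_model()].
#' @param X External feature matrix (named columns covering every
#'   member's features) or a [feature_table].
#' @param score_type `"mean_probability"` (default) or `"vote_fraction"`.
#' @return Data frame with per-patient `class`, `score`, and the member
#'   vote matrix as attribute `"votes"`.
#' @export
ensemble_predict <- function(ensemble, X,
                             score_type = c("mean_probability", "vote_fraction")) {
  score_type <- match.arg(score_type)
  if (inherits(X, "feature_table")) X <- X$X
  members <- ensemble$members
  probs <- vapply(members, function(m) {
    predict(m, X, type = "response")
  }, numeric(nrow(X)))
  votes <- vapply(seq_along(members), function(i) {
    as.integer(probs[, i] >= members[[i]]$tau)
  }, integer(nrow(X)))
  cls <- apply(votes, 1, majority_vote)
  score <- if (score_type == "mean_probability") {
    rowMeans(probs)
  } else {
    rowMeans(votes)
  }
  out <- data.frame(class = cls, score = score)
  attr(out, "votes") <- votes
  out
}

#' Classification metric panel
#'
#' Confusion-matrix metrics plus the rank AUC of the continuous scores
#' (ties counted 1/2). G-mean is `sqrt(sensitivity * specificity)`.
#' Metrics undefined because a class or prediction level is absent (e.g.
#' sensitivity with no positives) are reported as `NA` with a warning,
#' never coerced to 0.
#'
#' @param predicted_classes Binary predictions.
#' @param scores Continuous scores (for AUC); may be `NULL`.
#' @param labels Binary reference labels.
#' @return Named list: `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `gmean`, `ppv`, `npv`.
#' @export
compute_metrics <- function(predicted_classes, scores, labels) {
  labels <- as.integer(labels)
  pred <- as.integer(predicted_classes)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)

  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, n1, "sensitivity")
  spec <- safe_div(tn, n0, "specificity")
  auc <- if (!is.null(scores) && n1 > 0 && n0 > 0) {
    r <- rank(scores)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    if (is.null(scores)) NA_real_ else {
      warning("AUC undefined with a single class; reported as NA")
      NA_real_
    }
  }
  list(
    auc = auc,
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens,
    specificity = spec,
    gmean = if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec),
    ppv = safe_div(tp, tp + fp, "PPV"),
    npv = safe_div(tn, tn + fn, "NPV")
  )
}

#' Volumetric baseline model
#'
#' Runs a single volume feature through the same nested CV machinery
#' (shrinkage selection, threshold optimization, repetitions) as the
#' radiomic models, giving the univariate logistic baseline against which
#' radiomics is compared.
#'
#' @param volumes Positive tumor volumes (one per patient); typically
#'   pre-treatment, post-treatment, or percentage-change values.
#' @param labels Binary response labels.
#' @param cv_cfg,enet_cfg Configurations, as for [repeat_nested_cv()].
#' @param feature_name Column name for the volume feature.
#' @return A `repetition_results` object.
#' @export
volumetric_baseline <- function(volumes, labels, cv_cfg = cv_config(),
                                enet_cfg = elastic_net_config(),
                                feature_name = "volume_cm3") {
  X <- matrix(as.numeric(volumes), ncol = 1,
              dimnames = list(NULL, feature_name))
  tab <- feature_table(X, labels)
  repeat_nested_cv(tab, cv_cfg, enet_cfg, skip_redundancy = TRUE)
}

#' Compare two metric distributions
#'
#' Two-sided non-parametric comparison: Wilcoxon signed-rank on paired
#' samples from matched repetition schedules, or the rank-sum
#' (Mann-Whitney U) test for unpaired distributions. Exact p-values are
#' used when the sample permits (no ties / small n), otherwise the normal
#' approximation.
#'
#' @param dist_a,dist_b Numeric metric values across repetitions.
#' @param paired Use the signed-rank test on matched repetitions.
#' @return List with `p_value`, `statistic`, and `method`.
#' @export
compare_metric_distributions <- function(dist_a, dist_b, paired = FALSE) {
  if (paired) {
    if (length(dist_a) != length(dist_b)) {
      stop("paired comparison needs equal-length distributions")
    }
    if (all(dist_a == dist_b)) {
      warning("all paired differences are zero; p = 1")
      return(list(p_value = 1, statistic = NA_real_,
                  method = "Wilcoxon signed-rank"))
    }
    ht <- suppressWarnings(stats::wilcox.test(dist_a, dist_b, paired = TRUE))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(dist_a, dist_b))
  }
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       method = ht$method)
}

#' Bonferroni-Holm adjustment
#'
#' @param p Vector of raw p-values.
#' @return Holm-adjusted p-values (same order).
#' @export
holm_adjust <- function(p) {
  stats::p.adjust(p, method = "holm")
}
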