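# Occurrence-count stability analysis: how often each feature receives a
# non-zero Elastic Net coefficient across all fitted model instances,
# selection of the relevant features, reduced refit on the curated set
# (same data partitions), and coefficient averaging.

#' Count non-zero coefficient occurrences across model instances
#'
#' @param models List of `fitted_crs_model`s (e.g. the `models` element of
#'   a [repeat_nested_cv()] result).
#' @param feature_names Optional universe of feature names; defaults to
#'   the union over models. Features a model never retained (dropped by
#'   the redundancy filter) count 0 for that model.
#' @return Named integer vector of occurrence counts, descending.
#' @export
count_occurrences <- function(models, feature_names = NULL) {
  if (length(models) < 1) stop("at least one model is required")
  if (is.null(feature_names)) {
    feature_names <- unique(unlist(lapply(models, `[[`, "features")))
  }
  counts <- stats::setNames(integer(length(feature_names)), feature_names)
  for (m in models) {
    nz <- names(m$beta)[m$beta != 0]
    nz <- intersect(nz, feature_names)
    counts[nz] <- counts[nz] + 1L
  }
  sort(counts, decreasing = TRUE)
}

#' Block-level occurrence analysis for cohorts with known redundancy
#'
#' When a cohort carries blocks of rank-correlated copies of the same
#' underlying measurement (as synthetic cohorts do by construction), the
#' embedded redundancy filter may retain a different block member in
#' different model instances, splitting that measurement's occurrence
#' count across column names. These helpers collapse the analysis to
#' blocks: a block occurs in an instance when any member has a non-zero
#' coefficient, and its per-instance coefficient is the sum over members
#' (at most one member survives filtering per instance).
#'
#' @param models List of `fitted_crs_model`s.
#' @param blocks Named list: block name -> character vector of member
#'   feature names (the block parent is added automatically if absent).
#' @return `block_occurrences`: named integer counts in deterministic
#'   order (descending count, ties by name). `block_mean_coefficients`:
#'   named numeric mean per-instance block coefficients (absent counted
#'   as 0).
#' @export
block_occurrences <- function(models, blocks) {
  blocks <- normalize_blocks(blocks)
  cnt <- vapply(blocks, function(members) {
    sum(vapply(models, function(m) {
      b <- m$beta[intersect(members, names(m$beta))]
      length(b) > 0 && any(b != 0)
    }, logical(1)))
  }, integer(1))
  cnt[order(-cnt, names(cnt))]
}

#' @rdname block_occurrences
#' @export
block_mean_coefficients <- function(models, blocks) {
  blocks <- normalize_blocks(blocks)
  vapply(blocks, function(members) {
    mean(vapply(models, function(m) {
      b <- m$beta[intersect(members, names(m$beta))]
      if (length(b)) sum(b) else 0
    }, numeric(1)))
  }, numeric(1))
}

#' @noRd
normalize_blocks <- function(blocks) {
  if (is.null(names(blocks))) stop("blocks must be a named list")
  stats::setNames(
    lapply(names(blocks), function(b) union(b, blocks[[b]])),
    names(blocks)
  )
}

#' Select relevant features by occurrence threshold
#'
#' Features selected strictly more often than `threshold_fraction` of the
#' model instances, plus any forced-in features (by default the
#' whole-tumor volume, included for clinical recognition). Ordered by
#' descending count, ties by name.
#'
#' @param counts Named occurrence counts from [count_occurrences()].
#' @param total Total number of model instances.
#' @param threshold_fraction Strict selection threshold as a fraction of
#'   `total` (default 0.6, i.e. more than 300 of 500 instances).
#' @param forced Character vector of features always included (default
#'   `"volume_cm3"`); ignored when absent from `counts`' universe is fine,
#'   they are appended regardless.
#' @return Character vector of selected feature names.
#' @export
select_relevant <- function(counts, total, threshold_fraction = 0.6,
                            forced = "volume_cm3") {
  if (total <= 0) stop("total must be positive")
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  sel <- names(counts)[counts > threshold_fraction * total]
  out <- union(sel, forced)
  if (length(out) == 0) {
    warning("no feature exceeded the occurrence threshold")
  }
  out
}

#' Refit on the reduced (curated) feature set
#'
#' Reruns the repeated nested CV restricted to the selected features with
#' identical seeds, hence identical fold partitions, and with the
#' redundancy filter skipped (the set is already curated). All other
#' stages (standardization, lambda selection, threshold optimization) are
#' unchanged.
#'
#' @param table The full [feature_table].
#' @param selected_features Features to keep (must exist in `table`).
#' @param cv_cfg,enet_cfg The same configurations as the full run.
#' @return A `repetition_results` object.
#' @export
refit_reduced <- function(table, selected_features,
                          cv_cfg = cv_config(),
                          enet_cfg = elastic_net_config()) {
  missing_f <- setdiff(selected_features, colnames(table$X))
  if (length(missing_f)) {
    stop("selected feature(s) not in table: ",
         paste(missing_f, collapse = ", "))
  }
  reduced <- feature_table(table$X[, selected_features, drop = FALSE],
                           table$labels, ids = table$ids)
  repeat_nested_cv(reduced, cv_cfg, enet_cfg, skip_redundancy = TRUE)
}

#' Average coefficients over model instances
#'
#' Arithmetic mean of each selected feature's Elastic Net coefficient over
#' model instances. Two conventions are reported side by side: the mean
#' over all instances (a feature absent from an instance - eliminated by
#' filtering or shrunk to exactly zero - contributes 0) and the mean over
#' only the instances where the coefficient is non-zero.
#'
#' @param models List of `fitted_crs_model`s.
#' @param selected_features Features to summarize.
#' @return Data frame with `feature`, `mean_coef` (all-instance mean, the
#'   default reporting convention), `mean_coef_when_selected`,
#'   `occurrences`, and `sign`.
#' @export
average_coefficients <- function(models, selected_features) {
  rows <- lapply(selected_features, function(f) {
    vals <- vapply(models, function(m) {
      if (f %in% names(m$beta)) unname(m$beta[f]) else 0
    }, numeric(1))
    nz <- vals[vals != 0]
    mean_all <- mean(vals)
    data.frame(
      feature = f,
      mean_coef = mean_all,
      mean_coef_when_selected = if (length(nz)) mean(nz) else 0,
      occurrences = sum(vals != 0),
      sign = if (mean_all > 0) "+" else if (mean_all < 0) "-" else "0"
    )
  })
  do.call(rbind, rows)
}

#' Build the full signature report
#'
#' Convenience wrapper: occurrence counts over a fitted run, relevant
#' feature selection, reduced refit with identical partitions, and
#' averaged coefficients of the reduced models.
#'
#' @param table The discovery [feature_table].
#' @param full_run A `repetition_results` from [repeat_nested_cv()].
#' @param threshold_fraction,forced Passed to [select_relevant()].
#' @param cv_cfg,enet_cfg Configurations (must match the full run for the
#'   partitions to be identical).
#' @return A `signature_report` list with `counts`, `total_instances`,
#'   `selected`, `reduced_run`, and `coefficients`.
#' @export
signature_report <- function(table, full_run, threshold_fraction = 0.6,
                             forced = "volume_cm3",
                             cv_cfg = full_run$cv_config,
                             enet_cfg = full_run$enet_config) {
  counts <- count_occurrences(full_run$models,
                              feature_names = colnames(table$X))
  total <- length(full_run$models)
  forced <- intersect(forced, colnames(table$X))
  selected <- select_relevant(counts, total, threshold_fraction, forced)
  reduced <- refit_reduced(table, selected, cv_cfg, enet_cfg)
  coefs <- average_coefficients(reduced$models, selected)
  structure(list(counts = counts, total_instances = total,
                 selected = selected, reduced_run = reduced,
                 coefficients = coefs),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("<signature_report> ", length(x$selected), " features selected from ",
      x$total_instances, " model instances\n", sep = "")
  df <- x$coefficients
  df$count <- x$counts[df$feature]
  print(df[, c("feature", "count", "mean_coef", "sign")], row.names = FALSE)
  invisible(x)
}

#' Serialize a signature report to JSON
#'
#' @param x A `signature_report`.
#' @param path Output path.
#' @export
write_signature_report <- function(x, path) {
  jsonlite::write_json(
    list(
      total_instances = x$total_instances,
      counts = as.list(x$counts),
      selected = x$selected,
      coefficients = x$coefficients
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
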