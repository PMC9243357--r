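# Synthetic feature-table cohorts: informative features with a logistic
# label model, rank-correlated redundant copies, and independent noise.
# These emulate the statistical structure the modeling pipeline assumes
# (correlated feature blocks at Spearman rho >= 0.90, a handful of truly
# predictive features, class imbalance) with known ground truth.

#' Feature table container
#'
#' A patient-by-feature numeric matrix with binary response labels
#' (1 = complete histopathologic response, CRS3; 0 = non-complete,
#' CRS1-2) and patient identifiers.
#'
#' @param X Numeric matrix, rows = patients, named columns = features.
#' @param labels Binary vector (0/1), one per row.
#' @param ids Optional character patient identifiers.
#' @return A `feature_table` object.
#' @export
feature_table <- function(X, labels, ids = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("one label per row is required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (any(!is.finite(X))) stop("feature matrix must not contain missing values")
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(X)))
  structure(list(X = X, labels = labels, ids = as.character(ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$X), " patients x ", ncol(x$X),
      " features; positives ", sum(x$labels), "/", length(x$labels),
      " (", round(100 * mean(x$labels)), "%)\n", sep = "")
  invisible(x)
}

#' @rdname feature_table
#' @param path CSV path. The file has a `patient_id` column, one column per
#'   feature, and a `label` column.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(patient_id = x$ids, x$X, label = x$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("patient_id", "label") %in% names(df))) {
    stop("feature CSV needs `patient_id` and `label` columns")
  }
  feat <- setdiff(names(df), c("patient_id", "label"))
  feature_table(as.matrix(df[feat]), df$label, ids = df$patient_id)
}

#' Cohort specification for synthetic feature tables
#'
#' @param n_patients Cohort size.
#' @param prevalence Target rate of label 1, strictly in (0, 1). Defaults
#'   mirror a discovery cohort of 61 patients with 41% complete responders.
#' @param n_informative Number of truly informative features.
#' @param n_noise Number of independent noise features.
#' @param n_redundant_per_block Rank-correlated copies added per
#'   informative feature.
#' @param effect_sizes Log-odds coefficients of the informative features
#'   (recycled to `n_informative`).
#' @param within_block_correlation Target Spearman correlation between a
#'   redundant copy and its block parent; must exceed the redundancy
#'   filter's threshold (> 0.90) so blocks are collapsible.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 61,
                        prevalence = 0.41,
                        n_informative = 5,
                        n_noise = 10,
                        n_redundant_per_block = 2,
                        effect_sizes = 1,
                        within_block_correlation = 0.95,
                        seed = 1L) {
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must be strictly between 0 and 1")
  }
  if (n_informative + n_noise < 1) stop("at least one feature is required")
  if (n_redundant_per_block > 0 &&
      !(within_block_correlation > 0.90 && within_block_correlation <= 1)) {
    stop("within_block_correlation must lie in (0.90, 1]")
  }
  effect_sizes <- rep_len(as.numeric(effect_sizes), max(n_informative, 1L))
  structure(as.list(environment()), class = "cohort_spec")
}

# A rank-preserving copy of `parent` with Spearman correlation close to
# (and at least) `target`: for target = 1 a strictly monotone transform;
# otherwise additive noise whose scale is tuned by bisection on the
# realized Spearman correlation.
#' @noRd
redundant_copy <- function(parent, target) {
  if (target >= 1) {
    return(parent + 0.05 * parent^3)
  }
  z <- stats::rnorm(length(parent))
  lo <- 0
  hi <- 4 * stats::sd(parent)
  s <- hi / 4
  for (i in 1:40) {
    child <- parent + s * z
    rho <- stats::cor(parent, child, method = "spearman")
    if (abs(rho - target) < 1e-3 && rho >= target) break
    if (rho > target) lo <- s else hi <- s
    s <- (lo + hi) / 2
  }
  child <- parent + lo * z  # lo always satisfies rho >= target
  if (stats::cor(parent, child, method = "spearman") >= target) child else parent + 0 * z
}

#' Generate a synthetic feature cohort
#'
#' Informative features are independent standard normals; labels are drawn
#' from a logistic model `logit P(y=1) = b0 + X_inf %*% effect_sizes` whose
#' intercept `b0` is solved numerically (root finding on the cohort's mean
#' predicted probability) so the expected positive rate equals the target
#' prevalence. Redundant copies are rank-preserving perturbations of their
#' block parent with Spearman correlation at least
#' `within_block_correlation`; noise features are independent of both the
#' informative features and the labels.
#'
#' Column naming: `inf_01 ...` informative, `inf_01_r1 ...` redundant
#' copies, `noise_01 ...` noise.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `table` (a [feature_table]) and `truth` (list with
#'   `informative`, `effect_sizes`, `intercept`, `blocks`).
#' @export
generate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  p_inf <- spec$n_informative

  cols <- list()
  if (p_inf > 0) {
    Xi <- matrix(stats::rnorm(n * p_inf), n, p_inf)
    colnames(Xi) <- sprintf("inf_%02d", seq_len(p_inf))
    eta <- drop(Xi %*% spec$effect_sizes)
  } else {
    Xi <- NULL
    eta <- rep(0, n)
  }

  f <- function(b0) mean(stats::plogis(b0 + eta)) - spec$prevalence
  if (f(-50) > 0 || f(50) < 0) {
    stop("infeasible prevalence/effect combination: intercept search cannot bracket")
  }
  b0 <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  labels <- stats::rbinom(n, 1, stats::plogis(b0 + eta))

  blocks <- list()
  if (p_inf > 0) {
    cols <- c(cols, lapply(seq_len(p_inf), function(j) Xi[, j]))
    names(cols) <- colnames(Xi)
    if (spec$n_redundant_per_block > 0) {
      for (j in seq_len(p_inf)) {
        kids <- character(0)
        for (r in seq_len(spec$n_redundant_per_block)) {
          nm <- sprintf("inf_%02d_r%d", j, r)
          cols[[nm]] <- redundant_copy(Xi[, j], spec$within_block_correlation)
          kids <- c(kids, nm)
        }
        blocks[[sprintf("inf_%02d", j)]] <- kids
      }
    }
  }
  if (spec$n_noise > 0) {
    Xn <- matrix(stats::rnorm(n * spec$n_noise), n, spec$n_noise)
    for (j in seq_len(spec$n_noise)) {
      cols[[sprintf("noise_%02d", j)]] <- Xn[, j]
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(
    table = feature_table(X, labels),
    truth = list(
      informative = if (p_inf > 0) colnames(Xi) else character(0),
      effect_sizes = if (p_inf > 0) stats::setNames(spec$effect_sizes, colnames(Xi)) else numeric(0),
      intercept = b0,
      blocks = blocks
    )
  )
}
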