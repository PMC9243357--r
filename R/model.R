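# Elastic Net logistic modeling inside a nested k-fold cross-validation
# (default 5 x 5) repeated over random permutations of the discovery
# cohort. Supervised steps (redundancy filtering, standardization, lambda
# selection, threshold optimization) only ever see training partitions;
# outer-test rows are scored exactly once per repetition.

#' Cross-validation configuration
#'
#' @param k_outer,k_inner Outer and inner fold counts (default 5 and 5).
#' @param n_repetitions Number of random-permutation repetitions of the
#'   whole nested procedure (default 100, yielding
#'   `n_repetitions * k_outer` fitted model instances).
#' @param stratified Stratify fold assignment by class (default TRUE;
#'   with 21-41% positives unstratified 5-fold splits easily produce
#'   single-class folds).
#' @param base_seed Integer seed from which all fold permutations derive.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_outer = 5, k_inner = 5, n_repetitions = 100,
                      stratified = TRUE, base_seed = 1L) {
  if (k_outer < 2 || k_inner < 2) stop("fold counts must be at least 2")
  structure(list(k_outer = k_outer, k_inner = k_inner,
                 n_repetitions = n_repetitions, stratified = stratified,
                 base_seed = as.integer(base_seed)),
            class = "cv_config")
}

#' Elastic Net configuration
#'
#' @param alpha Mixing parameter in `[0, 1]` between the L1 (`alpha = 1`)
#'   and L2 (`alpha = 0`) penalties; default 0.5.
#' @param n_lambda Length of the log-spaced shrinkage grid (>= 50).
#' @param lambda_min_ratio Smallest grid value relative to the largest.
#' @param tol Optimizer convergence threshold.
#' @param maxit Maximum optimizer iterations.
#' @return An `enet_config` list.
#' @export
elastic_net_config <- function(alpha = 0.5, n_lambda = 100,
                               lambda_min_ratio = 1e-3,
                               tol = 1e-8, maxit = 1e5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (n_lambda < 50) stop("lambda grid must have at least 50 values")
  structure(list(alpha = alpha, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 tol = tol, maxit = maxit),
            class = "enet_config")
}

# Descending log-spaced lambda grid anchored at the smallest lambda that
# zeroes all coefficients (lasso limit, floored for small alpha).
#' @noRd
lambda_grid <- function(X, y, config) {
  n <- nrow(X)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / (n * max(config$alpha, 0.01))
  lam_max <- max(lam_max, 1e-4)
  exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

#' Fit a penalized logistic regression at a single shrinkage value
#'
#' Minimizes the mean binomial deviance plus
#' `lambda * (alpha * ||beta||_1 + (1 - alpha) * ||beta||_2^2 / 2)` with an
#' unpenalized intercept, via coordinate descent (glmnet). `X` is expected
#' to be standardized already; no internal standardization is applied.
#'
#' @param X Standardized numeric matrix (named columns).
#' @param y Binary 0/1 response with both classes present.
#' @param lambda Positive shrinkage value.
#' @param alpha Elastic-net mixing parameter.
#' @param config An [elastic_net_config()] (for tolerance and iterations).
#' @return List with `beta` (named coefficient vector) and `beta0`
#'   (intercept).
#' @export
fit_elastic_net <- function(X, y, lambda, alpha = 0.5,
                            config = elastic_net_config(alpha = alpha)) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  # glmnet needs >= 2 columns; a constant zero column has zero gradient and
  # stays at coefficient 0 under the penalty, so it never alters the fit
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, .pad = 0)
  path <- sort(unique(c(lambda * c(16, 8, 4, 2), lambda)), decreasing = TRUE)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                      lambda = path, standardize = FALSE,
                      thresh = config$tol, maxit = config$maxit)
  cf <- as.matrix(stats::coef(g, s = lambda, exact = FALSE))[, 1]
  beta <- cf[-1]
  if (padded) beta <- beta[names(beta) != ".pad"]
  list(beta = beta, beta0 = unname(cf[1]), lambda = lambda)
}

#' @noRd
binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Stratified fold assignment
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed for the permutation.
#' @param stratified Keep class proportions per fold.
#' @return Integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(y, k, seed, stratified = TRUE) {
  set.seed(seed)
  fold <- integer(length(y))
  if (stratified) {
    if (min(table(y)) < k) {
      stop("stratification impossible: a class has fewer members than folds")
    }
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(seq_along(y))] <- rep_len(seq_len(k), length(y))
  }
  fold
}

#' Select the shrinkage value by inner-fold deviance
#'
#' Evaluates a shared descending lambda grid by k-fold cross-validated
#' mean binomial deviance and returns the minimizer; ties go to the larger
#' (more parsimonious) lambda.
#'
#' @param X Standardized training matrix.
#' @param y Binary labels.
#' @param config An [elastic_net_config()].
#' @param folds Optional precomputed fold ids; defaults to stratified
#'   folds from `seed`.
#' @param k Number of folds when `folds` is NULL.
#' @param seed Seed for default fold assignment.
#' @param grid Optional lambda grid; derived from the data when NULL.
#' @return List with `lambda`, `grid`, and `mean_deviance` per grid value.
#' @export
select_lambda <- function(X, y, config = elastic_net_config(), folds = NULL,
                          k = 5, seed = 1L, grid = NULL) {
  X <- as.matrix(X)
  if (is.null(grid)) grid <- lambda_grid(X, y, config)
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  dev <- matrix(NA_real_, max(folds), length(grid))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xi <- X[tr, , drop = FALSE]
    padded <- ncol(Xi) == 1
    if (padded) Xi <- cbind(Xi, .pad = 0)
    g <- glmnet::glmnet(Xi, y[tr], family = "binomial", alpha = config$alpha,
                        lambda = grid, standardize = FALSE,
                        thresh = config$tol, maxit = config$maxit)
    Xv <- X[!tr, , drop = FALSE]
    if (padded) Xv <- cbind(Xv, .pad = 0)
    p <- stats::predict(g, newx = Xv, s = grid, type = "response",
                        exact = FALSE)
    dev[f, ] <- apply(p, 2, function(pp) binomial_deviance(y[!tr], pp))
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(mean_dev)  # grid is descending: first minimum = largest
  list(lambda = grid[best], grid = grid, mean_deviance = mean_dev)
}

#' Optimize the decision threshold by G-mean
#'
#' Sweeps the midpoints of the sorted unique validation scores and returns
#' the threshold maximizing the G-mean
#' `sqrt(sensitivity * specificity)` of the classification
#' `score >= threshold`; ties go to the smallest threshold. With fewer
#' than two distinct scores the single score value is returned (G-mean is
#' 0 everywhere in that degenerate case).
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param labels Binary labels; both classes must be present.
#' @return Scalar threshold.
#' @export
optimize_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes are needed to optimize a threshold")
  }
  u <- sort(unique(scores))
  if (length(u) < 2) return(u[1])
  cand <- (u[-1] + u[-length(u)]) / 2
  gm <- vapply(cand, function(t) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    sqrt(sens * spec)
  }, numeric(1))
  cand[which.max(gm)]  # which.max returns the first (smallest) maximizer
}

# One outer fold: embedded inner loop for filtering/standardization/lambda/
# threshold, final refit on the full outer-training partition.
#' @noRd
fit_outer_fold <- function(X, y, outer_train, cv_cfg, enet_cfg, rep_index,
                           fold_index, skip_redundancy = FALSE) {
  Xtr <- X[outer_train, , drop = FALSE]
  ytr <- y[outer_train]

  feats_final <- if (skip_redundancy) colnames(Xtr) else
    redundancy_filter(Xtr, ytr)
  zs_final <- zscore_fit(Xtr[, feats_final, drop = FALSE])
  feats_final <- zs_final$features
  Xtr_s <- zscore_apply(Xtr, zs_final)
  grid <- lambda_grid(Xtr_s, ytr, enet_cfg)

  inner_folds <- stratified_folds(
    ytr, cv_cfg$k_inner,
    seed = derive_seed(cv_cfg$base_seed, "inner", rep_index, fold_index),
    stratified = cv_cfg$stratified
  )
  dev <- matrix(NA_real_, cv_cfg$k_inner, length(grid))
  val_prob <- vector("list", cv_cfg$k_inner)
  for (f in seq_len(cv_cfg$k_inner)) {
    tr <- inner_folds != f
    fi <- if (skip_redundancy) colnames(Xtr) else
      redundancy_filter(Xtr[tr, , drop = FALSE], ytr[tr])
    zs <- zscore_fit(Xtr[tr, fi, drop = FALSE])
    Xi <- zscore_apply(Xtr[tr, , drop = FALSE], zs)
    padded <- ncol(Xi) == 1
    if (padded) Xi <- cbind(Xi, .pad = 0)
    g <- glmnet::glmnet(Xi, ytr[tr], family = "binomial",
                        alpha = enet_cfg$alpha, lambda = grid,
                        standardize = FALSE, thresh = enet_cfg$tol,
                        maxit = enet_cfg$maxit)
    Xv <- zscore_apply(Xtr[!tr, , drop = FALSE], zs)
    if (padded) Xv <- cbind(Xv, .pad = 0)
    p <- stats::predict(g, newx = Xv, s = grid, type = "response",
                        exact = FALSE)
    dev[f, ] <- apply(p, 2, function(pp) binomial_deviance(ytr[!tr], pp))
    val_prob[[f]] <- list(rows = which(!tr), p = p)
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(mean_dev)
  lambda_star <- grid[best]

  inner_scores <- numeric(length(ytr))
  for (f in seq_len(cv_cfg$k_inner)) {
    inner_scores[val_prob[[f]]$rows] <- val_prob[[f]]$p[, best]
  }
  tau <- optimize_threshold(inner_scores, ytr)

  fit <- fit_elastic_net(Xtr_s[, feats_final, drop = FALSE], ytr,
                         lambda = lambda_star, alpha = enet_cfg$alpha,
                         config = enet_cfg)
  structure(list(
    features = feats_final,
    zscore = zs_final,
    beta = fit$beta,
    beta0 = fit$beta0,
    lambda = lambda_star,
    tau = tau,
    repetition = rep_index,
    outer_fold = fold_index,
    rows_train = outer_train
  ), class = "fitted_crs_model")
}

#' Predict with a fitted model
#'
#' Standardizes with the model's own training parameters, applies the
#' logistic linear predictor, and (optionally) thresholds at the model's
#' optimized decision threshold.
#'
#' @param object A `fitted_crs_model`.
#' @param newdata Numeric matrix containing at least the model's features.
#' @param type `"response"` for probabilities, `"class"` for 0/1 votes at
#'   the model threshold.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer classes.
#' @export
predict.fitted_crs_model <- function(object, newdata,
                                     type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xs <- zscore_apply(newdata, object$zscore)
  eta <- drop(Xs[, object$features, drop = FALSE] %*%
                object$beta[object$features]) + object$beta0
  p <- stats::plogis(eta)
  if (type == "class") as.integer(p >= object$tau) else p
}

#' One nested cross-validation pass
#'
#' Runs the full leakage-safe nested CV once: for every outer fold, the
#' inner loop applies the supervised redundancy filter and z-score
#' standardization on inner-training data only, selects the shrinkage
#' value minimizing mean inner-validation deviance, optimizes the decision
#' threshold on pooled inner-validation predictions, and refits on the
#' full outer-training partition. Every row is scored exactly once as an
#' outer-test observation.
#'
#' @param table A [feature_table].
#' @param cv_cfg A [cv_config()].
#' @param enet_cfg An [elastic_net_config()].
#' @param rep_index Repetition number (determines the fold permutation via
#'   the config's base seed).
#' @param skip_redundancy Skip the redundancy filter (used for reduced
#'   refits on already-curated feature sets and single-feature baselines).
#' @return List with `models` (k_outer `fitted_crs_model`s),
#'   `predictions` (data frame: row, label, score, class, fold), and
#'   `metrics` (from [compute_metrics()] on the pooled outer predictions).
#' @export
nested_cv_run <- function(table, cv_cfg = cv_config(),
                          enet_cfg = elastic_net_config(),
                          rep_index = 1L, skip_redundancy = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$X
  y <- table$labels
  outer_folds <- stratified_folds(
    y, cv_cfg$k_outer,
    seed = derive_seed(cv_cfg$base_seed, "outer", rep_index),
    stratified = cv_cfg$stratified
  )
  models <- vector("list", cv_cfg$k_outer)
  score <- numeric(length(y))
  class <- integer(length(y))
  for (o in seq_len(cv_cfg$k_outer)) {
    tr <- which(outer_folds != o)
    te <- which(outer_folds == o)
    m <- fit_outer_fold(X, y, tr, cv_cfg, enet_cfg, rep_index, o,
                        skip_redundancy = skip_redundancy)
    models[[o]] <- m
    score[te] <- predict(m, X[te, , drop = FALSE], type = "response")
    class[te] <- as.integer(score[te] >= m$tau)
  }
  preds <- data.frame(row = seq_along(y), label = y, score = score,
                      class = class, fold = outer_folds)
  list(models = models, predictions = preds,
       metrics = compute_metrics(class, score, y))
}

#' Repeated nested cross-validation
#'
#' Repeats [nested_cv_run()] over `n_repetitions` random permutations of
#' the cohort (different fold assignments per repetition, all derived from
#' the base seed), producing `n_repetitions * k_outer` fitted model
#' instances and a per-repetition metrics table.
#'
#' @inheritParams nested_cv_run
#' @return A `repetition_results` list with `models` (flat list of all
#'   instances), `metrics` (one row per repetition), `runs` (per-repetition
#'   outputs), and the configs.
#' @export
repeat_nested_cv <- function(table, cv_cfg = cv_config(),
                             enet_cfg = elastic_net_config(),
                             skip_redundancy = FALSE) {
  runs <- lapply(seq_len(cv_cfg$n_repetitions), function(r) {
    nested_cv_run(table, cv_cfg, enet_cfg, rep_index = r,
                  skip_redundancy = skip_redundancy)
  })
  metrics <- do.call(rbind, lapply(seq_along(runs), function(r) {
    data.frame(repetition = r, t(unlist(runs[[r]]$metrics)))
  }))
  structure(list(
    models = do.call(c, lapply(runs, `[[`, "models")),
    metrics = metrics,
    runs = runs,
    cv_config = cv_cfg,
    enet_config = enet_cfg
  ), class = "repetition_results")
}

#' @export
print.repetition_results <- function(x, ...) {
  cat("<repetition_results> ", length(x$models), " model instances (",
      x$cv_config$n_repetitions, " repetitions x ", x$cv_config$k_outer,
      " outer folds)\n", sep = "")
  cat("mean outer AUC ", round(mean(x$metrics$auc), 3),
      " +/- ", round(stats::sd(x$metrics$auc), 3), "\n", sep = "")
  invisible(x)
}
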