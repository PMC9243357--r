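# Elastic Net fitting, shrinkage selection, threshold optimization, and
# the leakage-safe nested cross-validation.

std <- function(X) scale(X)[, , drop = FALSE]

test_that("full shrinkage collapses to the intercept-only model", {
  set.seed(1)
  n <- 80
  X <- std(matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4))))
  y <- rbinom(n, 1, 0.4)
  fit <- fit_elastic_net(X, y, lambda = 50, alpha = 0.5)
  expect_true(all(fit$beta == 0))
  expect_equal(plogis(fit$beta0), mean(y), tolerance = 1e-6)
})

test_that("vanishing ridge penalty recovers the IRLS (glm) solution", {
  set.seed(2)
  n <- 300
  X <- std(matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c"))))
  eta <- 0.8 * X[, 1] - 0.5 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_elastic_net(X, y, lambda = 1e-8, alpha = 0)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)[-1]), tolerance = 1e-4)
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("ridge shares the coefficient between duplicated columns", {
  set.seed(3)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x))
  X <- cbind(x1 = x, x2 = x)
  fit <- fit_elastic_net(X, y, lambda = 0.05, alpha = 0)
  expect_equal(unname(fit$beta["x1"]), unname(fit$beta["x2"]), tolerance = 1e-3)
})

test_that("single-feature fits work (zero-padding trick is inert)", {
  set.seed(4)
  n <- 150
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  X1 <- matrix(x, ncol = 1, dimnames = list(NULL, "only"))
  fit <- fit_elastic_net(X1, y, lambda = 1e-8, alpha = 0)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$beta["only"]), unname(coef(ref)[2]), tolerance = 1e-3)
  expect_false(".pad" %in% names(fit$beta))
})

test_that("lambda selection prefers the null model on pure noise", {
  set.seed(5)
  n <- 100
  X <- std(matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("n", 1:8))))
  y <- rbinom(n, 1, 0.4)
  sel <- select_lambda(X, y, seed = 7)
  expect_gte(sel$lambda, sel$grid[5])  # at or very near the top of the grid

  # strong predictor: interior lambda, better-than-null deviance
  set.seed(6)
  n <- 400
  X2 <- std(matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("s", 1:5))))
  y2 <- rbinom(n, 1, plogis(2 * X2[, 1]))
  sel2 <- select_lambda(X2, y2, seed = 8)
  expect_lt(sel2$lambda, sel2$grid[2])
  expect_gt(sel2$lambda, min(sel2$grid))
  null_dev <- -2 * mean(y2 * log(mean(y2)) + (1 - y2) * log(1 - mean(y2)))
  expect_lt(min(sel2$mean_deviance), null_dev)
  # exhaustive-grid check: the reported lambda minimizes the reported curve
  expect_equal(sel2$mean_deviance[match(sel2$lambda, sel2$grid)],
               min(sel2$mean_deviance))
  # repeatability
  sel2b <- select_lambda(X2, y2, seed = 8)
  expect_identical(sel2, sel2b)
})

test_that("non-zero count shrinks monotonically along the lambda grid", {
  set.seed(9)
  n <- 120
  X <- std(matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6))))
  y <- rbinom(n, 1, plogis(X %*% c(1.5, -1, 0.7, 0, 0, 0)))
  grid <- exp(seq(log(0.5), log(0.001), length.out = 25))
  nnz <- vapply(grid, function(l) {
    sum(fit_elastic_net(X, y, lambda = l, alpha = 0.5)$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))  # grid descends, support grows
})

test_that("threshold optimization matches an exhaustive midpoint sweep", {
  # perfectly separated: smallest optimal midpoint, G-mean 1
  sc <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  lb <- c(0, 0, 0, 1, 1)
  tau <- optimize_threshold(sc, lb)
  expect_equal(tau, 0.55)
  expect_equal(sqrt(mean(sc[lb == 1] >= tau) * mean(sc[lb == 0] < tau)), 1)

  # 8-point toy set against brute force
  set.seed(10)
  sc2 <- round(runif(8), 3)
  lb2 <- c(0, 1, 0, 1, 1, 0, 0, 1)
  u <- sort(unique(sc2))
  cand <- (u[-1] + u[-length(u)]) / 2
  gm <- vapply(cand, function(t) {
    sqrt(mean(sc2[lb2 == 1] >= t) * mean(sc2[lb2 == 0] < t))
  }, numeric(1))
  expect_equal(optimize_threshold(sc2, lb2), cand[which.max(gm)])

  # degenerate identical scores
  expect_equal(optimize_threshold(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.4)
  expect_error(optimize_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("stratified folds keep both classes in every fold", {
  y <- rep(c(0, 1), c(36, 25))
  f <- stratified_folds(y, 5, seed = 3)
  tab <- table(f, y)
  expect_true(all(tab > 0))
  expect_identical(stratified_folds(y, 5, seed = 3),
                   stratified_folds(y, 5, seed = 3))
  expect_error(stratified_folds(rep(c(0, 1), c(58, 3)), 5, seed = 1),
               "stratification impossible")
})

test_that("nested CV scores each row exactly once and is reproducible", {
  co <- generate_feature_cohort(cohort_spec(
    n_patients = 61, prevalence = 0.41, n_informative = 3, n_noise = 6,
    n_redundant_per_block = 1, seed = 51
  ))
  run <- nested_cv_run(co$table, cv_config(base_seed = 61))
  expect_length(run$models, 5)
  expect_identical(sort(run$predictions$row), 1:61)
  expect_identical(run$predictions$label, co$table$labels)

  run2 <- nested_cv_run(co$table, cv_config(base_seed = 61))
  expect_equal(run, run2)
})

test_that("outer-test rows never influence fitted parameters (leakage sentinel)", {
  co <- generate_feature_cohort(cohort_spec(
    n_patients = 60, prevalence = 0.4, n_informative = 3, n_noise = 5,
    n_redundant_per_block = 0, seed = 52
  ))
  cvc <- cv_config(base_seed = 71)
  run <- nested_cv_run(co$table, cvc)
  folds <- stratified_folds(co$table$labels, 5,
                            seed = crsradiomics:::derive_seed(71, "outer", 1))
  # corrupt the fold-1 test rows; the fold-1 model must be unchanged
  X2 <- co$table$X
  set.seed(99)
  X2[folds == 1, ] <- matrix(rnorm(sum(folds == 1) * ncol(X2)),
                             ncol = ncol(X2))
  tab2 <- feature_table(X2, co$table$labels)
  run2 <- nested_cv_run(tab2, cvc)
  m1 <- run$models[[1]]
  m2 <- run2$models[[1]]
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$tau, m2$tau)
  expect_identical(m1$zscore, m2$zscore)
  # predictions for those rows do change
  expect_false(isTRUE(all.equal(run$predictions$score[folds == 1],
                                run2$predictions$score[folds == 1])))
  # training and evaluation row sets are disjoint for every model
  for (m in run$models) {
    expect_length(intersect(m$rows_train, which(folds == m$outer_fold)), 0)
  }
})

test_that("repetition bookkeeping: counts and determinism", {
  co <- generate_feature_cohort(cohort_spec(
    n_patients = 50, prevalence = 0.4, n_informative = 2, n_noise = 4,
    n_redundant_per_block = 0, seed = 53
  ))
  run <- repeat_nested_cv(co$table, cv_config(n_repetitions = 2, base_seed = 81))
  expect_length(run$models, 10)
  expect_identical(nrow(run$metrics), 2L)
  run2 <- repeat_nested_cv(co$table, cv_config(n_repetitions = 2, base_seed = 81))
  expect_equal(run$metrics, run2$metrics)
})
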