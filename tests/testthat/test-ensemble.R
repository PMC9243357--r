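# Majority voting, ensemble prediction, the metric panel, the volumetric
# baseline, and non-parametric comparisons.

make_member <- function(feature, beta, beta0 = 0, tau = 0.5, mu = 0, sd = 1) {
  structure(list(
    features = feature,
    zscore = structure(list(mean = setNames(mu, feature),
                            sd = setNames(sd, feature), features = feature),
                       class = "zscore_params"),
    beta = setNames(beta, feature), beta0 = beta0, lambda = 0.1, tau = tau
  ), class = "fitted_crs_model")
}

test_that("majority vote agrees with exhaustive counting over all 2^5 patterns", {
  pats <- expand.grid(rep(list(0:1), 5))
  for (r in seq_len(nrow(pats))) {
    v <- as.integer(pats[r, ])
    expect_identical(majority_vote(v), as.integer(sum(v) >= 3))
  }
  expect_identical(majority_vote(c(1, 1, 1, 0, 0)), 1L)
  expect_identical(majority_vote(rep(0, 5)), 0L)
  expect_error(majority_vote(c(0, 1)), "odd")
})

test_that("ensemble prediction uses member-wise standardization and votes", {
  X <- matrix(c(-2, -0.5, 0.5, 2), ncol = 1, dimnames = list(NULL, "f"))
  same <- lapply(1:5, function(i) make_member("f", beta = 2))
  ens <- ensemble_model(same)
  ep <- ensemble_predict(ens, X)
  single <- predict(same[[1]], X, type = "class")
  expect_identical(ep$class, single)
  expect_equal(ep$score, predict(same[[1]], X, type = "response"))

  # 3 votes vs 2: class follows the majority regardless of probabilities
  members <- c(
    lapply(1:3, function(i) make_member("f", beta = 2, tau = 0.01)),   # vote 1
    lapply(1:2, function(i) make_member("f", beta = 2, tau = 0.9999))  # vote 0
  )
  ep2 <- ensemble_predict(ensemble_model(members), X)
  expect_true(all(ep2$class == 1L))

  # perturbing member probabilities without crossing thresholds cannot
  # change the class
  shifted <- c(
    lapply(1:3, function(i) make_member("f", beta = 2, beta0 = 0.5, tau = 0.01)),
    lapply(1:2, function(i) make_member("f", beta = 2, beta0 = 0.5, tau = 0.9999))
  )
  ep3 <- ensemble_predict(ensemble_model(shifted), X)
  expect_identical(ep3$class, ep2$class)
  expect_false(isTRUE(all.equal(ep3$score, ep2$score)))

  expect_error(ensemble_predict(ensemble_model(same),
                                matrix(1, 2, 1, dimnames = list(NULL, "g"))),
               "lacks")
  expect_error(ensemble_model(same[1:4]), "odd")
})

test_that("metric panel follows confusion-matrix definitions", {
  m <- compute_metrics(c(1, 1, 0, 0), c(.9, .8, .2, .1), c(1, 1, 0, 0))
  expect_true(all(unlist(m) == 1))

  # always-negative classifier on a 21%-positive cohort
  lab <- rep(c(1, 0), c(10, 38))
  m2 <- suppressWarnings(compute_metrics(rep(0, 48), NULL, lab))
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$gmean, 0)
  expect_equal(m2$npv, 38 / 48)
  expect_warning(compute_metrics(rep(0, 48), NULL, lab), "PPV undefined")

  # no positives in the reference: sensitivity is NA, not 0
  w <- capture_warnings(m3 <- compute_metrics(c(0, 1), c(.2, .8), c(0, 0)))
  expect_true(any(grepl("sensitivity undefined", w)))
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$gmean))

  # AUC equals brute-force pairwise concordance on a 20-point set
  set.seed(20)
  sc <- round(runif(20), 2)  # duplicates force tie handling
  lb <- rbinom(20, 1, 0.5)
  m4 <- compute_metrics(as.integer(sc > .5), sc, lb)
  expect_equal(m4$auc, oracle_auc(sc, lb), tolerance = 1e-12)
  expect_equal(m4$gmean, sqrt(m4$sensitivity * m4$specificity))
})

test_that("volumetric baseline is a null model when volume carries no signal", {
  set.seed(30)
  vols <- rlnorm(60, log(50), 0.6)
  labs <- rbinom(60, 1, 0.4)
  run <- volumetric_baseline(vols, labs, cv_config(n_repetitions = 4,
                                                   base_seed = 17))
  expect_length(run$models, 20)
  expect_gt(mean(run$metrics$auc), 0.3)
  expect_lt(mean(run$metrics$auc), 0.7)
  run2 <- volumetric_baseline(vols, labs, cv_config(n_repetitions = 4,
                                                    base_seed = 17))
  expect_equal(run$metrics, run2$metrics)
})

test_that("volume shifted down for responders becomes predictive", {
  set.seed(31)
  labs <- rep(c(1, 0), c(25, 36))
  # responders' median volume about 0.44x that of non-responders
  vols <- rlnorm(61, log(ifelse(labs == 1, 36.9, 84.6)), 0.5)
  run <- volumetric_baseline(vols, labs, cv_config(n_repetitions = 4,
                                                   base_seed = 18))
  expect_gt(mean(run$metrics$auc), 0.6)
})

test_that("rank-sum, signed-rank and Holm behave like the textbook cases", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2 / choose(6,3)
  cmp <- compare_metric_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$p_value, 0.1)
  expect_equal(2 / choose(6, 3), 0.1)

  expect_warning(eq <- compare_metric_distributions(1:5 / 10, 1:5 / 10,
                                                    paired = TRUE),
                 "zero")
  expect_equal(eq$p_value, 1)

  set.seed(40)
  a <- rnorm(20); b <- a + 0.5
  p <- compare_metric_distributions(a, b, paired = TRUE)$p_value
  expect_lt(p, 0.01)

  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # sorted: 0.01*3 = 0.03, 0.03*2 = 0.06, then the step-down maximum
  # carries 0.06 over the smaller 0.04*1
  expect_equal(holm_adjust(c(0.03, 0.01, 0.04)), c(0.06, 0.03, 0.06))
})
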