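test_that("survival dichotomization labels, excludes and errors as specified", {
  tab <- data.frame(patient = c("p1", "p2", "p3", "p4", "p5"),
                    time = c(1.5, 3.0, 1.0, 2.5, 2.0),
                    event = c(1, 0, 0, 1, 1))
  res <- dichotomize_survival(tab, threshold = 2)
  expect_equal(unname(res$labels["p1"]), 1L)   # event before threshold
  expect_equal(unname(res$labels["p2"]), 0L)   # censored beyond threshold
  expect_equal(res$excluded, "p3")             # censored before threshold
  expect_equal(unname(res$labels["p4"]), 0L)   # event after threshold
  expect_equal(unname(res$labels["p5"]), 1L)   # event at threshold counts
  all_excluded <- data.frame(patient = "x", time = 0.5, event = 0)
  expect_error(dichotomize_survival(all_excluded, 2), "no patients")
})

test_that("mRMR picks label-identical features first and shuns duplicates", {
  set.seed(61)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  perfect <- labels + 0.001 * rnorm(n)
  feats <- cbind(perfect = perfect,
                 dup = perfect,           # exact duplicate: full redundancy
                 weak = labels + rnorm(n),
                 noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- mrmr_select(feats, labels, 2)
  expect_equal(sel[1], 1)            # maximal mutual information
  expect_false(sel[2] == 2)          # duplicate penalized by redundancy
  # label-independent noise ranks below a deterministic dependence
  sel3 <- mrmr_select(feats[, c(4, 5, 3)], labels, 1)
  expect_equal(sel3, 3)
})

test_that("mRMR is deterministic and never prefers constant features", {
  set.seed(62)
  labels <- rep(0:1, 25)
  feats <- cbind(const = rep(1, 50), info = labels + rnorm(50, 0, 0.3))
  expect_equal(mrmr_select(feats, labels, 1), 2)
  expect_identical(mrmr_select(feats, labels, 2),
                   mrmr_select(feats, labels, 2))
})

test_that("AUC is the tie-aware pairwise probability", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 1, 0)), 0)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  # Mann-Whitney identity on random inputs
  set.seed(63)
  for (i in 1:50) {
    sc <- sample(1:8, 20, replace = TRUE)  # ties included
    lb <- rbinom(20, 1, 0.5)
    if (length(unique(lb)) < 2) next
    pairs <- outer(sc[lb == 1], sc[lb == 0],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(sc, lb), mean(pairs), tolerance = 1e-12)
  }
})

test_that("MCC evaluates the confusion formula with the zero convention", {
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(mcc(3, fp = 1, tn = 4, fn = 2), 10 / sqrt(600))
  expect_equal(mcc(rep(1, 6), rbinom(6, 1, 0.5)), 0)   # one-class prediction
  # symmetry under simultaneous label/prediction flip
  set.seed(64)
  pred <- rbinom(30, 1, 0.5); truth <- rbinom(30, 1, 0.5)
  expect_equal(mcc(pred, truth), mcc(1 - pred, 1 - truth))
})

test_that("Kaplan-Meier estimator matches the hand product-limit example", {
  km <- km_estimator(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  expect_equal(km$surv_fn(1), 0.75)
  expect_equal(km$surv_fn(2), 0.375)
  expect_equal(km$surv_fn(0.5), 1)
  # all censored -> S identically 1
  km2 <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km2$surv_fn(c(0.5, 2.5)), c(1, 1))
  # no censoring: empirical survival function, steps of 1/n
  km3 <- km_estimator(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(km3$surv, c(0.75, 0.5, 0.25, 0))
  expect_error(km_estimator(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test is null for identical groups and matches survdiff", {
  t1 <- c(1, 2, 3, 4); e1 <- c(1, 0, 1, 1)
  res <- logrank_test(t1, e1, t1, e1)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  # no events at all
  res0 <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # worked 6-subject example against an explicit risk-table computation
  time1 <- c(1, 3, 5); ev1 <- c(1, 1, 0)
  time2 <- c(2, 4, 6); ev2 <- c(1, 1, 1)
  res6 <- logrank_test(time1, ev1, time2, ev2)
  o_minus_e <- 0; v <- 0
  all_t <- sort(unique(c(time1[ev1 == 1], time2[ev2 == 1])))
  for (t in all_t) {
    n1 <- sum(time1 >= t); n2 <- sum(time2 >= t); n <- n1 + n2
    d1 <- sum(time1 == t & ev1 == 1); d2 <- sum(time2 == t & ev2 == 1)
    d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  expect_equal(res6$statistic, o_minus_e^2 / v, tolerance = 1e-10)
})

test_that("stratification success rate counts p < 0.05", {
  expect_equal(stratification_success_rate(c(0.01, 0.2, 0.03)), 2 / 3)
  expect_equal(stratification_success_rate(c(0.5, 0.06)), 0)
  expect_equal(stratification_success_rate(c(0.001, 0.04)), 1)
  expect_error(stratification_success_rate(numeric(0)), "empty")
})

test_that("cv_spec validates and carries the documented defaults", {
  spec <- cv_spec()
  expect_equal(spec$outer_folds, 5L)
  expect_equal(spec$inner_folds, 3L)
  expect_equal(spec$iterations, 10L)
  expect_equal(spec$feature_sizes, seq(5L, 40L, 5L))
  expect_error(cv_spec(outer_folds = 1))
  expect_error(cv_spec(feature_sizes = c(10, 5)))
})

test_that("nested CV separates separable classes and partitions the cohort", {
  set.seed(65)
  n <- 120; ngene <- 60
  labels <- rep(0:1, each = n / 2)
  feats <- matrix(2^rnorm(n * ngene, 6), n, ngene)
  feats[, 1:10] <- feats[, 1:10] * 2^(3 * labels)   # strong signal genes
  colnames(feats) <- sprintf("g%02d", 1:ngene)
  spec <- cv_spec(iterations = 1, feature_sizes = c(5, 10), seed = 7)
  res <- nested_cv(feats, labels, spec)
  expect_gte(res$mean_auc, 0.95)
  expect_gte(res$mean_mcc, 0.8)
  # held-out predictions cover each patient exactly once per iteration
  expect_equal(sort(res$predictions$index), seq_len(n))
})

test_that("all three classifier plug-ins satisfy the fit/score contract", {
  set.seed(66)
  n <- 80
  labels <- rep(0:1, each = n / 2)
  x <- cbind(matrix(rnorm(n * 4), n, 4), signal = labels + rnorm(n, 0, 0.3))
  for (nm in c("logistic", "svm", "boosting")) {
    clf <- make_classifier(nm)
    mod <- clf$fit(x, labels)
    sc <- clf$score(mod, x)
    expect_length(sc, n)
    expect_true(all(sc >= 0 & sc <= 1), label = nm)
    expect_gt(auc(sc, labels), 0.8)
  }
})
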