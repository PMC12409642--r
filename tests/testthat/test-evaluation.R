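# Metrics, repeated cross-validation and between-model comparison.

test_that("AUC equals U/(n_pos*n_neg) with ties counted one half", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(167)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    a <- auc(scores, labels)
    expect_equal(a, trapezoid_auc(scores, labels), tolerance = 1e-12)
    # rank-based identity: U statistic over product of class sizes
    U <- sum(rank(scores)[labels == 1]) -
      sum(labels == 1) * (sum(labels == 1) + 1) / 2
    expect_equal(a, U / (sum(labels == 1) * sum(labels == 0)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(173)
  for (i in 1:10) {
    scores <- runif(50)
    labels <- rbinom(50, 1, 0.6)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels),
                 as.numeric(pROC::auc(labels, scores, quiet = TRUE,
                                      direction = "<")),
                 tolerance = 1e-12)
  }
})

test_that("metrics match a hand-built confusion matrix", {
  m <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(m[c("accuracy", "precision", "sensitivity",
                          "specificity", "f1", "auc")]),
               rep(1, 6))

  # always-negative rule on balanced labels
  expect_warning(
    m2 <- compute_metrics(c(0.1, 0.2, 0.3, 0.4), c(1, 0, 1, 0), 0.9),
    "precision")
  expect_equal(unname(m2["sensitivity"]), 0)
  expect_equal(unname(m2["specificity"]), 1)
  expect_equal(unname(m2["accuracy"]), 0.5)

  set.seed(179)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- runif(n); labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    thr <- runif(1)
    got <- suppressWarnings(compute_metrics(scores, labels, thr))
    want <- brute_metrics(scores, labels, thr)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
    # F1 identity where defined
    if (got["precision"] + got["sensitivity"] > 0)
      expect_equal(unname(got["f1"]),
                   unname(2 * got["precision"] * got["sensitivity"] /
                            (got["precision"] + got["sensitivity"])),
                   tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE follows the closed form", {
  expect_equal(hanley_mcneil_se(1.0, 30, 20), 0)
  expect_equal(hanley_mcneil_se(0.5, 10, 10), sqrt(0.0175))
  # Q1/Q2 bookkeeping in the summary object
  s <- auc_summary(0.8, 40, 25)
  expect_equal(s$Q1, 0.8 / 1.2)
  expect_equal(s$Q2, 2 * 0.64 / 1.8)
  expect_equal(s$SE, hanley_mcneil_se(0.8, 40, 25))
  # monotone decrease in n_pos at fixed A, n_neg
  ses <- sapply(c(10, 20, 40, 80), hanley_mcneil_se, A = 0.7, n_neg = 30)
  expect_true(all(diff(ses) < 0))
})

test_that("Hanley-McNeil SE approximates the Monte-Carlo SD of the AUC", {
  set.seed(181)
  aucs <- replicate(3000, auc(rnorm(20), rep(c(1, 0), each = 10)))
  expect_lt(abs(sd(aucs) - hanley_mcneil_se(0.5, 10, 10)), 0.02)
})

test_that("AUC comparison is antisymmetric and identity-consistent", {
  s1 <- auc_summary(0.805, 42, 22)
  s2 <- auc_summary(0.648, 95, 63)
  cmp <- compare_auc(s1, s2)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$z, 0)
  rev <- compare_auc(s2, s1)
  expect_equal(rev$z, -cmp$z)
  expect_equal(rev$p, cmp$p)

  same <- compare_auc(s1, s1)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  degenerate <- compare_auc(auc_summary(1, 5, 5), auc_summary(1, 8, 8))
  expect_equal(degenerate$p, 1)
  expect_warning(cmp0 <- compare_auc(auc_summary(1, 5, 5),
                                     auc_summary(0, 8, 8)), "zero standard")
  expect_equal(cmp0$p, 0)
})

test_that("Welch t-test matches the reference and handles degeneracy", {
  set.seed(191)
  a <- rnorm(40); b <- rnorm(35, 0.2, 2)
  got <- compare_metric_ttest(a, b)
  ref <- t.test(a, b)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  expect_equal(compare_metric_ttest(a, a)$t, 0)
  expect_equal(compare_metric_ttest(rep(1, 5), rep(1, 5)),
               list(t = 0, df = NA_real_, p = 1))
  # constant shift at n=100 is overwhelmingly significant
  x <- rnorm(100)
  expect_lt(compare_metric_ttest(x + 10, x)$p, 1e-6)
})

test_that("Welch p agrees with a permutation test on Gaussian vectors", {
  set.seed(193)
  a <- rnorm(30, 0.5); b <- rnorm(30)
  got <- compare_metric_ttest(a, b)$p
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(10000, {
    ix <- sample(60, 30)
    abs(mean(pooled[ix]) - mean(pooled[-ix]))
  })
  expect_lt(abs(got - mean(perm >= obs - 1e-12)), 0.02)
})

test_that("repeated CV separates a strong planted cohort and is reproducible", {
  tab <- generate_cohort(cohort_spec(
    n_male = 100, n_female = 100, n_features = 20, n_signal_male = 4,
    n_signal_female = 4, effect_size = 3, block_size = 4,
    confounder_frac = 0, seed = 197))
  feats <- c(attr(tab, "signal_male"), attr(tab, "signal_female"))
  rep1 <- suppressWarnings(repeated_cv(tab, feats, n_rounds = 2, k = 10,
                                       seed = 17))
  expect_gt(rep1$summary$mean[rep1$summary$metric == "auc"], 0.95)
  expect_true(all(rep1$summary$ci_low <= rep1$summary$mean + 1e-12))
  expect_true(all(rep1$summary$mean <= rep1$summary$ci_high + 1e-12))
  expect_equal(nrow(rep1$per_round), 2)
  expect_true(all(as.matrix(rep1$per_round) >= 0 &
                    as.matrix(rep1$per_round) <= 1))

  rep2 <- suppressWarnings(repeated_cv(tab, feats, n_rounds = 2, k = 10,
                                       seed = 17))
  expect_identical(rep1$per_round, rep2$per_round)
  expect_identical(rep1$summary, rep2$summary)
})

test_that("repeated CV refuses folds larger than a class", {
  tab <- small_cohort(seed = 199)
  expect_error(repeated_cv(tab, feature_names(tab)[1:5], n_rounds = 1,
                           k = nrow(tab)), "smaller k")
})

test_that("evaluation report files reflect the report object", {
  tab <- small_cohort(seed = 211)
  rep1 <- suppressWarnings(repeated_cv(tab, feature_names(tab)[1:8],
                                       n_rounds = 2, k = 5, seed = 18))
  stem <- file.path(withr::local_tempdir(), "eval")
  write_evaluation_report(rep1, stem)
  smry <- read.csv(paste0(stem, "_summary.csv"))
  expect_equal(smry$mean, rep1$summary$mean, tolerance = 1e-9)
  rounds <- read.csv(paste0(stem, "_rounds.csv"))
  expect_equal(nrow(rounds), 2)
})
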