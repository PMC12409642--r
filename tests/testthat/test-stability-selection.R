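# Rank-sum p-values and stability selection.

test_that("rank-sum p-value matches full enumeration on small groups", {
  expect_equal(rank_sum_pvalue(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(31)
  for (i in 1:20) {
    m <- sample(3:7, 1); n <- sample(3:7, 1)
    x <- round(rnorm(m), 3); y <- round(rnorm(n, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(rank_sum_pvalue(x, y), enum_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p-value agrees with the reference implementation", {
  set.seed(37)
  # exact branch
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(10, 0.8)
    expect_equal(rank_sum_pvalue(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # approximate branch, with and without ties
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(30, 0.3)
    expect_equal(rank_sum_pvalue(x, y),
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
    xt <- round(x, 1); yt <- round(y, 1)
    expect_equal(rank_sum_pvalue(xt, yt),
                 wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("degenerate and invalid rank-sum inputs are handled", {
  expect_equal(rank_sum_pvalue(c(5, 5, 5), c(5, 5, 5)), 1.0)
  expect_error(rank_sum_pvalue(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum type-I error is calibrated at alpha = 0.05", {
  set.seed(41)
  rej <- mean(replicate(2000, {
    rank_sum_pvalue(rnorm(50), rnorm(50)) < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("the vectorised matrix path equals the scalar approximation", {
  set.seed(43)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[, 4] <- round(X[, 4], 1)  # induce ties in one column
  g <- rep(c(TRUE, FALSE), c(35, 25))
  p_mat <- gendrad:::.rank_sum_p_matrix(X, g)
  p_ref <- apply(X, 2, function(col)
    wilcox.test(col[g], col[!g], exact = FALSE, correct = TRUE)$p.value)
  expect_equal(p_mat, unname(p_ref), tolerance = 1e-10)
})

test_that("selection frequencies are k/n_rounds and thresholding is >=", {
  tab <- small_cohort(seed = 47)
  cfg <- selection_config(n_rounds = 25, seed = 2)
  res <- select_features(tab, cfg)
  expect_true(all(res$frequency >= 0 & res$frequency <= 1))
  expect_true(all(abs(res$frequency * 25 - round(res$frequency * 25)) < 1e-9))
  # retention uses frequency >= threshold, so a boundary feature is kept
  boundary <- names(res$frequency)[res$frequency >= cfg$freq_threshold]
  expect_setequal(res$selected, boundary)
  # selected preserves input column order
  expect_equal(res$selected,
               intersect(feature_names(tab), res$selected))
})

test_that("lowering the frequency threshold never shrinks the selection", {
  tab <- small_cohort(seed = 53)
  res <- select_features(tab, selection_config(n_rounds = 25, seed = 3))
  sel_40 <- names(res$frequency)[res$frequency >= 0.40]
  sel_25 <- names(res$frequency)[res$frequency >= 0.25]
  expect_true(all(sel_40 %in% sel_25))
})

test_that("one full-sample round reduces to a single rank-sum test", {
  tab <- small_cohort(seed = 59)
  res <- select_features(tab, selection_config(n_rounds = 1,
                                               subsample_frac = 1, seed = 4))
  single <- sapply(feature_names(tab), function(f) {
    p <- gendrad:::.rank_sum_p_matrix(feature_matrix(tab, f), tab$label == 1)
    p < 0.05
  })
  expect_equal(unname(res$frequency == 1), unname(single))
  expect_setequal(res$selected, feature_names(tab)[single])
})

test_that("selection is deterministic given the seed", {
  tab <- small_cohort(seed = 61)
  a <- select_features(tab, selection_config(n_rounds = 15, seed = 5))
  b <- select_features(tab, selection_config(n_rounds = 15, seed = 5))
  expect_identical(a, b)
})

test_that("stratified subsampling preserves class prevalence each round", {
  label <- rep(c(1L, 0L), c(117, 79))
  set.seed(67)
  for (i in 1:20) {
    idx <- gendrad:::.draw_subsample(label, 0.8, TRUE)
    expect_length(idx, ceiling(0.8 * 196))
    expect_lt(abs(mean(label[idx]) - mean(label)), 0.01)
  }
})

test_that("planted signal features are recovered within their gender", {
  # moderate effect, within-gender selection
  reps <- lapply(1:3, function(s) {
    tab <- generate_cohort(cohort_spec(
      n_male = 100, n_female = 100, n_features = 80, n_signal_male = 6,
      n_signal_female = 6, effect_size = 1.5, block_size = 8,
      confounder_frac = 0, seed = 70 + s))
    males <- stratum_subset(tab, "male")
    res <- select_features(males, selection_config(n_rounds = 30,
                                                   seed = 80 + s))
    mean(attr(tab, "signal_male") %in% res$selected)
  })
  expect_gte(mean(unlist(reps)), 0.8)
})

test_that("null selection rate reflects the borderline-feature mass", {
  # Under the null the procedure still selects the few-percent of features
  # whose full-sample p lands below ~0.04: subsample rounds are correlated
  # through the shared cohort, so frequencies do not concentrate at alpha.
  tab <- generate_cohort(cohort_spec(
    n_male = 117, n_female = 79, n_features = 150, effect_size = 0,
    n_signal_male = 0, n_signal_female = 0, confounder_frac = 0, seed = 73))
  res <- select_features(tab, selection_config(n_rounds = 30, seed = 6))
  frac <- length(res$selected) / 150
  expect_lt(frac, 0.12)
  # frequencies are bimodal-ish: most features essentially never significant
  expect_gt(mean(res$frequency < 0.2), 0.75)
})

test_that("selection requires two classes and writes its report", {
  tab <- small_cohort(seed = 79)
  one_class <- tab[tab$label == 1, ]
  class(one_class) <- class(tab)
  expect_error(select_features(one_class, selection_config(n_rounds = 2)),
               "class")
  res <- select_features(tab, selection_config(n_rounds = 5, seed = 7))
  stem <- file.path(withr::local_tempdir(), "sel")
  write_selection_result(res, stem)
  csv <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), length(feature_names(tab)))
  expect_equal(sum(csv$selected), length(res$selected))
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$config$n_rounds, 5)
})
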