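# Shared fixtures and independent oracles used across the suite.

# a small planted cohort for quick end-to-end checks
small_cohort <- function(seed = 7, n_male = 40, n_female = 30,
                         n_features = 60, effect = 2, conf = 0.1) {
  generate_cohort(cohort_spec(
    n_male = n_male, n_female = n_female, n_features = n_features,
    n_signal_male = 5, n_signal_female = 5, effect_size = effect,
    block_size = 5, block_rho = 0.4, confounder_frac = conf, seed = seed))
}

# hand-rolled feature table without the generator
toy_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    gender = rep(c("M", "F"), length.out = n),
    dfs_months = c(runif(n %/% 2, 0, 36), runif(n - n %/% 2, 37, 100)),
    f_a = rnorm(n), f_b = rnorm(n), f_c = rnorm(n))
  feature_table(df)
}

# exact two-sided rank-sum p by full enumeration of rank assignments
enum_ranksum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# trapezoidal ROC integration (independent AUC oracle)
trapezoid_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  # step through unique thresholds, accumulating trapezoids in ROC space
  tps <- cumsum(labels == 1); fps <- cumsum(labels == 0)
  keep <- c(scores[-1] != scores[-length(scores)], TRUE)
  tpr <- c(0, tps[keep] / n_pos); fpr <- c(0, fps[keep] / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# brute-force Youden search over all candidate thresholds
brute_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  J <- sapply(cand, function(t) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    sens + spec - 1
  })
  list(threshold = cand[which.max(J)], J = max(J))
}

# permutation null for the Pearson chi-square statistic of a 2 x C table:
# individual-level rows reproducing the table, column labels permuted
perm_chisq_p <- function(counts, n_perm = 4000, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(i = seq_len(nrow(counts)), j = seq_len(ncol(counts)))
  n_cell <- counts[as.matrix(cells)]
  grp <- rep(cells$i, n_cell)
  lev <- rep(cells$j, n_cell)
  stat <- function(g, l) {
    tab <- table(g, l)
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  }
  obs <- stat(grp, lev)
  perms <- replicate(n_perm, stat(grp, sample(lev)))
  # mid-p: the uncorrected Pearson p approximates the mid-p of the discrete
  # conditional null, whose steps exceed Monte-Carlo error at these counts
  mean(perms > obs + 1e-9) + 0.5 * mean(abs(perms - obs) <= 1e-9)
}

# confusion-matrix metrics computed longhand
brute_metrics <- function(scores, labels, thr) {
  pred <- as.integer(scores >= thr)
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(accuracy = (tp + tn) / length(labels), precision = prec,
    sensitivity = sens,
    specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
    f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens))
}
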