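# Repeated cross-validated evaluation, metric aggregation and between-model
# statistical comparison.

#' Area under the ROC curve
#'
#' Rank-based AUC: the Mann-Whitney U statistic divided by
#' \eqn{n_{pos} \cdot n_{neg}}, with ties counted one half. Equivalent to
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("auc: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics at a threshold
#'
#' Builds the confusion matrix with the rule "positive iff score >=
#' threshold" and returns accuracy, precision, sensitivity, specificity, F1
#' and the threshold-free AUC. Ratios with a zero denominator are reported
#' as 0 with a warning.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @param threshold decision threshold.
#' @return named numeric vector of class \code{metric_vector} with entries
#'   \code{accuracy}, \code{precision}, \code{sensitivity},
#'   \code{specificity}, \code{f1}, \code{auc}.
#' @export
compute_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("compute_metrics: both classes must be present", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("compute_metrics: ", what, " undefined (0/0); reported as 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  structure(c(accuracy = (tp + tn) / length(labels), precision = precision,
              sensitivity = sensitivity, specificity = specificity, f1 = f1,
              auc = auc(scores, labels)),
            class = c("metric_vector", "numeric"))
}

#' Repeated stratified k-fold cross-validated evaluation
#'
#' For each round, patients are partitioned into k class-stratified folds;
#' the soft-voting ensemble is fitted on each k-1 fold training set and
#' scores the held-out fold. The round's out-of-fold scores are pooled, a
#' Youden-index threshold is derived on those pooled scores and the metric
#' vector is computed at that threshold (AUC is threshold-free). Deriving
#' the threshold on the same pooled scores it is applied to mirrors the
#' usual practice in this literature but is optimistic for the
#' threshold-dependent metrics; the summary carries a note to that effect.
#'
#' Summaries report the across-round mean with a 95\% confidence interval of
#' the mean (mean +/- 1.96 sd/sqrt(n_rounds)); the across-round sd and
#' 2.5/97.5 percentiles are also emitted so the spread of the round
#' distribution can be read directly.
#'
#' @param table a \code{\link{feature_table}}; each class needs at least
#'   \code{k} members.
#' @param features feature columns used by the ensemble.
#' @param n_rounds number of cross-validation rounds (default 100).
#' @param k number of folds (default 10).
#' @param seed master seed; round r uses seed + r.
#' @param learners learner panel passed to \code{\link{fit_ensemble}}.
#' @return an object of class \code{evaluation_report}: \code{per_round}
#'   (data frame of round-level metrics), \code{summary} (per metric: mean,
#'   ci_low, ci_high, sd, p2.5, p97.5), counts and the configuration.
#' @export
repeated_cv <- function(table, features = feature_names(table),
                        n_rounds = 100, k = 10, seed = 1L,
                        learners = default_learners()) {
  label <- table$label
  if (min(table(label)) < k)
    stop("repeated_cv: a class has fewer than k = ", k,
         " members; use a smaller k", call. = FALSE)
  X_features <- features
  Xall <- feature_matrix(table, X_features)
  per_round <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    round_seed <- as.integer(seed) + r
    scores <- .with_seed(round_seed, {
      fold <- .stratified_folds(label, k)
      sc <- numeric(nrow(table))
      for (f in seq_len(k)) {
        tr_tab <- table[fold != f, , drop = FALSE]
        class(tr_tab) <- class(table)
        model <- fit_ensemble(tr_tab, X_features,
                              seed = round_seed * 1000L + f,
                              learners = learners)
        sc[fold == f] <- soft_vote_proba(
          model, Xall[fold == f, , drop = FALSE])
      }
      sc
    })
    thr <- youden_threshold(scores, label)
    per_round[[r]] <- compute_metrics(scores, label, thr$threshold)
  }
  per_round <- as.data.frame(do.call(rbind, per_round))
  summary <- do.call(rbind, lapply(names(per_round), function(m) {
    v <- per_round[[m]]
    mu <- mean(v); s <- stats::sd(v)
    half <- 1.96 * s / sqrt(length(v))
    data.frame(metric = m, mean = mu, ci_low = mu - half, ci_high = mu + half,
               sd = s, p2.5 = unname(stats::quantile(v, 0.025)),
               p97.5 = unname(stats::quantile(v, 0.975)))
  }))
  structure(list(per_round = per_round, summary = summary,
                 n_rounds = as.integer(n_rounds), k = as.integer(k),
                 seed = as.integer(seed),
                 n_pos = sum(label == 1L), n_neg = sum(label == 0L),
                 note = paste("Youden threshold derived on each round's",
                              "pooled out-of-fold scores and applied to the",
                              "same scores; threshold-dependent metrics are",
                              "optimistic.")),
            class = "evaluation_report")
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form SE of an AUC estimate A from the class counts:
#' \deqn{SE^2 = \frac{A(1-A) + (n_{pos}-1)(Q_1 - A^2) +
#'   (n_{neg}-1)(Q_2 - A^2)}{n_{pos} n_{neg}}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param A AUC in [0, 1].
#' @param n_pos,n_neg class counts (>= 1).
#' @return the standard error.
#' @export
hanley_mcneil_se <- function(A, n_pos, n_neg) {
  stopifnot(A >= 0, A <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_pos - 1) * (q1 - A^2) + (n_neg - 1) * (q2 - A^2)) /
         (n_pos * n_neg))
}

#' Summarise an AUC for Hanley-McNeil comparison
#'
#' @param A AUC in [0, 1].
#' @param n_pos,n_neg positive/negative class counts behind the estimate.
#' @return object of class \code{auc_summary} with \code{A}, \code{n_pos},
#'   \code{n_neg}, \code{Q1}, \code{Q2} and \code{SE}.
#' @export
auc_summary <- function(A, n_pos, n_neg) {
  structure(list(A = A, n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 Q1 = A / (2 - A), Q2 = 2 * A^2 / (1 + A),
                 SE = hanley_mcneil_se(A, n_pos, n_neg)),
            class = "auc_summary")
}

#' Compare two AUCs (Hanley-McNeil z-test)
#'
#' Independent-samples form: \eqn{z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2}},
#' two-sided p from the standard normal. No correlation term is applied:
#' the compared models are trained on different (sub)samples.
#'
#' @param s1,s2 \code{\link{auc_summary}} objects.
#' @return list with \code{z} and two-sided \code{p}.
#' @export
compare_auc <- function(s1, s2) {
  stopifnot(inherits(s1, "auc_summary"), inherits(s2, "auc_summary"))
  se <- sqrt(s1$SE^2 + s2$SE^2)
  if (se == 0) {
    if (s1$A == s2$A) return(list(z = 0, p = 1))
    warning("compare_auc: zero standard errors with unequal AUCs")
    return(list(z = sign(s1$A - s2$A) * Inf, p = 0))
  }
  z <- (s1$A - s2$A) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Welch t-test on round-level metric vectors
#'
#' Two-sample unequal-variance (Welch) t-test on per-round metric values,
#' two-sided. Degenerate zero-variance inputs are handled explicitly: equal
#' constant vectors give t = 0, p = 1; unequal constants give p = 0 with a
#' warning.
#'
#' @param rounds_a,rounds_b numeric vectors (length >= 2) of round-level
#'   metric values for the two models.
#' @return list with \code{t}, \code{df} and two-sided \code{p}.
#' @export
compare_metric_ttest <- function(rounds_a, rounds_b) {
  stopifnot(length(rounds_a) >= 2, length(rounds_b) >= 2)
  na <- length(rounds_a); nb <- length(rounds_b)
  va <- stats::var(rounds_a); vb <- stats::var(rounds_b)
  d <- mean(rounds_a) - mean(rounds_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, df = NA_real_, p = 1))
    warning("compare_metric_ttest: zero variance with unequal means")
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Write an evaluation report
#'
#' Writes \code{<path>_rounds.csv} (per-round metric table),
#' \code{<path>_summary.csv} (metric, mean, ci_low, ci_high, sd,
#' percentiles) and \code{<path>.json} with both plus the configuration.
#'
#' @param report an \code{evaluation_report}.
#' @param path output path stem.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  utils::write.csv(report$per_round, paste0(path, "_rounds.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, paste0(path, "_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, n_rounds = report$n_rounds, k = report$k,
         seed = report$seed, n_pos = report$n_pos, n_neg = report$n_neg,
         note = report$note),
    paste0(path, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(path)
}
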