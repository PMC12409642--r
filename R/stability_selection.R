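# Stability feature selection: frequency of rank-sum significance across
# random subsamples.

#' Two-sided Wilcoxon/Mann-Whitney rank-sum p-value
#'
#' Computes the two-sided rank-sum p-value for a difference in location
#' between two samples. When both groups have at most 12 observations and
#' there are no ties, the exact null distribution of the Mann-Whitney U
#' statistic is used; otherwise a normal approximation with tie correction
#' and continuity correction is applied.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return p-value in (0, 1].
#' @export
rank_sum_pvalue <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("rank_sum_pvalue: both samples must be non-empty", call. = FALSE)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m <= 12 && n <= 12 && !ties) {
    p <- if (U > m * n / 2) {
      stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      stats::pwilcox(U, m, n)
    }
    return(min(1, 2 * p))
  }
  .ranksum_normal_p(U, m, n, tie_term = .tie_term(r))
}

# sum(t^3 - t) over tie groups of the pooled ranks
.tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

# two-sided normal-approximation p with tie and continuity correction,
# matching the classical large-sample rank-sum test
.ranksum_normal_p <- function(U, m, n, tie_term) {
  mu <- m * n / 2
  N <- m + n
  sigma2 <- (m * n / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Vectorised rank-sum p-values for every column of X between the two groups
# coded by the logical vector g (TRUE = first group). Uses the same
# tie-corrected continuity-corrected normal approximation as
# rank_sum_pvalue's large-sample branch.
.rank_sum_p_matrix <- function(X, g) {
  m <- sum(g); n <- sum(!g)
  N <- m + n
  vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j])
    U <- sum(r[g]) - m * (m + 1) / 2
    .ranksum_normal_p(U, m, n, tie_term = .tie_term(r))
  }, numeric(1))
}

#' Configure stability feature selection
#'
#' @param n_rounds number of random subsamples (default 500).
#' @param subsample_frac fraction of patients drawn (without replacement)
#'   in each round (default 0.80).
#' @param alpha per-test significance level; a feature counts as significant
#'   in a round when its rank-sum p-value is strictly below \code{alpha}.
#' @param freq_threshold minimum significance frequency for retention; a
#'   feature is retained when significant in at least this fraction of
#'   rounds (default 0.40).
#' @param stratified draw subsamples stratified by class label so every
#'   round preserves the cohort prevalence (default \code{TRUE}).
#' @param seed integer seed; selection is deterministic given the config.
#' @return an object of class \code{selection_config}.
#' @export
selection_config <- function(n_rounds = 500, subsample_frac = 0.80,
                             alpha = 0.05, freq_threshold = 0.40,
                             stratified = TRUE, seed = 1L) {
  if (!(alpha > 0 && alpha < 1))
    stop("invalid selection_config: alpha must lie in (0, 1)", call. = FALSE)
  if (!(freq_threshold >= 0 && freq_threshold <= 1))
    stop("invalid selection_config: freq_threshold must lie in [0, 1]",
         call. = FALSE)
  if (!(subsample_frac > 0 && subsample_frac <= 1))
    stop("invalid selection_config: subsample_frac must lie in (0, 1]",
         call. = FALSE)
  if (n_rounds < 1)
    stop("invalid selection_config: n_rounds must be >= 1", call. = FALSE)
  structure(list(n_rounds = as.integer(n_rounds),
                 subsample_frac = subsample_frac, alpha = alpha,
                 freq_threshold = freq_threshold,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "selection_config")
}

# largest-remainder apportionment of total m across strata of sizes n_k
.apportion <- function(m, sizes) {
  quota <- m * sizes / sum(sizes)
  base <- floor(quota)
  rem <- m - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  pmin(as.integer(base), sizes)
}

# one stratified (or simple) subsample of indices
.draw_subsample <- function(label, frac, stratified) {
  n <- length(label)
  m <- ceiling(frac * n)
  if (!stratified) return(sort(sample.int(n, m)))
  idx0 <- which(label == 0L); idx1 <- which(label == 1L)
  take <- .apportion(m, c(length(idx0), length(idx1)))
  sort(c(sample(idx0, take[1]), sample(idx1, take[2])))
}

#' Stability-based feature selection by rank-sum resampling
#'
#' Repeatedly draws random subsamples of the cohort, tests every feature
#' between the two outcome groups with a two-sided rank-sum test, and
#' records for each feature the fraction of rounds in which it was
#' significant (p < \code{alpha}). Features significant in at least
#' \code{freq_threshold} of the rounds are retained.
#'
#' @param table a \code{\link{feature_table}} with both classes present.
#' @param config a \code{\link{selection_config}}.
#' @param features feature columns to consider (default: all).
#' @return an object of class \code{selection_result}: \code{frequency}
#'   (named vector, feature order preserved), \code{selected} (retained
#'   feature names in input column order), \code{n_redrawn} (rounds redrawn
#'   because a class was absent) and the config echo.
#' @export
select_features <- function(table, config = selection_config(),
                            features = feature_names(table)) {
  stopifnot(inherits(config, "selection_config"))
  label <- table$label
  if (length(unique(label)) < 2)
    stop("select_features: both outcome classes must be present",
         call. = FALSE)
  if (min(table(label)) < 2)
    stop("select_features: need at least 2 patients per class", call. = FALSE)
  X <- feature_matrix(table, features)

  hits <- integer(ncol(X))
  n_redrawn <- 0L
  .with_seed(config$seed, {
    for (r in seq_len(config$n_rounds)) {
      repeat {
        idx <- .draw_subsample(label, config$subsample_frac,
                               config$stratified)
        if (length(unique(label[idx])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      p <- .rank_sum_p_matrix(X[idx, , drop = FALSE], label[idx] == 1L)
      hits <- hits + (p < config$alpha)
    }
  })
  if (n_redrawn > 0)
    message("select_features: ", n_redrawn,
            " subsample round(s) redrawn due to an empty class")

  frequency <- hits / config$n_rounds
  names(frequency) <- colnames(X)
  structure(list(frequency = frequency,
                 selected = colnames(X)[frequency >= config$freq_threshold],
                 n_redrawn = n_redrawn, config = config),
            class = "selection_result")
}

#' Write a selection report
#'
#' Writes \code{<path>.csv} with columns \code{feature,frequency,selected}
#' and a JSON sidecar \code{<path>.json} echoing the configuration and seed.
#'
#' @param result a \code{selection_result}.
#' @param path output path stem (extensions are appended).
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  df <- data.frame(feature = names(result$frequency),
                   frequency = unname(result$frequency),
                   selected = names(result$frequency) %in% result$selected)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(result$config), n_selected = length(result$selected),
         n_redrawn = result$n_redrawn),
    paste0(path, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(path)
}
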