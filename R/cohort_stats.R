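# Clinical-covariate association and comparability testing: Pearson
# chi-square for nominal covariates, rank-sum for interval covariates.

#' Pearson chi-square association test
#'
#' Pearson chi-square without continuity correction on a 2 x C contingency
#' table; degrees of freedom (2-1)(C-1).
#'
#' @param counts 2 x C matrix of non-negative counts with positive margins.
#' @return list with \code{statistic}, \code{df} and \code{p}.
#' @export
chi_square_association <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("chi_square_association: negative cell count",
                            call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi_square_association: zero row or column margin", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Compare covariate distributions between two groups
#'
#' For each covariate, tests whether its distribution differs between the
#' two levels of a grouping variable (outcome or gender): Pearson chi-square
#' (no continuity correction) for nominal covariates, two-sided rank-sum for
#' interval covariates. Missing covariate values are excluded pairwise and
#' counted; a covariate entirely missing in one group is marked not
#' testable instead of silently dropped.
#'
#' @param covariates data frame of per-patient covariates; may contain
#'   \code{NA}.
#' @param group vector (two levels, no missing values) aligned with the
#'   rows of \code{covariates}.
#' @param nominal character vector naming the nominal covariates; all other
#'   columns are treated as interval-scaled.
#' @return data frame with one row per covariate: \code{covariate},
#'   \code{type}, \code{statistic}, \code{p}, \code{n_used},
#'   \code{n_missing}, \code{testable}.
#' @export
compare_cohorts <- function(covariates, group, nominal = character(0)) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(group))
  if (anyNA(group)) stop("compare_cohorts: missing values in group",
                         call. = FALSE)
  lev <- unique(group)
  if (length(lev) != 2)
    stop("compare_cohorts: grouping must have exactly two levels",
         call. = FALSE)
  rows <- lapply(names(covariates), function(cv) {
    x <- covariates[[cv]]
    ok <- !is.na(x)
    n_missing <- sum(!ok)
    g <- group[ok]; x <- x[ok]
    type <- if (cv %in% nominal) "nominal" else "interval"
    if (sum(g == lev[1]) == 0 || sum(g == lev[2]) == 0)
      return(data.frame(covariate = cv, type = type, statistic = NA_real_,
                        p = NA_real_, n_used = sum(ok),
                        n_missing = n_missing, testable = FALSE))
    if (type == "nominal") {
      tab <- table(factor(g, levels = lev), x)
      if (ncol(tab) < 2 || any(colSums(tab) == 0)) {
        # a single observed level carries no association information
        return(data.frame(covariate = cv, type = type, statistic = 0,
                          p = 1, n_used = sum(ok), n_missing = n_missing,
                          testable = TRUE))
      }
      res <- chi_square_association(tab)
      stat <- res$statistic; p <- res$p
    } else {
      stat <- NA_real_
      p <- rank_sum_pvalue(x[g == lev[1]], x[g == lev[2]])
    }
    data.frame(covariate = cv, type = type, statistic = stat, p = p,
               n_used = sum(ok), n_missing = n_missing, testable = TRUE)
  })
  do.call(rbind, rows)
}
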