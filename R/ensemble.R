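# AUC-weighted soft-voting ensemble with Youden-index thresholding.

#' Normalise per-learner AUCs into soft-vote weights
#'
#' Weights are the raw AUC values normalised to sum to one, so a learner
#' with a higher AUC contributes more to the vote. AUCs below 0.5 are kept
#' as-is (with a warning): the weighting rule uses the AUC values directly.
#'
#' @param aucs numeric vector of per-learner AUCs.
#' @return non-negative weights summing to 1.
#' @export
auc_weights <- function(aucs) {
  if (any(aucs < 0.5))
    warning("auc_weights: AUC below 0.5 for ",
            sum(aucs < 0.5), " learner(s); raw values used as weights")
  if (sum(aucs) <= 0) return(rep(1 / length(aucs), length(aucs)))
  aucs / sum(aucs)
}

# stratified k-fold assignment: shuffled round-robin within each class
.stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (cl in unique(label)) {
    idx <- sample(which(label == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit the AUC-weighted soft-voting ensemble
#'
#' Fits the five-learner panel on standardised training features. Each
#' learner's voting weight is its AUC estimated by inner stratified 5-fold
#' cross-validation on the training data (out-of-fold scores pooled before
#' computing the AUC), normalised so the weights sum to one; the learners
#' are then refitted on the full training set.
#'
#' @param train a \code{\link{feature_table}} with at least two patients per
#'   class.
#' @param features feature columns used by the model.
#' @param seed integer seed governing fold assignment and learner
#'   initialisation.
#' @param learners learner panel (default: the five families).
#' @param inner_k inner folds for weight estimation (default 5; shrunk to
#'   the minority-class size when a class has fewer than \code{inner_k}
#'   members, with a message).
#' @return an object of class \code{ensemble_model}: fitted \code{learners},
#'   \code{weights}, \code{inner_auc}, \code{feature_list} and the training
#'   standardisation parameters.
#' @export
fit_ensemble <- function(train, features = feature_names(train), seed = 1L,
                         learners = default_learners(), inner_k = 5) {
  label <- train$label
  if (length(unique(label)) < 2 || min(table(label)) < 2)
    stop("fit_ensemble: need at least 2 patients per class", call. = FALSE)
  X <- feature_matrix(train, features)
  std <- .standardize_fit(X)
  Xs <- .standardize_apply(X, std)
  k <- min(inner_k, min(table(label)))
  if (k < inner_k)
    message("fit_ensemble: inner folds shrunk to ", k,
            " (minority class size)")

  res <- .with_seed(seed, {
    fold <- .stratified_folds(label, k)
    inner_scores <- matrix(NA_real_, nrow(Xs), length(learners))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(label[tr])) < 2) next
      for (j in seq_along(learners)) {
        m <- learners[[j]]$fit(Xs[tr, , drop = FALSE], label[tr])
        inner_scores[!tr, j] <-
          learners[[j]]$predict_proba(m, Xs[!tr, , drop = FALSE])
      }
    }
    inner_auc <- vapply(seq_along(learners), function(j) {
      ok <- !is.na(inner_scores[, j])
      auc(inner_scores[ok, j], label[ok])
    }, numeric(1))
    fitted <- lapply(learners, function(l) l$fit(Xs, label))
    list(inner_auc = inner_auc, fitted = fitted)
  })

  structure(list(learners = learners, fitted = res$fitted,
                 weights = auc_weights(res$inner_auc),
                 inner_auc = res$inner_auc, feature_list = features,
                 standardization = std, seed = as.integer(seed)),
            class = "ensemble_model")
}

# weighted soft-vote combination of a probability matrix (rows = samples,
# columns = learners)
.combine_probs <- function(P, w) {
  stopifnot(ncol(P) == length(w))
  drop(P %*% w)
}

#' Soft-voting ensemble probabilities
#'
#' The ensemble class-1 probability is the weighted mean of the base
#' learners' class-1 probabilities, \eqn{p(x) = \sum_k w_k p_k(x)}, with the
#' AUC-derived weights of \code{\link{fit_ensemble}}.
#'
#' @param model an \code{ensemble_model}.
#' @param newdata a \code{feature_table} or numeric matrix containing the
#'   model's feature columns.
#' @return vector of class-1 probabilities in [0, 1].
#' @export
soft_vote_proba <- function(model, newdata) {
  stopifnot(inherits(model, "ensemble_model"))
  X <- if (is.matrix(newdata)) {
    miss <- setdiff(model$feature_list, colnames(newdata))
    if (length(miss) > 0)
      stop("soft_vote_proba: missing feature column(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    newdata[, model$feature_list, drop = FALSE]
  } else {
    feature_matrix(newdata, model$feature_list)
  }
  Xs <- .standardize_apply(X, model$standardization)
  P <- vapply(seq_along(model$learners), function(j) {
    model$learners[[j]]$predict_proba(model$fitted[[j]], Xs)
  }, numeric(nrow(Xs)))
  if (!is.matrix(P)) P <- matrix(P, nrow = 1)
  pmin(1, pmax(0, .combine_probs(P, model$weights)))
}

#' Youden-index optimal threshold
#'
#' Scans the unique observed scores as candidate thresholds (positive call
#' iff score >= t) and returns the one maximising the Youden index
#' J = sensitivity + specificity - 1. Ties in J are broken toward the
#' smallest threshold (the more sensitive rule).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return list of class \code{threshold_result} with \code{threshold} and
#'   \code{J}.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("youden_threshold: both classes must be present", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  cand <- sort(unique(scores))
  # positives called at threshold t: scores >= t
  sens <- vapply(cand, function(t) sum(scores >= t & labels == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(scores < t & labels == 0L) / n_neg,
                 numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1]  # smallest threshold among ties
  structure(list(threshold = cand[best], J = J[best]),
            class = "threshold_result")
}

#' Write an ensemble-model summary
#'
#' JSON summary: per-learner inner AUCs, normalised weights, feature list
#' and seed.
#'
#' @param model an \code{ensemble_model}.
#' @param path output JSON path.
#' @export
write_ensemble_summary <- function(model, path) {
  stopifnot(inherits(model, "ensemble_model"))
  jsonlite::write_json(
    list(families = vapply(model$learners, `[[`, "", "family"),
         inner_auc = model$inner_auc, weights = model$weights,
         features = model$feature_list, seed = model$seed),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
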