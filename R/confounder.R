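# Confounding-patient detection: repeated multi-classifier subsampling and
# a first-quartile rule on per-patient out-of-sample correct-classification
# rates.

#' Configure the confounder screen
#'
#' @param n_rounds number of random training subsamples (default 500).
#' @param subsample_frac fraction of patients used for training in each
#'   round; the remainder is scored out-of-sample (default 0.80).
#' @param learners list of \code{\link{make_learner}} specs (default: the
#'   five-classifier panel).
#' @param quantile_level quantile of the per-patient correct-rate
#'   distribution below which a patient is flagged (default 0.25, the first
#'   quartile).
#' @param seed integer seed.
#' @return an object of class \code{screen_config}.
#' @export
screen_config <- function(n_rounds = 500, subsample_frac = 0.80,
                          learners = default_learners(),
                          quantile_level = 0.25, seed = 1L) {
  if (!(quantile_level > 0 && quantile_level < 1))
    stop("invalid screen_config: quantile_level must lie in (0, 1)",
         call. = FALSE)
  if (!(subsample_frac > 0 && subsample_frac < 1))
    stop("invalid screen_config: subsample_frac must lie in (0, 1)",
         call. = FALSE)
  if (n_rounds < 1)
    stop("invalid screen_config: n_rounds must be >= 1", call. = FALSE)
  stopifnot(length(learners) >= 1,
            all(vapply(learners, inherits, TRUE, "learner_spec")))
  structure(list(n_rounds = as.integer(n_rounds),
                 subsample_frac = subsample_frac, learners = learners,
                 quantile_level = quantile_level, seed = as.integer(seed)),
            class = "screen_config")
}

#' Screen a cohort for confounding patients
#'
#' In each round a class-stratified training subsample is drawn, every
#' learner of the panel is fitted on it (features standardised by the
#' training statistics), and the held-out patients are predicted
#' out-of-sample. Each held-out prediction is scored correct when the
#' class-1 probability, thresholded at 0.5, matches the recorded label. A
#' patient's correct rate is the mean over all (round, learner) evaluations
#' in which they were held out. Patients whose correct rate falls strictly
#' below the first quartile (linear-interpolation quantile at
#' \code{quantile_level}) of the correct-rate distribution are flagged as
#' confounders and removed from the retained table.
#'
#' Note the quartile rule always removes roughly a quarter of the cohort,
#' even when no patient is genuinely mislabelled; it is a relative screen,
#' not an absolute noise test.
#'
#' @param table a \code{\link{feature_table}} with both classes present.
#' @param features feature columns used by the learners (typically the
#'   stability-selected set).
#' @param config a \code{\link{screen_config}}.
#' @return an object of class \code{confounder_result}: \code{correct_rate}
#'   and \code{n_evaluations} (named by patient), \code{cutoff},
#'   \code{flagged} (patient ids), \code{retained_table} and a config echo.
#' @export
run_confounder_screen <- function(table, features = feature_names(table),
                                  config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  label <- table$label
  if (length(unique(label)) < 2)
    stop("run_confounder_screen: both outcome classes must be present",
         call. = FALSE)
  X <- feature_matrix(table, features)
  n <- nrow(X)
  n_learners <- length(config$learners)

  correct <- numeric(n)
  evals <- integer(n)
  .with_seed(config$seed, {
    for (r in seq_len(config$n_rounds)) {
      tr <- .draw_subsample(label, config$subsample_frac, stratified = TRUE)
      te <- setdiff(seq_len(n), tr)
      if (length(te) == 0 || length(unique(label[tr])) < 2) next
      std <- .standardize_fit(X[tr, , drop = FALSE])
      Xtr <- .standardize_apply(X[tr, , drop = FALSE], std)
      Xte <- .standardize_apply(X[te, , drop = FALSE], std)
      for (lrn in config$learners) {
        model <- lrn$fit(Xtr, label[tr])
        pred <- as.integer(lrn$predict_proba(model, Xte) >= 0.5)
        correct[te] <- correct[te] + (pred == label[te])
        evals[te] <- evals[te] + 1L
      }
    }
  })
  if (any(evals == 0))
    stop("run_confounder_screen: ", sum(evals == 0), " patient(s) were ",
         "never held out; increase n_rounds", call. = FALSE)

  rate <- correct / evals
  names(rate) <- table$patient_id
  names(evals) <- table$patient_id
  cutoff <- unname(stats::quantile(rate, config$quantile_level, type = 7))
  flagged <- table$patient_id[rate < cutoff]
  retained <- table[!(table$patient_id %in% flagged), , drop = FALSE]
  class(retained) <- class(table)
  structure(list(correct_rate = rate, n_evaluations = evals,
                 cutoff = cutoff, flagged = flagged,
                 retained_table = retained, config = config),
            class = "confounder_result")
}

#' First-quartile flagging rule on a correct-rate vector
#'
#' The cutoff/flagging rule of the confounder screen in isolation: cutoff is
#' the linear-interpolation quantile of \code{rates} at \code{level}, and
#' values strictly below the cutoff are flagged.
#'
#' @param rates named numeric vector of per-patient correct rates.
#' @param level quantile level (default 0.25).
#' @return list with \code{cutoff} and logical \code{flagged} (same order
#'   and names as \code{rates}).
#' @export
quartile_flag <- function(rates, level = 0.25) {
  cutoff <- unname(stats::quantile(rates, level, type = 7))
  list(cutoff = cutoff, flagged = rates < cutoff)
}

#' Write a confounder-screen report
#'
#' Writes \code{<path>.csv} with columns
#' \code{patient_id,correct_rate,n_evaluations,flagged} and a JSON sidecar
#' with the cutoff, configuration and seed.
#'
#' @param result a \code{confounder_result}.
#' @param path output path stem.
#' @export
write_confounder_result <- function(result, path) {
  stopifnot(inherits(result, "confounder_result"))
  ids <- names(result$correct_rate)
  df <- data.frame(patient_id = ids,
                   correct_rate = unname(result$correct_rate),
                   n_evaluations = unname(result$n_evaluations),
                   flagged = ids %in% result$flagged)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  cfg <- result$config
  jsonlite::write_json(
    list(cutoff = result$cutoff, n_flagged = length(result$flagged),
         n_rounds = cfg$n_rounds, subsample_frac = cfg$subsample_frac,
         quantile_level = cfg$quantile_level, seed = cfg$seed,
         learners = vapply(cfg$learners, `[[`, "", "family")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(path)
}
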