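# Orchestration of the full framework over the all/male/female strata:
# stability selection -> confounder screening -> repeated cross-validated
# evaluation, followed by cross-stratum comparisons.

#' Configure a framework run
#'
#' @param input a path to a feature-table CSV, a \code{feature_table}, or a
#'   \code{\link{cohort_spec}} (simulation mode).
#' @param strata subset of \code{c("all", "male", "female")}.
#' @param selection a \code{\link{selection_config}}; its seed is overridden
#'   by a stratum-specific seed derived from \code{seed}.
#' @param screening a \code{\link{screen_config}}; seed handled likewise.
#' @param n_cv_rounds,k repeated cross-validation rounds and folds.
#' @param seed master seed; every stage seed is derived from it by a fixed
#'   offset so strata are independently reproducible.
#' @param out_dir optional output directory for report files.
#' @param fast reduced-scale preset (50 selection rounds, 50 screening
#'   rounds, 10 CV rounds) for quick runs; full defaults are 500/500/100.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(input, strata = c("all", "male", "female"),
                       selection = selection_config(),
                       screening = screen_config(),
                       n_cv_rounds = 100, k = 10, seed = 1L, out_dir = NULL,
                       fast = FALSE) {
  strata <- match.arg(strata, c("all", "male", "female"), several.ok = TRUE)
  if (length(strata) == 0) stop("invalid run_config: strata must be non-empty",
                                call. = FALSE)
  stopifnot(inherits(selection, "selection_config"),
            inherits(screening, "screen_config"))
  if (isTRUE(fast)) {
    selection$n_rounds <- min(selection$n_rounds, 50L)
    screening$n_rounds <- min(screening$n_rounds, 50L)
    n_cv_rounds <- min(n_cv_rounds, 10L)
  }
  structure(list(input = input, strata = strata, selection = selection,
                 screening = screening, n_cv_rounds = as.integer(n_cv_rounds),
                 k = as.integer(k), seed = as.integer(seed),
                 out_dir = out_dir, fast = isTRUE(fast)),
            class = "run_config")
}

.STRATUM_OFFSET <- c(all = 0L, male = 1L, female = 2L)

.load_input <- function(input) {
  if (inherits(input, "cohort_spec")) return(generate_cohort(input))
  if (inherits(input, "feature_table")) return(input)
  if (is.character(input) && length(input) == 1)
    return(read_feature_table(input))
  stop("run_framework: input must be a CSV path, a feature_table or a ",
       "cohort_spec", call. = FALSE)
}

#' Run the gender-stratified framework
#'
#' Executes, for each requested stratum (all patients, males only, females
#' only): (i) stability feature selection, (ii) confounder screening on the
#' selected features, (iii) repeated stratified k-fold cross-validated
#' evaluation of the soft-voting ensemble on the retained patients. Then
#' computes cross-stratum comparisons: selected-feature overlap counts,
#' Hanley-McNeil AUC z-tests of each gender model against the pooled model,
#' and Welch t-tests on each round-level metric. A stratum too small for the
#' requested folds is skipped with an explicit error record; the others
#' proceed.
#'
#' When \code{out_dir} is set, per-stage CSV/JSON reports, a comparisons
#' table, a \code{run.log} and a manifest (config echo, seeds, input MD5,
#' per-stage patient/feature counts) are written; re-running with the same
#' config and seed reproduces every output byte-for-byte.
#'
#' @param config a \code{\link{run_config}}.
#' @return list with \code{table} (the input cohort), \code{strata} (per
#'   stratum: \code{selection}, \code{screen}, \code{evaluation},
#'   \code{counts} or an \code{error} record), \code{comparisons} and
#'   \code{manifest}.
#' @export
run_framework <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- .load_input(config$input)
  out_dir <- config$out_dir
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.character(config$input))
      write_feature_table(table, file.path(out_dir, "cohort.csv"))
  }
  input_path <- if (is.character(config$input)) config$input
    else if (!is.null(out_dir)) file.path(out_dir, "cohort.csv") else NULL
  input_md5 <- if (!is.null(input_path))
    unname(tools::md5sum(input_path)) else NA_character_

  strata_res <- list()
  counts <- list()
  for (st in config$strata) {
    off <- .STRATUM_OFFSET[[st]]
    sub <- stratum_subset(table, st)
    log("stratum ", st, ": ", nrow(sub), " patients, ",
        length(feature_names(sub)), " features")
    res <- tryCatch({
      sel_cfg <- config$selection
      sel_cfg$seed <- config$seed + 100L + off
      sel <- select_features(sub, sel_cfg)
      log("stratum ", st, ": selected ", length(sel$selected), " features")
      if (length(sel$selected) == 0)
        stop("no feature reached the selection frequency threshold",
             call. = FALSE)

      scr_cfg <- config$screening
      scr_cfg$seed <- config$seed + 200L + off
      scr <- run_confounder_screen(sub, sel$selected, scr_cfg)
      log("stratum ", st, ": flagged ", length(scr$flagged),
          " confounders of ", nrow(sub), " (cutoff ",
          format(scr$cutoff, digits = 4), "); ",
          nrow(scr$retained_table), " retained")

      ev <- repeated_cv(scr$retained_table, sel$selected,
                        n_rounds = config$n_cv_rounds, k = config$k,
                        seed = config$seed + 300L + off)
      log("stratum ", st, ": mean AUC ",
          format(ev$summary$mean[ev$summary$metric == "auc"], digits = 4))
      list(selection = sel, screen = scr, evaluation = ev,
           counts = list(n_input = nrow(sub),
                         n_features = length(feature_names(sub)),
                         n_selected = length(sel$selected),
                         n_flagged = length(scr$flagged),
                         n_retained = nrow(scr$retained_table)))
    }, error = function(e) {
      log("stratum ", st, ": SKIPPED (", conditionMessage(e), ")")
      list(error = conditionMessage(e))
    })
    strata_res[[st]] <- res
    counts[[st]] <- res$counts
    if (!is.null(out_dir) && is.null(res$error)) {
      write_selection_result(res$selection,
                             file.path(out_dir, paste0("selection_", st)))
      write_confounder_result(res$screen,
                              file.path(out_dir, paste0("confounders_", st)))
      write_evaluation_report(res$evaluation,
                              file.path(out_dir, paste0("evaluation_", st)))
    }
  }

  comparisons <- .cross_stratum_comparisons(strata_res, log)
  manifest <- list(
    strata = config$strata, seed = config$seed, fast = config$fast,
    selection = unclass(config$selection),
    screening = list(n_rounds = config$screening$n_rounds,
                     subsample_frac = config$screening$subsample_frac,
                     quantile_level = config$screening$quantile_level,
                     learners = vapply(config$screening$learners, `[[`, "",
                                       "family")),
    n_cv_rounds = config$n_cv_rounds, k = config$k,
    input_md5 = input_md5, counts = counts)

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10)
    if (!is.null(comparisons$auc))
      utils::write.csv(comparisons$auc,
                       file.path(out_dir, "comparison_auc.csv"),
                       row.names = FALSE)
    if (!is.null(comparisons$metrics))
      utils::write.csv(comparisons$metrics,
                       file.path(out_dir, "comparison_metrics.csv"),
                       row.names = FALSE)
    if (!is.null(comparisons$overlap))
      utils::write.csv(comparisons$overlap,
                       file.path(out_dir, "feature_overlap.csv"),
                       row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(table = table, strata = strata_res, comparisons = comparisons,
       manifest = manifest)
}

.cross_stratum_comparisons <- function(strata_res, log) {
  ok <- names(strata_res)[vapply(strata_res,
                                 function(x) is.null(x$error), TRUE)]
  sel_sets <- lapply(strata_res[ok], function(x) x$selection$selected)

  overlap <- NULL
  if (length(ok) >= 2) {
    pairs <- utils::combn(ok, 2, simplify = FALSE)
    overlap <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(stratum_a = pr[1], stratum_b = pr[2],
                 n_a = length(sel_sets[[pr[1]]]),
                 n_b = length(sel_sets[[pr[2]]]),
                 n_overlap = length(intersect(sel_sets[[pr[1]]],
                                              sel_sets[[pr[2]]])))
    }))
  }

  auc_cmp <- NULL
  metric_cmp <- NULL
  if ("all" %in% ok) {
    ev_all <- strata_res$all$evaluation
    s_all <- auc_summary(ev_all$summary$mean[ev_all$summary$metric == "auc"],
                         ev_all$n_pos, ev_all$n_neg)
    for (st in setdiff(ok, "all")) {
      ev <- strata_res[[st]]$evaluation
      s_st <- auc_summary(ev$summary$mean[ev$summary$metric == "auc"],
                          ev$n_pos, ev$n_neg)
      cmp <- compare_auc(s_st, s_all)
      log("comparison ", st, " vs all: AUC ",
          format(s_st$A, digits = 4), " vs ", format(s_all$A, digits = 4),
          ", z = ", format(cmp$z, digits = 4),
          ", p = ", format(cmp$p, digits = 4),
          " (note: the all stratum contains the ", st, " patients)")
      auc_cmp <- rbind(auc_cmp,
                       data.frame(stratum = st, auc = s_st$A,
                                  auc_all = s_all$A, z = cmp$z, p = cmp$p))
      if (nrow(ev$per_round) >= 2 && nrow(ev_all$per_round) >= 2) {
        mt <- do.call(rbind, lapply(names(ev$per_round), function(m) {
          tt <- compare_metric_ttest(ev$per_round[[m]], ev_all$per_round[[m]])
          data.frame(stratum = st, metric = m,
                     mean = mean(ev$per_round[[m]]),
                     mean_all = mean(ev_all$per_round[[m]]),
                     t = tt$t, df = tt$df, p = tt$p)
        }))
        metric_cmp <- rbind(metric_cmp, mt)
      }
    }
  }
  list(overlap = overlap, auc = auc_cmp, metrics = metric_cmp)
}
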