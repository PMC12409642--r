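# Synthetic cohort generation and the CSV feature-table format.

.META_COLS <- c("patient_id", "gender", "dfs_months", "label")

#' Specify a synthetic cohort
#'
#' Parameters of the synthetic radiomic cohort generator. Defaults emulate
#' the structure of a resectable colorectal-liver-metastases cohort: 196
#' patients (117 male, 79 female), about 59.7\% progressing within three
#' years, 1316 radiomic features organised in equicorrelated blocks, disjoint
#' male-specific and female-specific discriminative feature sets, and a
#' fraction of label-noise "confounder" patients whose recorded outcome
#' contradicts their feature signal.
#'
#' @param n_male,n_female number of male / female patients.
#' @param prevalence expected fraction of positive (progressing) patients.
#' @param n_features total number of radiomic feature columns.
#' @param n_signal_male,n_signal_female number of discriminative features
#'   planted for each gender; the two sets are disjoint by construction.
#' @param effect_size standardised mean shift (z-units) applied to a
#'   gender's signal features in its positive patients.
#' @param block_size features per equicorrelated noise block; the default of
#'   14 mirrors one block per base feature across the 14 image variants.
#' @param block_rho within-block equicorrelation in [0, 1). The default of
#'   0.7 reflects the strong redundancy of radiomic features, where image
#'   variants of the same base statistic are close surrogates of each other;
#'   each gender's signal features fill whole blocks of their own, so the
#'   discriminative signal is carried by a small number of correlated
#'   feature families rather than 20 independent axes.
#' @param confounder_frac fraction of patients whose label is flipped after
#'   the feature signal is generated (label-noise confounders).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_male = 117, n_female = 79, prevalence = 0.597,
                        n_features = 1316, n_signal_male = 20,
                        n_signal_female = 20, effect_size = 1.5,
                        block_size = 14, block_rho = 0.7,
                        confounder_frac = 0.15, seed = 1L) {
  spec <- structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    prevalence = prevalence, n_features = as.integer(n_features),
    n_signal_male = as.integer(n_signal_male),
    n_signal_female = as.integer(n_signal_female),
    effect_size = effect_size, block_size = as.integer(block_size),
    block_rho = block_rho, confounder_frac = confounder_frac,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  chk <- function(ok, msg) if (!ok) stop("invalid cohort_spec: ", msg,
                                         call. = FALSE)
  chk(spec$n_male >= 0 && spec$n_female >= 0 && spec$n_male + spec$n_female > 0,
      "n_male + n_female must be positive")
  chk(spec$prevalence > 0 && spec$prevalence < 1,
      "prevalence must lie in (0, 1)")
  chk(spec$n_features >= 1, "n_features must be >= 1")
  chk(spec$n_signal_male >= 0 && spec$n_signal_female >= 0,
      "signal feature counts must be non-negative")
  chk(spec$n_signal_male + spec$n_signal_female <= spec$n_features,
      "n_signal_male + n_signal_female must not exceed n_features")
  chk(spec$block_size >= 1, "block_size must be >= 1")
  chk(spec$block_rho >= 0 && spec$block_rho < 1,
      "block_rho must lie in [0, 1)")
  chk(spec$confounder_frac >= 0 && spec$confounder_frac < 1,
      "confounder_frac must lie in [0, 1)")
  invisible(spec)
}

#' Construct a feature table
#'
#' A feature table is a data frame with metadata columns \code{patient_id}
#' (unique strings), \code{gender} (\code{"M"}/\code{"F"}),
#' \code{dfs_months} (non-negative disease-free-survival months) and
#' \code{label} (1 = progression within 3 years, i.e. DFS <= 36 months;
#' 0 otherwise), followed by numeric radiomic feature columns. Labels must
#' be consistent with DFS where both are present, and no feature, gender or
#' label value may be missing.
#'
#' @param df a data frame with the columns described above.
#' @return \code{df} with class \code{feature_table} prepended, validated.
#' @export
feature_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"label" %in% names(df) && "dfs_months" %in% names(df)) {
    df$label <- as.integer(df$dfs_months <= 36)
  }
  req <- c("patient_id", "gender", "label")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("feature table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$gender <- as.character(df$gender)
  df$label <- as.integer(df$label)
  class(df) <- unique(c("feature_table", class(df)))
  validate_feature_table(df)
  df
}

validate_feature_table <- function(table) {
  chk <- function(ok, msg) if (!ok) stop("invalid feature table: ", msg,
                                         call. = FALSE)
  chk(anyDuplicated(table$patient_id) == 0, "duplicate patient_id values")
  chk(anyDuplicated(names(table)) == 0, "duplicate column names")
  chk(!anyNA(table$gender) && all(table$gender %in% c("M", "F")),
      "gender must be 'M' or 'F' with no missing values")
  chk(!anyNA(table$label) && all(table$label %in% c(0L, 1L)),
      "label must be 0/1 with no missing values")
  if ("dfs_months" %in% names(table)) {
    chk(!anyNA(table$dfs_months) && all(table$dfs_months >= 0),
        "dfs_months must be non-negative with no missing values")
    chk(all(table$label == as.integer(table$dfs_months <= 36)),
        "label inconsistent with dfs_months (positive iff DFS <= 36 months)")
  }
  feats <- feature_names(table)
  for (f in feats) {
    col <- table[[f]]
    if (!is.numeric(col))
      stop("invalid feature table: feature column '", f, "' is not numeric",
           call. = FALSE)
    if (anyNA(col))
      stop("invalid feature table: missing value in feature column '", f,
           "' (row ", which(is.na(col))[1], ")", call. = FALSE)
  }
  invisible(table)
}

#' Feature column names of a feature table
#'
#' @param table a \code{feature_table}.
#' @return character vector of feature column names (metadata columns
#'   excluded), in table column order.
#' @export
feature_names <- function(table) {
  setdiff(names(table), .META_COLS)
}

#' Feature matrix of a feature table
#'
#' @param table a \code{feature_table}.
#' @param features optional subset of feature columns.
#' @return numeric matrix (patients x features) with patient_id rownames.
#' @export
feature_matrix <- function(table, features = feature_names(table)) {
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0)
    stop("features not present in table: ",
         paste(utils::head(missing_f, 5), collapse = ", "), call. = FALSE)
  m <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  rownames(m) <- table$patient_id
  storage.mode(m) <- "double"
  m
}

#' Generate a synthetic radiomic cohort
#'
#' Draws a patient-by-feature table with the statistical structure the
#' downstream analysis assumes. Noise features are block-equicorrelated
#' standard normals. Each gender has its own disjoint set of signal
#' features, mean-shifted by \code{effect_size} in that gender's positive
#' patients only. Finally a simple-random \code{confounder_frac} of patients
#' have their label (and DFS) flipped while their features keep the
#' pre-flip class structure, emulating patients whose imaging contradicts
#' their recorded outcome. DFS months are drawn consistent with the final
#' label (at most 36 for positives, above 36 otherwise).
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a \code{\link{feature_table}} with attributes
#'   \code{signal_male}, \code{signal_female} (planted feature names),
#'   \code{flipped} (patient ids whose label was flipped) and \code{spec}.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  n <- spec$n_male + spec$n_female
  p <- spec$n_features

  all_names <- generate_feature_names(TRUE)
  feat_names <- if (p <= length(all_names)) all_names[seq_len(p)] else
    c(all_names, sprintf("synthetic_extra_%04d", seq_len(p - length(all_names))))

  rng <- .with_seed(spec$seed, {
    gender <- c(rep("M", spec$n_male), rep("F", spec$n_female))
    label0 <- stats::rbinom(n, 1L, spec$prevalence)

    # block-equicorrelated noise: x = sqrt(rho) * block factor + sqrt(1-rho) e
    n_blocks <- ceiling(p / spec$block_size)
    block_of <- rep(seq_len(n_blocks), each = spec$block_size)[seq_len(p)]
    factors <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    X <- sqrt(spec$block_rho) * factors[, block_of, drop = FALSE] +
      sqrt(1 - spec$block_rho) * matrix(stats::rnorm(n * p), n, p)

    # signal features fill whole blocks, each gender in blocks of its own,
    # so the two planted sets are disjoint and each forms a correlated
    # feature family (as selected radiomic families are in practice); if
    # there are too few blocks, fall back to disjoint random placement
    need_m <- ceiling(spec$n_signal_male / spec$block_size)
    need_f <- ceiling(spec$n_signal_female / spec$block_size)
    if (need_m + need_f <= n_blocks) {
      blks <- sample.int(n_blocks, need_m + need_f)
      feats_in <- function(bs) which(block_of %in% bs)
      sig_m <- sort(feats_in(blks[seq_len(need_m)]))[
        seq_len(spec$n_signal_male)]
      sig_f <- sort(feats_in(blks[need_m + seq_len(need_f)]))[
        seq_len(spec$n_signal_female)]
    } else {
      idx <- sample.int(p, spec$n_signal_male + spec$n_signal_female)
      sig_m <- sort(idx[seq_len(spec$n_signal_male)])
      sig_f <- sort(idx[spec$n_signal_male + seq_len(spec$n_signal_female)])
    }

    pos_m <- which(gender == "M" & label0 == 1L)
    pos_f <- which(gender == "F" & label0 == 1L)
    X[pos_m, sig_m] <- X[pos_m, sig_m] + spec$effect_size
    X[pos_f, sig_f] <- X[pos_f, sig_f] + spec$effect_size

    label <- label0
    n_flip <- round(spec$confounder_frac * n)
    flip <- if (n_flip > 0) sample.int(n, n_flip) else integer(0)
    label[flip] <- 1L - label[flip]

    dfs <- ifelse(label == 1L, stats::runif(n, 0, 36),
                  stats::runif(n, 36 + 1e-6, 120))
    list(gender = gender, label = label, X = X, dfs = dfs,
         sig_m = sig_m, sig_f = sig_f, flip = flip)
  })

  ids <- sprintf("P%03d", seq_len(n))
  colnames(rng$X) <- feat_names
  df <- data.frame(patient_id = ids, gender = rng$gender,
                   dfs_months = rng$dfs, label = as.integer(rng$label),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(rng$X))
  tab <- feature_table(df)
  attr(tab, "signal_male") <- feat_names[rng$sig_m]
  attr(tab, "signal_female") <- feat_names[rng$sig_f]
  attr(tab, "flipped") <- ids[sort(rng$flip)]
  attr(tab, "spec") <- spec
  tab
}

# evaluate expr under a local RNG seed without touching the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a feature table to CSV
#'
#' Plain UTF-8 CSV with a header row: \code{patient_id}, \code{gender},
#' \code{dfs_months} (if present), \code{label}, then numeric feature
#' columns. Values are written at full precision so a write/read round-trip
#' is lossless.
#'
#' @param table a \code{feature_table}.
#' @param path output file path.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the format of \code{\link{write_feature_table}}: required columns
#' \code{patient_id}, \code{gender} and at least one of \code{dfs_months} /
#' \code{label}; every remaining column is a numeric feature. When
#' \code{label} is absent it is derived from DFS (positive iff
#' \code{dfs_months <= 36}). Validation failures name the offending column
#' and row.
#'
#' @param path CSV file path.
#' @return a validated \code{\link{feature_table}}.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!"patient_id" %in% names(df))
    stop("parse error: required column 'patient_id' missing", call. = FALSE)
  if (!"gender" %in% names(df))
    stop("parse error: required column 'gender' missing", call. = FALSE)
  if (!any(c("dfs_months", "label") %in% names(df)))
    stop("parse error: need at least one of 'dfs_months'/'label'",
         call. = FALSE)
  feats <- setdiff(names(df), .META_COLS)
  for (f in feats) {
    if (!is.numeric(df[[f]]))
      stop("parse error: feature column '", f, "' is not numeric",
           call. = FALSE)
    if (anyNA(df[[f]]))
      stop("parse error: missing value in feature column '", f, "' (row ",
           which(is.na(df[[f]]))[1], ")", call. = FALSE)
  }
  feature_table(df)
}

#' Subset a feature table to one gender stratum
#'
#' @param table a \code{feature_table}.
#' @param stratum one of \code{"all"}, \code{"male"}, \code{"female"}.
#' @return the corresponding \code{feature_table} subset.
#' @export
stratum_subset <- function(table, stratum = c("all", "male", "female")) {
  stratum <- match.arg(stratum)
  keep <- switch(stratum, all = rep(TRUE, nrow(table)),
                 male = table$gender == "M", female = table$gender == "F")
  out <- table[keep, , drop = FALSE]
  class(out) <- class(table)
  out
}
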