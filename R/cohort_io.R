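#' Read a tabular cohort from CSV
#'
#' Reads one row per patient presentation. Feature columns must be numeric;
#' empty cells and the literal `NA` are treated as missing. Outcome and
#' sensitive columns may hold strings or integers; their vocabularies are
#' recorded in first-appearance order and mapped to dense 0-based codes.
#'
#' @param path path to a CSV file with a header row.
#' @param outcome_col name of the outcome column.
#' @param sensitive_col name of the sensitive-attribute column.
#' @param feature_cols names of the feature columns; defaults to every other
#'   column.
#' @return a [sample_set()].
#' @export
read_cohort <- function(path, outcome_col, sensitive_col, feature_cols = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  for (col in c(outcome_col, sensitive_col)) {
    if (!col %in% names(raw)) {
      stop("cohort file is missing required column '", col, "'")
    }
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(raw), c(outcome_col, sensitive_col))
  } else {
    missing_feat <- setdiff(feature_cols, names(raw))
    if (length(missing_feat)) {
      stop("cohort file is missing feature column(s): ",
           paste(missing_feat, collapse = ", "))
    }
  }
  if (!length(feature_cols)) stop("no feature columns in cohort file")

  feat <- matrix(NA_real_, nrow(raw), length(feature_cols),
                 dimnames = list(NULL, feature_cols))
  for (j in seq_along(feature_cols)) {
    cell <- raw[[feature_cols[j]]]
    empty <- is.na(cell) | cell == "" | cell == "NA"
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in feature column '%s' at row %d",
                   cell[bad[1]], feature_cols[j], bad[1]))
    }
    val[empty] <- NA_real_
    feat[, j] <- val
  }

  out_levels <- unique(raw[[outcome_col]])
  sens_levels <- unique(raw[[sensitive_col]])
  if (anyNA(out_levels) || any(out_levels == "") ||
      anyNA(sens_levels) || any(sens_levels == "")) {
    stop("outcome and sensitive labels must not be missing")
  }
  sample_set(
    feat,
    match(raw[[outcome_col]], out_levels) - 1L,
    match(raw[[sensitive_col]], sens_levels) - 1L,
    feature_names = feature_cols,
    outcome_levels = out_levels,
    sensitive_levels = sens_levels
  )
}

#' Write a cohort to CSV
#'
#' Features are written as decimal text with 17 significant digits, so a
#' write/read round trip reproduces every double bit-for-bit. Missing cells
#' are written as empty fields; labels are written using their vocabulary
#' names.
#'
#' @param data a [sample_set()].
#' @param path output CSV path.
#' @param outcome_col,sensitive_col column names used for the labels.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, outcome_col = "outcome",
                         sensitive_col = "sensitive") {
  txt <- matrix("", n_samples(data), n_features(data))
  ok <- !is.na(data$features)
  txt[ok] <- sprintf("%.17g", data$features[ok])
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- data$feature_names
  df[[outcome_col]] <- data$outcome_levels[data$outcome + 1L]
  df[[sensitive_col]] <- data$sensitive_levels[data$sensitive + 1L]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit preprocessing statistics on a training split
#'
#' Computes, per feature: the median over non-missing values (used for
#' imputation), and the mean and standard deviation of the median-imputed
#' column (used for standardization). Statistics are fitted on the training
#' split only and then applied unchanged to validation and test data.
#'
#' @param train a [sample_set()] (the training split).
#' @return an object of class `preprocess_stats` with fields `median`, `mean`,
#'   `sd` (length-D numeric) and `constant` (logical flag for zero-variance
#'   features).
#' @export
fit_preprocess <- function(train) {
  x <- train$features
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    stop("feature(s) with no observed training values: ",
         paste(train$feature_names[all_missing], collapse = ", "))
  }
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  imp <- x
  for (j in seq_len(ncol(x))) imp[is.na(imp[, j]), j] <- med[j]
  mu <- colMeans(imp)
  sdev <- apply(imp, 2L, stats::sd)
  structure(
    list(median = med, mean = mu, sd = sdev,
         constant = sdev < 1e-12,
         feature_names = train$feature_names),
    class = "preprocess_stats"
  )
}

#' Apply fitted preprocessing to a sample set
#'
#' Missing cells are replaced by the stored training median, then every
#' feature is centred and scaled by the stored training mean and standard
#' deviation. Constant features (training s.d. zero) map to 0 rather than
#' dividing by zero. The result has no missing cells.
#'
#' @param stats a `preprocess_stats` object from [fit_preprocess()].
#' @param data a [sample_set()] with the same feature dimension.
#' @return a preprocessed [sample_set()].
#' @export
apply_preprocess <- function(stats, data) {
  stopifnot(inherits(stats, "preprocess_stats"))
  d <- n_features(data)
  if (length(stats$median) != d) {
    stop(sprintf("preprocess stats were fitted on %d features but data has %d",
                 length(stats$median), d))
  }
  x <- data$features
  for (j in seq_len(d)) x[is.na(x[, j]), j] <- stats$median[j]
  scale_by <- ifelse(stats$constant, 1, stats$sd)
  x <- sweep(x, 2L, stats$mean, "-")
  x <- sweep(x, 2L, scale_by, "/")
  x[, stats$constant] <- 0
  out <- data
  out$features <- x
  out
}

#' Specify a train/validation/test split
#'
#' @param fractions numeric vector of 2 (train/validation) or 3
#'   (train/validation/test) fractions in (0,1) summing to 1.
#' @param seed integer seed; the same seed always yields the same split.
#' @param stratify one of `"both"` (outcome x sensitive jointly, the
#'   default, since both imbalances matter here), `"outcome"`, `"sensitive"`,
#'   or `"none"`.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.6, 0.2, 0.2), seed = 0L,
                       stratify = c("both", "outcome", "sensitive", "none")) {
  stratify <- match.arg(stratify)
  if (!length(fractions) %in% c(2L, 3L)) {
    stop("fractions must have length 2 or 3")
  }
  if (any(fractions <= 0) || any(fractions >= 1)) {
    stop("each fraction must lie strictly between 0 and 1")
  }
  if (abs(sum(fractions) - 1) > 1e-12) stop("fractions must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratify = stratify),
            class = "split_spec")
}

# Largest-remainder apportionment of n items into parts with the given
# fractions; every part count is within 1 of n * fraction.
apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a cohort into train/validation(/test) parts
#'
#' Rows are partitioned disjointly and exhaustively. With stratification,
#' each stratum is apportioned separately so its per-part fractions are
#' within one sample of the requested fractions. Deterministic given the
#' spec's seed.
#'
#' @param data a [sample_set()].
#' @param spec a [split_spec()].
#' @return a named list of [sample_set()] parts: `train`, `validation` and,
#'   with 3 fractions, `test`.
#' @export
split_cohort <- function(data, spec) {
  stopifnot(inherits(spec, "split_spec"))
  n_parts <- length(spec$fractions)
  strata <- switch(spec$stratify,
    both = paste(data$outcome, data$sensitive, sep = "/"),
    outcome = as.character(data$outcome),
    sensitive = as.character(data$sensitive),
    none = rep("all", n_samples(data))
  )
  idx_by <- split(seq_len(n_samples(data)), strata)
  small <- vapply(idx_by, length, 1L) < n_parts
  if (any(small)) {
    stop("stratum too small to split: ",
         paste(names(idx_by)[small], collapse = ", "))
  }
  parts <- vector("list", n_parts)
  with_seed(spec$seed, {
    for (s in idx_by) {
      s <- sample(s)
      cnt <- apportion(length(s), spec$fractions)
      off <- 0L
      for (p in seq_len(n_parts)) {
        parts[[p]] <- c(parts[[p]], s[off + seq_len(cnt[p])])
        off <- off + cnt[p]
      }
    }
  })
  parts <- lapply(parts, sort)
  names(parts) <- c("train", "validation", "test")[seq_len(n_parts)]
  lapply(parts, function(i) data[i])
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package randomness never leaks into user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
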