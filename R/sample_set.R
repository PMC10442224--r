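#' Construct a sample set
#'
#' A `sample_set` is the unit of data every stage of the package consumes: a
#' numeric feature matrix (with `NA` marking missing cells), an integer
#' outcome label per row and an integer sensitive-attribute label per row.
#' Labels are dense 0-based integers; the original label vocabulary is kept in
#' `outcome_levels` / `sensitive_levels` so reports can use the source names.
#'
#' @param features numeric matrix, one row per sample; `NA` means missing.
#' @param outcome integer vector of 0-based outcome labels, length `nrow(features)`.
#' @param sensitive integer vector of 0-based sensitive-group labels.
#' @param feature_names optional character vector of feature names; defaults
#'   to the column names of `features` or `f1..fD`.
#' @param outcome_levels character vector naming the outcome classes, in the
#'   order of their integer codes.
#' @param sensitive_levels character vector naming the sensitive groups.
#' @return an object of class `sample_set`.
#' @export
sample_set <- function(features, outcome, sensitive,
                       feature_names = NULL,
                       outcome_levels = NULL,
                       sensitive_levels = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  if (n < 1L || d < 1L) {
    stop("a sample_set needs at least one row and one feature column")
  }
  outcome <- as.integer(outcome)
  sensitive <- as.integer(sensitive)
  if (length(outcome) != n || length(sensitive) != n) {
    stop("outcome and sensitive labels must have one entry per row")
  }
  if (anyNA(outcome) || anyNA(sensitive)) {
    stop("labels must not be missing")
  }
  if (any(outcome < 0L) || any(sensitive < 0L)) {
    stop("labels must be 0-based non-negative integers")
  }
  if (is.null(outcome_levels)) {
    outcome_levels <- as.character(seq_len(max(outcome) + 1L) - 1L)
  }
  if (is.null(sensitive_levels)) {
    sensitive_levels <- as.character(seq_len(max(sensitive) + 1L) - 1L)
  }
  if (max(outcome) >= length(outcome_levels)) {
    stop("outcome label out of range of outcome_levels")
  }
  if (max(sensitive) >= length(sensitive_levels)) {
    stop("sensitive label out of range of sensitive_levels")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d))
  }
  stopifnot(length(feature_names) == d)
  colnames(features) <- feature_names
  structure(
    list(
      features = features,
      outcome = outcome,
      sensitive = sensitive,
      feature_names = feature_names,
      outcome_levels = as.character(outcome_levels),
      sensitive_levels = as.character(sensitive_levels)
    ),
    class = "sample_set"
  )
}

#' Number of samples / features in a sample set
#' @param x a `sample_set`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$features)

#' @rdname n_samples
#' @export
n_features <- function(x) ncol(x$features)

#' Per-class outcome counts of a sample set
#'
#' Counts every class of the vocabulary, including classes absent from this
#' particular subset (count 0), so reward weights derived from a training
#' split stay aligned with the full label vocabulary.
#'
#' @param x a `sample_set`.
#' @return named integer vector, one entry per outcome class.
#' @export
outcome_counts <- function(x) {
  k <- length(x$outcome_levels)
  cnt <- tabulate(x$outcome + 1L, nbins = k)
  names(cnt) <- x$outcome_levels
  cnt
}

#' Per-group sensitive-attribute counts of a sample set
#' @param x a `sample_set`.
#' @return named integer vector, one entry per sensitive group.
#' @export
sensitive_counts <- function(x) {
  m <- length(x$sensitive_levels)
  cnt <- tabulate(x$sensitive + 1L, nbins = m)
  names(cnt) <- x$sensitive_levels
  cnt
}

#' Subset a sample set by row indices
#' @param x a `sample_set`.
#' @param i integer row indices.
#' @param ... ignored.
#' @return a `sample_set` with the selected rows and unchanged vocabularies.
#' @export
`[.sample_set` <- function(x, i, ...) {
  sample_set(
    x$features[i, , drop = FALSE],
    x$outcome[i],
    x$sensitive[i],
    feature_names = x$feature_names,
    outcome_levels = x$outcome_levels,
    sensitive_levels = x$sensitive_levels
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(
    "<sample_set> %d samples x %d features, %d outcome classes, %d sensitive groups\n",
    n_samples(x), n_features(x),
    length(x$outcome_levels), length(x$sensitive_levels)
  ))
  cat("  outcome counts:  ",
      paste(sprintf("%s=%d", x$outcome_levels, outcome_counts(x)), collapse = ", "),
      "\n", sep = "")
  cat("  sensitive counts:",
      paste(sprintf("%s=%d", x$sensitive_levels, sensitive_counts(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
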