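#' Vector-normalized reciprocal class weights
#'
#' Computes the per-class reward weight lambda: the elementwise reciprocal of
#' the class counts, normalized so the weight vector has unit Euclidean norm.
#' Rarer classes therefore earn strictly larger weights, and the weights are
#' invariant to uniformly rescaling all counts.
#'
#' @param class_counts positive integer vector of per-class training counts.
#' @param norm `"l2"` (the default: divide by the Euclidean norm, so the
#'   result is a unit vector) or `"squared"` (divide by the squared norm; kept
#'   as a sensitivity switch because the printed normalization in some
#'   descriptions of this weighting is typographically ambiguous).
#' @return numeric vector of weights, same length as `class_counts`.
#' @export
compute_lambda <- function(class_counts, norm = c("l2", "squared")) {
  norm <- match.arg(norm)
  if (any(class_counts < 1)) {
    bad <- which(class_counts < 1)
    stop("class count must be >= 1; offending class index (0-based): ",
         paste(bad - 1L, collapse = ", "))
  }
  recip <- 1 / as.numeric(class_counts)
  denom <- sum(recip^2)
  if (norm == "l2") denom <- sqrt(denom)
  recip / denom
}

#' Construct a reward scheme
#'
#' Bundles the outcome-class and sensitive-class lambda weight vectors with
#' the discount factor and the reward mode. In `debias` mode a correct
#' prediction earns `+lambda_sensitive[group]` — inversely proportional to
#' the group's frequency, so correct predictions for rare groups are worth
#' more — and an incorrect prediction costs `-lambda_outcome[label]`. In
#' `outcome_only` mode (the no-debiasing comparator) both branches use the
#' outcome weights.
#'
#' @param outcome_counts per-outcome-class training counts.
#' @param sensitive_counts per-sensitive-group training counts.
#' @param gamma discount factor in [0,1); defaults to 0.1, weighting
#'   immediate classification reward far above the future of the episode.
#' @param mode `"debias"` or `"outcome_only"`.
#' @param norm passed to [compute_lambda()].
#' @return an object of class `reward_scheme`.
#' @export
reward_scheme <- function(outcome_counts, sensitive_counts, gamma = 0.1,
                          mode = c("debias", "outcome_only"),
                          norm = c("l2", "squared")) {
  mode <- match.arg(mode)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  structure(
    list(lambda_outcome = compute_lambda(outcome_counts, norm),
         lambda_sensitive = compute_lambda(sensitive_counts, norm),
         gamma = gamma, mode = mode),
    class = "reward_scheme"
  )
}

#' Reward for a single prediction
#'
#' @param action predicted class (0-based).
#' @param outcome_label true outcome class (0-based).
#' @param sensitive_label sensitive group (0-based).
#' @param scheme a [reward_scheme()].
#' @return scalar reward; positive iff the prediction is correct.
#' @export
reward_of <- function(action, outcome_label, sensitive_label, scheme) {
  stopifnot(inherits(scheme, "reward_scheme"))
  k <- length(scheme$lambda_outcome)
  m <- length(scheme$lambda_sensitive)
  if (action < 0 || action >= k) stop("action out of range")
  if (outcome_label < 0 || outcome_label >= k) stop("outcome_label out of range")
  if (sensitive_label < 0 || sensitive_label >= m) {
    stop("sensitive_label out of range")
  }
  correct <- action == outcome_label
  if (scheme$mode == "debias") {
    if (correct) scheme$lambda_sensitive[sensitive_label + 1L]
    else -scheme$lambda_outcome[outcome_label + 1L]
  } else {
    if (correct) scheme$lambda_outcome[outcome_label + 1L]
    else -scheme$lambda_outcome[outcome_label + 1L]
  }
}

#' One environment step: reward and termination
#'
#' Implements the environment's reward procedure. The episode terminates
#' (`terminal = TRUE`) when the agent misclassifies a minority-outcome-class
#' sample — cutting off all further reward, which is what couples actions to
#' states in this sequential formulation — or when the last sample of the
#' pass has been consumed.
#'
#' @param sample_index 1-based row index into `data`.
#' @param action predicted class (0-based).
#' @param data a [sample_set()].
#' @param scheme a [reward_scheme()].
#' @param minority_label the outcome class with the smallest training count
#'   (0-based).
#' @param is_last_sample whether this is the final sample of the pass.
#' @return a list with elements `reward` and `terminal`.
#' @export
env_step <- function(sample_index, action, data, scheme, minority_label,
                     is_last_sample = FALSE) {
  if (sample_index < 1L || sample_index > n_samples(data)) {
    stop("sample_index out of range")
  }
  label <- data$outcome[sample_index]
  r <- reward_of(action, label, data$sensitive[sample_index], scheme)
  term <- (action != label && label == minority_label) || isTRUE(is_last_sample)
  list(reward = r, terminal = term)
}

#' Minority outcome class of a training set
#' @param train a [sample_set()].
#' @return the 0-based outcome label with the smallest training count
#'   (lowest index on ties).
#' @export
minority_outcome <- function(train) {
  unname(which.min(outcome_counts(train)) - 1L)
}
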