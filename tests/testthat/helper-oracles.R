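# Independent oracles used across the suite. These deliberately use naive
# formulations (pair enumeration, explicit sorting, literal formulas) so they
# share no code with the implementation they check.

# AUROC by exhaustive positive/negative pair enumeration, ties counted 1/2.
auroc_enum <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Population (divide-by-M) standard deviation.
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

# Median by explicit sort (midpoint convention for even counts).
median_by_sort <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Write a small cohort CSV from a data.frame of character columns.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A tiny preprocessed sample set for model-fitting unit tests: two Gaussian
# classes, two features, optionally two groups.
tiny_toy <- function(n_per_class = 100, margin = 4, seed = 1, groups = 1L) {
  ss <- generate_separable_toy(n_per_class, margin, seed = seed)
  if (groups > 1L) {
    set.seed(seed + 1000)
    ss$sensitive <- sample(0:(groups - 1L), n_samples(ss), replace = TRUE)
    ss$sensitive_levels <- LETTERS[seq_len(groups)]
  }
  stats <- fit_preprocess(ss)
  apply_preprocess(stats, ss)
}

# A dueling net whose Q-values are a given constant pair for every state:
# zero trunk, advantage bias solving g(m) = m - tanh(m/2) = Q2 - Q1, value
# bias absorbing the rest.
const_q_net <- function(qvec) {
  n <- dueling_net(2L, 2L, hidden = 4L)
  n$W1[] <- 0
  m <- uniroot(function(m) m - tanh(m / 2) - (qvec[2] - qvec[1]),
               c(-60, 60), tol = 1e-14)$root
  n$ba <- c(0, m)
  n$bv <- qvec[1] + 1 / (1 + exp(m))
  stopifnot(isTRUE(all.equal(q_values(n, c(1, 2)), qvec, tolerance = 1e-9)))
  n
}

# The headline biased-cohort study conditions: shared between the unit and
# acceptance suites so the scenario is defined exactly once.
headline_cohort_config <- function(seed) {
  cohort_config(
    n_samples = 4000L, n_features = 10L, n_informative = 5L,
    outcome_prevalence = 0.2, group_proportions = c(0.8, 0.2),
    signal_effect = 2, bias_shift = 1,
    bias_label_noise = c(0.05, 0.30), missing_rate = 0.05,
    seed = seed
  )
}

# One headline-scenario replicate: train debias RL and the unweighted
# baseline, calibrate each to 0.9 validation sensitivity, evaluate on test.
headline_replicate <- function(seed, rl_steps = 10000L, hidden = 128L,
                               epochs = 30L) {
  cohort <- generate_cohort(headline_cohort_config(seed))
  parts <- split_cohort(cohort, split_spec(c(0.6, 0.2, 0.2), seed = seed))
  stats <- fit_preprocess(parts$train)
  prep <- lapply(parts, function(p) apply_preprocess(stats, p))
  rl <- suppressWarnings(train_dqn(prep$train, NULL,
    training_config(total_steps = rl_steps, hidden = hidden, seed = seed)))
  bl <- train_baseline_nn(prep$train, NULL,
    baseline_config(epochs = epochs, hidden = hidden, seed = seed))
  cmp <- compare_models(list(rl_debias = rl, baseline = bl),
                        prep$test, prep$validation,
                        target_sensitivity = 0.9)
  cmp$table
}
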