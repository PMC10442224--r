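test_that("read_cohort builds a sample set with first-appearance vocabularies", {
  path <- write_fixture_csv(data.frame(
    age = c("34", "51", "", "47", "62"),
    crp = c("1.2", "3.4", "5.6", "NA", "0.1"),
    wbc = c("7", "8", "9", "10", "11"),
    outcome = c("0", "1", "0", "0", "1"),
    ethnicity = c("A", "B", "A", "C", "B")
  ))
  ss <- read_cohort(path, outcome_col = "outcome", sensitive_col = "ethnicity")
  expect_s3_class(ss, "sample_set")
  expect_equal(n_samples(ss), 5L)
  expect_equal(n_features(ss), 3L)
  expect_equal(length(ss$outcome_levels), 2L)
  expect_equal(length(ss$sensitive_levels), 3L)
  expect_equal(ss$sensitive_levels, c("A", "B", "C"))
  # empty and "NA" cells become missing; everything else parses
  expect_true(is.na(ss$features[3, "age"]))
  expect_true(is.na(ss$features[4, "crp"]))
  expect_equal(sum(is.na(ss$features)), 2L)
  expect_equal(unname(outcome_counts(ss)), c(3L, 2L))
})

test_that("read_cohort errors name the offending column or row", {
  path <- write_fixture_csv(data.frame(f1 = c("1", "2"), outcome = c("0", "1")))
  expect_error(read_cohort(path, "outcome", "ethnicity"), "ethnicity")
  bad <- write_fixture_csv(data.frame(f1 = c("1", "oops"),
                                      outcome = c("0", "1"),
                                      z = c("A", "B")))
  expect_error(read_cohort(bad, "outcome", "z"), "row 2")
  expect_error(read_cohort(tempfile(), "outcome", "z"), "not found")
})

test_that("write/read round trip reproduces features and labels exactly", {
  set.seed(42)
  ss <- generate_cohort(cohort_config(n_samples = 60L, n_features = 4L,
                                      missing_rate = 0.1, seed = 7L))
  path <- tempfile(fileext = ".csv")
  write_cohort(ss, path)
  back <- read_cohort(path, "outcome", "sensitive")
  expect_identical(back$outcome, ss$outcome)
  expect_identical(back$sensitive, ss$sensitive)
  expect_identical(back$outcome_levels, ss$outcome_levels)
  expect_identical(is.na(back$features), is.na(ss$features))
  expect_identical(back$features[!is.na(ss$features)],
                   ss$features[!is.na(ss$features)])
})

test_that("fit_preprocess matches a sorting-oracle median and flags constants", {
  ss <- sample_set(
    cbind(a = c(1, NA, 3), b = c(5, 5, 5), c = c(2, 4, 9)),
    outcome = c(0L, 1L, 0L), sensitive = c(0L, 0L, 0L)
  )
  st <- fit_preprocess(ss)
  expect_equal(unname(st$median["a"]), median_by_sort(c(1, 3)))
  expect_equal(unname(st$median["a"]), 2)
  expect_equal(unname(st$median["c"]), median_by_sort(c(2, 4, 9)))
  expect_equal(unname(st$sd["b"]), 0)
  expect_equal(unname(st$constant), c(FALSE, TRUE, FALSE))

  all_missing <- sample_set(cbind(a = c(NA_real_, NA_real_), b = c(1, 2)),
                            outcome = c(0L, 1L), sensitive = c(0L, 0L))
  expect_error(fit_preprocess(all_missing), "a")
})

test_that("apply_preprocess imputes the training median then standardizes", {
  train <- sample_set(cbind(x = c(1, NA, 3), y = c(2, 0, 4)),
                      outcome = c(0L, 1L, 0L), sensitive = c(0L, 0L, 0L))
  st <- fit_preprocess(train)
  out <- apply_preprocess(st, train)
  expect_false(anyNA(out$features))
  expect_equal(colMeans(out$features), c(x = 0, y = 0), tolerance = 1e-8)
  expect_equal(apply(out$features, 2, sd), c(x = 1, y = 1), tolerance = 1e-8)

  # a missing test cell is imputed to the training median (2) before scaling
  test <- sample_set(cbind(x = NA_real_, y = 6),
                     outcome = 0L, sensitive = 0L)
  tout <- apply_preprocess(st, test)
  expect_equal(tout$features[1, "x"], (2 - st$mean["x"]) / st$sd["x"],
               ignore_attr = TRUE)

  # constant training features map to 0, not NaN
  ctrain <- sample_set(cbind(k = c(5, 5, 5), y = c(1, 2, 3)),
                       outcome = c(0L, 1L, 0L), sensitive = c(0L, 0L, 0L))
  cout <- apply_preprocess(fit_preprocess(ctrain), ctrain)
  expect_equal(unname(cout$features[, "k"]), c(0, 0, 0))

  wrong_d <- sample_set(matrix(1, 2, 3), outcome = c(0L, 1L),
                        sensitive = c(0L, 0L))
  expect_error(apply_preprocess(st, wrong_d), "features")
})

test_that("split_cohort is an exact, stratified, deterministic partition", {
  ss <- generate_cohort(cohort_config(n_samples = 1000L, n_features = 3L,
                                      outcome_prevalence = 0.11,
                                      group_proportions = c(0.7, 0.3),
                                      missing_rate = 0, seed = 3L))
  spec <- split_spec(c(0.6, 0.2, 0.2), seed = 11L, stratify = "outcome")
  parts <- split_cohort(ss, spec)
  expect_equal(vapply(parts, n_samples, 1L),
               c(train = 600L, validation = 200L, test = 200L))

  # disjoint and exhaustive partition (row-identity via feature fingerprints)
  key <- function(p) sort(apply(p$features, 1, paste, collapse = "|"))
  all_rows <- unlist(lapply(parts, function(p)
    apply(p$features, 1, paste, collapse = "|")))
  expect_equal(unname(sort(all_rows)), key(ss))
  expect_equal(anyDuplicated(all_rows), 0L)

  # per-part positive counts within 1 sample of the requested fraction
  n_pos <- sum(ss$outcome == 1L)
  for (p in parts) {
    frac <- n_samples(p) / n_samples(ss)
    expect_lte(abs(sum(p$outcome == 1L) - n_pos * frac), 1)
  }

  # same seed, same assignment
  parts2 <- split_cohort(ss, spec)
  expect_identical(lapply(parts, `[[`, "features"),
                   lapply(parts2, `[[`, "features"))
})

test_that("split_cohort rejects bad fractions and undersized strata", {
  expect_error(split_spec(c(0.5, 0.4)), "sum to 1")
  expect_error(split_spec(c(1, 0, 0)), "strictly between")
  tinystrat <- sample_set(matrix(rnorm(8), 4, 2),
                          outcome = c(0L, 0L, 0L, 1L),
                          sensitive = rep(0L, 4))
  expect_error(
    split_cohort(tinystrat, split_spec(c(0.6, 0.2, 0.2), stratify = "outcome")),
    "stratum"
  )
})
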