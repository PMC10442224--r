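test_that("confusion counts follow the closed-on-positive threshold rule", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.5, 0.4, 0.1)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0)
  cm <- confusion_at(scores, labels, 0.55)
  expect_equal(cm[c("tp", "fn", "fp", "tn")],
               list(tp = 4L, fn = 1L, fp = 0L, tn = 3L))
  # perfect separation at a cut between the classes
  cm2 <- confusion_at(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(cm2$fn + cm2$fp, 0L)
  cm3 <- confusion_at(scores, labels, 2)
  expect_equal(cm3$tp + cm3$fp, 0L)
  # a score exactly at the threshold counts as positive
  expect_equal(confusion_at(c(0.5), c(1), 0.5)$tp, 1L)
  expect_error(confusion_at(c(0.1), c(2), 0.5), "binary")
})

test_that("classification metrics match hand-worked values with CIs", {
  cm <- structure(list(tp = 8L, fp = 10L, tn = 80L, fn = 2L),
                  class = "confusion_counts")
  m <- classification_metrics(cm)
  expect_equal(m$sensitivity[["value"]], 0.8)
  expect_lt(abs(m$specificity[["value"]] - 0.888889), 1e-6)
  expect_lt(abs(m$ppv[["value"]] - 0.444444), 1e-6)
  expect_lt(abs(m$npv[["value"]] - 0.975610), 1e-6)
  expect_lt(abs(m$f1 - 0.571429), 1e-6)
  # normal-approximation CI brackets the point estimate
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_lte(m[[nm]][["low"]], m[[nm]][["value"]])
    expect_gte(m[[nm]][["high"]], m[[nm]][["value"]])
  }
  expect_equal(m$sensitivity[["low"]], 0.8 - 1.96 * sqrt(0.8 * 0.2 / 10),
               tolerance = 1e-4)

  perfect <- classification_metrics(
    structure(list(tp = 5L, fp = 0L, tn = 5L, fn = 0L),
              class = "confusion_counts"))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$ppv[["value"]], 1)

  degenerate <- classification_metrics(
    structure(list(tp = 0L, fp = 0L, tn = 3L, fn = 2L),
              class = "confusion_counts"))
  expect_true(is.na(degenerate$ppv[["value"]]))
})

test_that("auroc equals exhaustive pair enumeration and is rank-invariant", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    scores <- round(rnorm(n), 1)          # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_enum(scores, labels))
    expect_equal(auroc(exp(3 * scores) - 2, labels), auroc(scores, labels))
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("Hanley-McNeil interval matches the worked standard error", {
  ci <- hanley_mcneil_ci(0.8, 10, 100)
  expect_lt(abs(ci$se - 0.086255), 1e-6)
  expect_equal(ci$low, 0.630941, tolerance = 1e-5)
  expect_equal(ci$high, 0.969059, tolerance = 1e-5)
  perfect <- hanley_mcneil_ci(1, 20, 50)
  expect_equal(perfect$se, 0)
  expect_equal(c(perfect$low, perfect$high), c(1, 1))
  set.seed(10)
  for (i in 1:20) {
    a <- runif(1)
    ci <- hanley_mcneil_ci(a, sample(5:50, 1), sample(5:50, 1))
    expect_lte(ci$low, a)
    expect_gte(ci$high, a)
  }
})

test_that("equalized-odds dispersion uses population s.d. of group rates", {
  # two groups engineered to TPRs {0.8, 0.6} and equal FPRs
  scores <- c(rep(c(1, 1, 1, 1, 0), 2), rep(c(1, 1, 1, 0, 0), 2), 1, 0, 1, 0)
  labels <- c(rep(1, 20), 0, 0, 0, 0)
  groups <- c(rep(0L, 10), rep(1L, 10), 0L, 0L, 1L, 1L)
  fr <- equalized_odds_sd(scores, labels, groups, threshold = 0.5)
  expect_equal(unname(fr$tpr), c(0.8, 0.6))
  expect_equal(fr$sd_tp, 0.1)
  expect_equal(fr$sd_fp, 0)
  expect_equal(fr$sd_tp, pop_sd(c(0.8, 0.6)))

  expect_lt(abs(pop_sd(c(1, 0.5, 0)) - 0.408248), 1e-6)
  expect_lt(abs(pop_sd(c(0.1, 0.1, 0.4)) - 0.141421), 1e-6)

  # identical rates across groups give zero dispersion
  fr0 <- equalized_odds_sd(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0L, 0L, 1L, 1L), 0.5)
  expect_equal(fr0$sd_tp, 0)
  expect_equal(fr0$sd_fp, 0)

  # permutation of group identities leaves the dispersion unchanged
  set.seed(11)
  sc <- runif(60); lb <- rbinom(60, 1, 0.4); gr <- sample(0:2, 60, replace = TRUE)
  if (all(tabulate(gr[lb == 1] + 1L, 3) > 0) &&
      all(tabulate(gr[lb == 0] + 1L, 3) > 0)) {
    f1 <- equalized_odds_sd(sc, lb, gr, 0.5)
    perm <- c(2L, 0L, 1L)
    f2 <- equalized_odds_sd(sc, lb, perm[gr + 1L], 0.5)
    expect_equal(f1$sd_tp, f2$sd_tp)
    expect_equal(f1$sd_fp, f2$sd_fp)
  }

  # a group with no positives is dropped from sd_tp with a warning
  expect_warning(
    fr2 <- equalized_odds_sd(c(1, 0, 1), c(1, 0, 0), c(0L, 0L, 1L), 0.5),
    "no positives"
  )
  expect_equal(fr2$sd_tp, 0)   # only one group contributes
})

test_that("per-group confusion cells sum to the pooled cells", {
  set.seed(12)
  sc <- runif(200); lb <- rbinom(200, 1, 0.3)
  gr <- sample(0:2, 200, replace = TRUE)
  pooled <- confusion_at(sc, lb, 0.6)
  cells <- sapply(0:2, function(g) {
    cm <- confusion_at(sc[gr == g], lb[gr == g], 0.6)
    c(cm$tp, cm$fp, cm$tn, cm$fn)
  })
  expect_equal(rowSums(cells),
               c(pooled$tp, pooled$fp, pooled$tn, pooled$fn))
})

test_that("threshold calibration hits the target sensitivity from above", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.5, 0.4, 0.1)
  lb <- c(1, 1, 1, 1, 1, 0, 0, 0)
  expect_equal(adjust_threshold(sc, lb, 0.8), 0.6)   # sensitivity exactly 4/5
  expect_equal(adjust_threshold(sc, lb, 0), 0.9)     # vacuous target
  # perfectly separated scores: threshold above all negatives, sensitivity 1
  thr <- adjust_threshold(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0), 1)
  expect_gt(thr, 0.3)
  expect_equal(sum(c(0.9, 0.8) >= thr), 2L)
  expect_error(adjust_threshold(c(0.5), c(0), 0.9), "positives")
  # whenever any threshold meets the target, the returned one does
  set.seed(13)
  for (i in 1:20) {
    sc <- runif(40); lb <- rbinom(40, 1, 0.4)
    if (sum(lb) == 0) next
    tg <- runif(1)
    thr <- adjust_threshold(sc, lb, tg)
    expect_gte(sum(sc >= thr & lb == 1) / sum(lb), tg)
  }
})

test_that("paired accuracy comparison behaves like a signed-rank test", {
  labels <- rep(c(0, 1), 50)
  preds <- as.integer(runif(100) < 0.5)
  expect_equal(paired_accuracy_test(preds, preds, labels), 1)
  # A correct on 30 samples where B is wrong, B never better
  a <- labels
  b <- labels
  b[1:30] <- 1 - b[1:30]
  expect_lt(paired_accuracy_test(a, b, labels), 0.01)
  expect_equal(paired_accuracy_test(a, b, labels),
               paired_accuracy_test(b, a, labels))
  expect_error(paired_accuracy_test(a[1:10], b, labels), "length")
})
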