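#' Configuration for the fully connected baseline
#'
#' @param hidden hidden-layer width.
#' @param dropout dropout probability during training.
#' @param learning_rate Adam learning rate.
#' @param epochs passes over the training data.
#' @param batch_size minibatch size.
#' @param weight_mode `"none"` (plain cross-entropy), `"sensitive_frequency"`
#'   (each sample's loss multiplied by the unit-norm reciprocal-frequency
#'   weight of its sensitive group — the cost-adjusted comparator), or
#'   `"outcome_frequency"` (weights from outcome-class counts). Weights are
#'   always derived from training counts only.
#' @param lambda_norm normalization for the weights (see [compute_lambda()]).
#' @param seed integer seed.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(hidden = 64L, dropout = 0.2, learning_rate = 1e-3,
                            epochs = 30L, batch_size = 64L,
                            weight_mode = c("none", "sensitive_frequency",
                                            "outcome_frequency"),
                            lambda_norm = c("l2", "squared"),
                            seed = 0L) {
  weight_mode <- match.arg(weight_mode)
  lambda_norm <- match.arg(lambda_norm)
  structure(
    list(hidden = as.integer(hidden), dropout = dropout,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), weight_mode = weight_mode,
         lambda_norm = lambda_norm, seed = as.integer(seed)),
    class = "baseline_config"
  )
}

#' Train a fully connected network baseline
#'
#' One hidden ReLU layer with dropout, softmax output, weighted cross-entropy
#' loss and Adam — the supervised counterpart of the RL classifier. In
#' `sensitive_frequency` mode the per-sample weight reuses the same
#' unit-norm reciprocal-count construction as the RL reward, so the
#' cost-adjusted baseline and the debiasing reward live on one scale.
#'
#' @param train a preprocessed [sample_set()] (no missing values).
#' @param validation optional preprocessed [sample_set()]; per-epoch AUROC is
#'   logged when present.
#' @param config a [baseline_config()].
#' @return an object of class `baseline_model`.
#' @export
train_baseline_nn <- function(train, validation = NULL,
                              config = baseline_config()) {
  stopifnot(inherits(train, "sample_set"), inherits(config, "baseline_config"))
  if (anyNA(train$features)) stop("training features must be preprocessed (no NA)")
  k <- length(train$outcome_levels)
  if (length(unique(train$outcome)) < 2L) {
    stop("training labels contain a single class")
  }
  x <- train$features
  y1 <- train$outcome + 1L
  n <- nrow(x)
  d <- ncol(x)
  w <- switch(config$weight_mode,
    none = rep(1, n),
    sensitive_frequency =
      compute_lambda(sensitive_counts(train), config$lambda_norm)[train$sensitive + 1L],
    outcome_frequency =
      compute_lambda(outcome_counts(train), config$lambda_norm)[y1]
  )
  has_val <- !is.null(validation) && n_samples(validation) > 0
  val_auroc <- numeric(0)

  with_seed(config$seed, {
    net <- list(W1 = init_dense(d, config$hidden),
                b1 = numeric(config$hidden),
                W2 = matrix(0, config$hidden, k),
                b2 = numeric(k))
    opt <- adam_state(net)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        pre <- sweep(xb %*% net$W1, 2L, net$b1, "+")
        h <- pmax(pre, 0)
        mask <- NULL
        if (config$dropout > 0) {
          mask <- matrix((stats::runif(length(h)) >= config$dropout) /
                           (1 - config$dropout), nrow(h), ncol(h))
          h <- h * mask
        }
        logits <- sweep(h %*% net$W2, 2L, net$b2, "+")
        p <- softmax_rows(logits)
        wi <- w[idx]
        glogit <- p * wi
        glogit[cbind(seq_along(idx), y1[idx])] <-
          glogit[cbind(seq_along(idx), y1[idx])] - wi
        glogit <- glogit / length(idx)
        gh <- glogit %*% t(net$W2)
        if (!is.null(mask)) gh <- gh * mask
        gh <- gh * (pre > 0)
        grads <- list(W1 = crossprod(xb, gh), b1 = colSums(gh),
                      W2 = crossprod(h, glogit), b2 = colSums(glogit))
        upd <- adam_step(net, grads, opt, config$learning_rate)
        net <- upd$params
        opt <- upd$state
      }
      if (has_val) {
        sc <- baseline_scores(net, validation$features)
        au <- tryCatch(auroc(sc, as.integer(validation$outcome == 1L)),
                       error = function(e) NA_real_)
        val_auroc <- c(val_auroc, au)
      }
    }
    structure(
      list(net = net, config = config,
           outcome_levels = train$outcome_levels,
           sensitive_levels = train$sensitive_levels,
           feature_names = train$feature_names,
           validation_log = if (has_val) {
             data.frame(epoch = seq_len(config$epochs), auroc = val_auroc)
           } else NULL),
      class = "baseline_model"
    )
  })
}

baseline_scores <- function(net, x, positive_class = 1L) {
  h <- pmax(sweep(x %*% net$W1, 2L, net$b1, "+"), 0)
  logits <- sweep(h %*% net$W2, 2L, net$b2, "+")
  softmax_rows(logits)[, positive_class + 1L]
}

#' Predict from a baseline network
#'
#' @param object a `baseline_model`.
#' @param newdata a preprocessed [sample_set()] or feature matrix.
#' @param type `"score"` (positive-class probability) or `"class"`.
#' @param positive_class 0-based positive class.
#' @param ... ignored.
#' @return numeric or integer vector.
#' @export
predict.baseline_model <- function(object, newdata,
                                   type = c("score", "class"),
                                   positive_class = 1L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "sample_set")) newdata$features else as.matrix(newdata)
  sc <- baseline_scores(object$net, x, positive_class)
  if (type == "score") sc else as.integer(sc >= 0.5)
}

#' Compare trained models on a common test set
#'
#' For every model: calibrate its decision threshold on the validation set to
#' the target sensitivity, then compute classification metrics (with AUROC
#' and Hanley-McNeil CI) and the equalized-odds fairness report on the test
#' set at that threshold. Also runs the paired Wilcoxon signed-rank
#' comparison of per-sample accuracy for every model pair.
#'
#' @param models named list of trained models (any object with a
#'   `predict(model, data, type = "score")` method).
#' @param test,validation preprocessed [sample_set()]s.
#' @param target_sensitivity sensitivity the thresholds are calibrated to.
#' @param positive_class 0-based positive class (default 1).
#' @return a list with `table` (one row per model: threshold, sensitivity,
#'   specificity, PPV, NPV, F1, AUROC and its CI, sd_TP, sd_FP), `fairness`
#'   (per-model [equalized_odds_sd()] reports) and `pairwise_p` (matrix of
#'   two-sided Wilcoxon p-values).
#' @export
compare_models <- function(models, test, validation, target_sensitivity = 0.9,
                           positive_class = 1L) {
  if (length(models) < 2L) stop("need at least 2 models to compare")
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  y_test <- as.integer(test$outcome == positive_class)
  y_val <- as.integer(validation$outcome == positive_class)
  rows <- list()
  fairness <- list()
  preds <- list()
  for (nm in names(models)) {
    sv <- predict(models[[nm]], validation, type = "score",
                  positive_class = positive_class)
    st <- predict(models[[nm]], test, type = "score",
                  positive_class = positive_class)
    thr <- adjust_threshold(sv, y_val, target_sensitivity)
    cm <- classification_metrics(confusion_at(st, y_test, thr))
    au <- auroc(st, y_test)
    ci <- hanley_mcneil_ci(au, sum(y_test == 1L), sum(y_test == 0L))
    fr <- equalized_odds_sd(st, y_test, test$sensitive, thr,
                            group_levels = test$sensitive_levels)
    preds[[nm]] <- as.integer(st >= thr)
    fairness[[nm]] <- fr
    rows[[nm]] <- data.frame(
      model = nm, threshold = thr,
      sensitivity = cm$sensitivity[["value"]],
      specificity = cm$specificity[["value"]],
      ppv = cm$ppv[["value"]], npv = cm$npv[["value"]], f1 = cm$f1,
      auroc = au, auroc_low = ci$low, auroc_high = ci$high,
      sd_tp = fr$sd_tp, sd_fp = fr$sd_fp,
      stringsAsFactors = FALSE
    )
  }
  nms <- names(models)
  pw <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (a in seq_along(nms)) {
    for (b in seq_along(nms)) {
      pw[a, b] <- if (a == b) 1 else {
        paired_accuracy_test(preds[[nms[a]]], preds[[nms[b]]], y_test)
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fairness = fairness, pairwise_p = pw)
}
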