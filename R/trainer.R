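#' Bounded replay memory
#'
#' First-in-first-out store of transitions backed by preallocated matrices.
#' Once full, the oldest transitions are overwritten. Batches are sampled
#' uniformly without replacement from the current contents.
#'
#' @param capacity maximum number of stored transitions.
#' @param n_inputs feature dimension of the states.
#' @return an object of class `replay_memory` (an environment).
#' @export
replay_memory <- function(capacity, n_inputs) {
  mem <- new.env(parent = emptyenv())
  mem$capacity <- as.integer(capacity)
  mem$S <- matrix(0, capacity, n_inputs)
  mem$S2 <- matrix(0, capacity, n_inputs)
  mem$A <- integer(capacity)
  mem$R <- numeric(capacity)
  mem$Tm <- logical(capacity)
  mem$size <- 0L
  mem$pos <- 0L
  class(mem) <- "replay_memory"
  mem
}

#' @rdname replay_memory
#' @param mem a `replay_memory`.
#' @param state,next_state length-D numeric state vectors; `next_state` may
#'   be `NULL` for terminal transitions (it is never used in the target).
#' @param action taken action (0-based).
#' @param reward scalar reward.
#' @param terminal whether the transition ended its episode.
#' @export
memory_push <- function(mem, state, action, reward, next_state, terminal) {
  i <- mem$pos %% mem$capacity + 1L
  mem$S[i, ] <- state
  mem$A[i] <- as.integer(action)
  mem$R[i] <- reward
  mem$S2[i, ] <- if (is.null(next_state)) 0 else next_state
  mem$Tm[i] <- isTRUE(terminal)
  mem$pos <- mem$pos + 1L
  mem$size <- min(mem$size + 1L, mem$capacity)
  invisible(mem)
}

#' @rdname replay_memory
#' @param batch_size number of transitions to draw.
#' @return `memory_sample` returns a list of batch matrices
#'   (`states`, `actions`, `rewards`, `next_states`, `terminal`).
#' @export
memory_sample <- function(mem, batch_size) {
  if (batch_size > mem$size) stop("batch_size exceeds memory size")
  idx <- sample.int(mem$size, batch_size)
  list(states = mem$S[idx, , drop = FALSE],
       actions = mem$A[idx],
       rewards = mem$R[idx],
       next_states = mem$S2[idx, , drop = FALSE],
       terminal = mem$Tm[idx])
}

# Coerce a list-of-transitions (as tests and users build them) into the
# batch-matrix layout the vectorized routines use.
as_transition_batch <- function(batch) {
  if (is.list(batch) && !is.null(batch$states)) return(batch)
  d <- length(batch[[1]]$state)
  list(
    states = do.call(rbind, lapply(batch, function(t) t$state)),
    actions = vapply(batch, function(t) as.integer(t$action), 1L),
    rewards = vapply(batch, function(t) as.numeric(t$reward), 1),
    next_states = do.call(rbind, lapply(batch, function(t) {
      if (is.null(t$next_state)) numeric(d) else t$next_state
    })),
    terminal = vapply(batch, function(t) isTRUE(t$terminal), TRUE)
  )
}

#' Double-DQN regression targets
#'
#' For each transition: the online network picks the greedy action in the
#' next state, the target network evaluates it, and
#' `y = r + (1 - term) * gamma * Q_target(s', a*)`. Terminal transitions
#' bootstrap nothing: `y = r` exactly.
#'
#' @param batch either a list of transitions (each with `state`, `action`,
#'   `reward`, `next_state`, `terminal`) or a batch from [memory_sample()].
#' @param online,target online and target [dueling_net()] parameter sets.
#' @param gamma discount factor.
#' @return numeric vector of targets, one per transition.
#' @export
ddqn_target <- function(batch, online, target, gamma) {
  b <- as_transition_batch(batch)
  y <- b$rewards
  live <- which(!b$terminal)
  if (length(live)) {
    ns <- b$next_states[live, , drop = FALSE]
    q_on <- dueling_forward(online, ns)$q
    a_star <- max.col(q_on, ties.method = "first")
    q_tg <- dueling_forward(target, ns)$q
    y[live] <- y[live] + gamma * q_tg[cbind(seq_along(live), a_star)]
  }
  y
}

#' Temporal-difference loss
#'
#' Sum over the batch of squared errors between the targets and the online
#' network's Q-value for the taken action (sum reduction by default; set
#' `reduce = "mean"` to average instead). Evaluated in scoring mode.
#'
#' @param batch transitions (see [ddqn_target()]).
#' @param online the online [dueling_net()].
#' @param targets numeric target vector from [ddqn_target()].
#' @param reduce `"sum"` (default) or `"mean"`.
#' @return scalar loss.
#' @export
td_loss <- function(batch, online, targets, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  b <- as_transition_batch(batch)
  if (length(targets) != length(b$actions)) {
    stop("targets length must equal batch size")
  }
  q <- dueling_forward(online, b$states)$q
  qa <- q[cbind(seq_along(b$actions), b$actions + 1L)]
  err <- sum((targets - qa)^2)
  if (reduce == "mean") err / length(targets) else err
}

#' Training configuration for the RL classifier
#'
#' @param total_steps number of environment steps (and, once the memory is
#'   warm, gradient updates). The full-scale schedule is 120,000 steps;
#'   reduced budgets are used for small synthetic problems.
#' @param batch_size replay batch size.
#' @param memory_capacity replay memory capacity.
#' @param target_sync_period steps between copying online to target weights.
#' @param gamma discount factor (default 0.1).
#' @param learning_rate Adam learning rate.
#' @param hidden hidden-layer width.
#' @param dropout dropout rate for training forward passes.
#' @param epsilon_start,epsilon_end exploration schedule endpoints; annealed
#'   linearly over `total_steps`.
#' @param reward_mode `"debias"` or `"outcome_only"` (see [reward_scheme()]).
#' @param lambda_norm normalization for the reward weights
#'   (see [compute_lambda()]).
#' @param episode_cap optional maximum samples per episode; `NULL` means an
#'   episode spans a full shuffled pass over the training data.
#' @param seed integer seed for all training randomness.
#' @return an object of class `training_config`.
#' @export
training_config <- function(total_steps = 120000L, batch_size = 64L,
                            memory_capacity = 10000L,
                            target_sync_period = 1000L,
                            gamma = 0.1, learning_rate = 1e-3,
                            hidden = 128L, dropout = 0.2,
                            epsilon_start = 1.0, epsilon_end = 0.01,
                            reward_mode = c("debias", "outcome_only"),
                            lambda_norm = c("l2", "squared"),
                            episode_cap = NULL, seed = 0L) {
  reward_mode <- match.arg(reward_mode)
  lambda_norm <- match.arg(lambda_norm)
  if (batch_size > memory_capacity) stop("batch_size must be <= memory_capacity")
  if (total_steps < 1 || batch_size < 1 || target_sync_period < 1) {
    stop("counts must be positive")
  }
  structure(
    list(total_steps = as.integer(total_steps),
         batch_size = as.integer(batch_size),
         memory_capacity = as.integer(memory_capacity),
         target_sync_period = as.integer(target_sync_period),
         gamma = gamma, learning_rate = learning_rate,
         hidden = as.integer(hidden), dropout = dropout,
         epsilon_start = epsilon_start, epsilon_end = epsilon_end,
         reward_mode = reward_mode, lambda_norm = lambda_norm,
         episode_cap = if (is.null(episode_cap)) NULL else as.integer(episode_cap),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Train the fairness-aware DQN classifier
#'
#' Runs the double-DQN training loop: per episode the training rows are
#' shuffled and presented in order as states; the agent picks actions
#' epsilon-greedily (epsilon annealed linearly over the whole run), receives
#' the debiasing reward, and the episode ends on a minority-class
#' misclassification or at the end of the pass. Each transition is pushed to
#' the replay memory; once the memory holds a full batch, every environment
#' step is followed by one Adam step on the temporal-difference loss against
#' double-DQN targets, and the target network is refreshed every
#' `target_sync_period` steps.
#'
#' @param train a preprocessed [sample_set()] (no missing values).
#' @param validation optional preprocessed [sample_set()] for periodic AUROC
#'   logging; with `NULL` or an empty set, validation metrics are omitted
#'   with a warning.
#' @param config a [training_config()].
#' @return an object of class `fairdqn_model`: the trained network, the
#'   reward scheme, the label vocabularies and a training log
#'   (`data.frame` of step, epsilon, loss, episode) plus per-interval
#'   validation AUROC where available.
#' @export
train_dqn <- function(train, validation = NULL, config = training_config()) {
  stopifnot(inherits(train, "sample_set"), inherits(config, "training_config"))
  if (anyNA(train$features)) stop("training features must be preprocessed (no NA)")
  k <- length(train$outcome_levels)
  if (k < 2L) stop("need at least 2 outcome classes")
  has_val <- !is.null(validation) && n_samples(validation) > 0
  if (!has_val) warning("no validation set; validation metrics omitted")

  scheme <- reward_scheme(outcome_counts(train), sensitive_counts(train),
                          gamma = config$gamma, mode = config$reward_mode,
                          norm = config$lambda_norm)
  minority <- minority_outcome(train)
  pol <- policy_config(config$epsilon_start, config$epsilon_end,
                       config$total_steps)

  x <- train$features
  y <- train$outcome
  z <- train$sensitive
  n <- nrow(x)
  d <- ncol(x)
  lam_out <- scheme$lambda_outcome
  lam_sens <- scheme$lambda_sensitive
  debias <- scheme$mode == "debias"
  cap <- if (is.null(config$episode_cap)) n else min(config$episode_cap, n)

  log_every <- max(1L, config$total_steps %/% 200L)
  log_steps <- integer(0); log_eps <- numeric(0)
  log_loss <- numeric(0); log_episode <- integer(0)
  val_steps <- integer(0); val_auroc <- numeric(0)
  val_every <- max(1L, config$total_steps %/% 10L)

  with_seed(config$seed, {
    online <- dueling_net(d, k, config$hidden, config$dropout)
    target <- online
    opt <- adam_state(online[c("W1", "b1", "Wv", "bv", "Wa", "ba")])
    mem <- replay_memory(config$memory_capacity, d)

    step <- 0L
    episode <- 0L
    while (step < config$total_steps) {
      episode <- episode + 1L
      ord <- sample.int(n)
      i <- 1L
      repeat {
        row <- ord[i]
        state <- x[row, ]
        eps <- epsilon_at(step, pol)
        if (stats::runif(1) < eps) {
          act <- sample.int(k, 1L) - 1L
        } else {
          act <- which.max(dueling_forward(online, matrix(state, 1L))$q) - 1L
        }
        correct <- act == y[row]
        r <- if (correct) {
          if (debias) lam_sens[z[row] + 1L] else lam_out[y[row] + 1L]
        } else {
          -lam_out[y[row] + 1L]
        }
        term <- (!correct && y[row] == minority) || i == cap
        memory_push(mem, state, act, r,
                    if (term) NULL else x[ord[i + 1L], ], term)

        loss <- NA_real_
        if (mem$size >= config$batch_size) {
          batch <- memory_sample(mem, config$batch_size)
          tv <- ddqn_target(batch, online, target, config$gamma)
          fw <- dueling_forward(online, batch$states, train = TRUE)
          a1 <- batch$actions + 1L
          grads <- dueling_backward(online, fw, a1, tv)
          upd <- adam_step(online[c("W1", "b1", "Wv", "bv", "Wa", "ba")],
                           grads, opt, config$learning_rate)
          online[names(upd$params)] <- upd$params
          opt <- upd$state
          qa <- fw$q[cbind(seq_along(a1), a1)]
          loss <- sum((tv - qa)^2)
        }
        step <- step + 1L
        if (step %% log_every == 0L || step == config$total_steps) {
          log_steps <- c(log_steps, step)
          log_eps <- c(log_eps, eps)
          log_loss <- c(log_loss, loss)
          log_episode <- c(log_episode, episode)
        }
        if (step %% config$target_sync_period == 0L) {
          target[c("W1", "b1", "Wv", "bv", "Wa", "ba")] <-
            online[c("W1", "b1", "Wv", "bv", "Wa", "ba")]
        }
        if (has_val && step %% val_every == 0L) {
          sc <- positive_score(dueling_forward(online, validation$features)$q,
                               positive_class = 1L)
          au <- tryCatch(auroc(sc, as.integer(validation$outcome == 1L)),
                         error = function(e) NA_real_)
          val_steps <- c(val_steps, step)
          val_auroc <- c(val_auroc, au)
        }
        if (term || step >= config$total_steps) break
        i <- i + 1L
      }
    }

    structure(
      list(net = online,
           scheme = scheme,
           minority_label = minority,
           config = config,
           outcome_levels = train$outcome_levels,
           sensitive_levels = train$sensitive_levels,
           feature_names = train$feature_names,
           log = data.frame(step = log_steps, epsilon = log_eps,
                            loss = log_loss, episode = log_episode),
           validation_log = if (has_val) {
             data.frame(step = val_steps, auroc = val_auroc)
           } else NULL),
      class = "fairdqn_model"
    )
  })
}

#' Predict from a trained RL classifier
#'
#' @param object a `fairdqn_model` from [train_dqn()].
#' @param newdata a preprocessed [sample_set()] or a feature matrix.
#' @param type `"score"` for the softmax positive-class score, `"class"` for
#'   the greedy (argmax-Q) class, or `"q"` for the raw Q-value matrix.
#' @param positive_class 0-based positive class for `type = "score"`.
#' @param ... ignored.
#' @return numeric vector, integer vector or matrix, one row/entry per sample.
#' @export
predict.fairdqn_model <- function(object, newdata, type = c("score", "class", "q"),
                                  positive_class = 1L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "sample_set")) newdata$features else as.matrix(newdata)
  q <- dueling_forward(object$net, x)$q
  switch(type,
    score = positive_score(q, positive_class),
    class = max.col(q, ties.method = "first") - 1L,
    q = q
  )
}

#' @export
print.fairdqn_model <- function(x, ...) {
  cat(sprintf(
    "<fairdqn_model> %s reward, %d features -> %d classes, hidden %d, %d steps\n",
    x$scheme$mode, x$net$n_inputs, x$net$n_actions, x$net$hidden,
    x$config$total_steps
  ))
  invisible(x)
}

#' Grid search with stratified cross-validation
#'
#' Evaluates every point of a hyperparameter grid by k-fold cross-validation
#' on the training set (folds stratified by outcome), scoring each fold by
#' validation AUROC of the trained RL classifier, and returns the point with
#' the best mean score. Grid points whose training diverges (non-finite
#' loss/scores) or whose folds degenerate to a single class score `NA` for
#' those folds.
#'
#' @param train a preprocessed [sample_set()].
#' @param grid named list of hyperparameter vectors; names must match
#'   [training_config()] arguments (e.g. `learning_rate`, `hidden`,
#'   `dropout`).
#' @param folds number of cross-validation folds (>= 2; default 5).
#' @param config base [training_config()]; grid values override its fields.
#'   Use a reduced `total_steps` here — the grid multiplies cost.
#' @return a list with `best` (named list of winning values), `scores`
#'   (data.frame of grid points, per-fold AUROCs and mean), and `config`
#'   (the base config with the winning values applied).
#' @export
grid_search_cv <- function(train, grid, folds = 5L, config = training_config()) {
  if (!length(grid)) stop("grid must be non-empty")
  if (folds < 2L) stop("need at least 2 folds")
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  fold_id <- with_seed(config$seed, {
    id <- integer(n_samples(train))
    for (cls in unique(train$outcome)) {
      rows <- which(train$outcome == cls)
      id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    id
  })
  score_mat <- matrix(NA_real_, nrow(pts), folds)
  for (p in seq_len(nrow(pts))) {
    cfg <- config
    for (nm in names(pts)) cfg[[nm]] <- pts[[nm]][p]
    for (f in seq_len(folds)) {
      tr <- train[fold_id != f]
      va <- train[fold_id == f]
      if (length(unique(tr$outcome)) < 2L || length(unique(va$outcome)) < 2L) {
        warning(sprintf("fold %d degenerate (single class); skipped", f))
        next
      }
      fit <- suppressWarnings(train_dqn(tr, validation = NULL, config = cfg))
      sc <- predict(fit, va, type = "score")
      if (all(is.finite(sc))) {
        score_mat[p, f] <- auroc(sc, as.integer(va$outcome == 1L))
      }
    }
  }
  mean_score <- rowMeans(score_mat, na.rm = TRUE)
  mean_score[is.nan(mean_score)] <- NA_real_
  best_idx <- which.max(mean_score)
  best <- as.list(pts[best_idx, , drop = FALSE])
  names(best) <- names(pts)
  cfg <- config
  for (nm in names(best)) cfg[[nm]] <- best[[nm]]
  scores <- cbind(pts, score_mat, mean_auroc = mean_score)
  names(scores)[seq(ncol(pts) + 1L, ncol(pts) + folds)] <-
    paste0("fold", seq_len(folds))
  list(best = best, scores = scores, config = cfg)
}
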