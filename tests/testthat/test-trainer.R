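test_that("replay memory is bounded FIFO with uniform batch sampling", {
  mem <- replay_memory(5, 2)
  for (t in 1:8) {
    memory_push(mem, c(t, t), t %% 2L, t / 10, c(t + 1, t + 1), FALSE)
    expect_equal(mem$size, min(t, 5L))
  }
  # after 8 pushes into capacity 5, transitions 4..8 remain (oldest evicted)
  expect_setequal(mem$R * 10, 4:8)
  set.seed(1)
  b <- memory_sample(mem, 3)
  expect_equal(nrow(b$states), 3L)
  expect_equal(anyDuplicated(b$states[, 1]), 0L)  # without replacement
  expect_error(memory_sample(mem, 9), "batch_size")
})

test_that("ddqn targets decouple selection from evaluation", {
  # terminal transitions bootstrap nothing
  net <- dueling_net(2, 2, hidden = 4)
  term_batch <- list(list(state = c(0, 0), action = 1L, reward = 0.5,
                          next_state = NULL, terminal = TRUE))
  expect_equal(ddqn_target(term_batch, net, net, gamma = 0.1), 0.5)

  # hand-worked case: online argmax picks action 2, target evaluates it
  online <- const_q_net(c(0.2, 0.7))
  target <- const_q_net(c(0.4, 0.5))
  batch <- list(list(state = c(0, 0), action = 0L, reward = 1,
                     next_state = c(3, 3), terminal = FALSE))
  expect_equal(ddqn_target(batch, online, target, gamma = 0.1), 1.05,
               tolerance = 1e-9)
  # discount-free limit: y = r for every transition
  expect_equal(ddqn_target(batch, online, target, gamma = 0), 1)
})

test_that("td loss is the summed squared error on taken actions", {
  net <- const_q_net(c(0.5, 0.5))
  batch <- list(
    list(state = c(0, 0), action = 0L, reward = 0, next_state = NULL,
         terminal = TRUE),
    list(state = c(0, 0), action = 1L, reward = 0, next_state = NULL,
         terminal = TRUE)
  )
  expect_equal(td_loss(batch, net, targets = c(1, 0)), 0.5, tolerance = 1e-9)
  expect_equal(td_loss(batch, net, targets = c(0.5, 0.5)), 0)
  expect_equal(td_loss(batch, net, targets = c(1, 0), reduce = "mean"), 0.25,
               tolerance = 1e-9)
  expect_error(td_loss(batch, net, targets = 1), "length")
})

test_that("training is reproducible and makes progress on an easy problem", {
  toy <- tiny_toy(n_per_class = 150, margin = 5, seed = 2)
  cfg <- training_config(total_steps = 2500L, hidden = 16L,
                         memory_capacity = 2000L, seed = 0L)
  fit1 <- suppressWarnings(train_dqn(toy, NULL, cfg))
  fit2 <- suppressWarnings(train_dqn(toy, NULL, cfg))
  holdout <- tiny_toy(n_per_class = 100, margin = 5, seed = 77)
  expect_identical(predict(fit1, holdout, type = "score"),
                   predict(fit2, holdout, type = "score"))
  expect_gte(mean(predict(fit1, holdout, type = "class") == holdout$outcome),
             0.9)
  # loss over the last tenth of training sits below its early average
  losses <- fit1$log$loss[!is.na(fit1$log$loss)]
  n <- length(losses)
  expect_lt(mean(losses[(n - n %/% 10):n]), mean(losses[1:(n %/% 10)]))
  # epsilon in the log follows the annealing schedule
  expect_equal(fit1$log$epsilon,
               epsilon_at(fit1$log$step - 1L,
                          policy_config(total_steps = 2500L)))
})

test_that("the training log tracks episodes and validation when supplied", {
  toy <- tiny_toy(n_per_class = 80, margin = 5, seed = 3)
  val <- tiny_toy(n_per_class = 40, margin = 5, seed = 4)
  fit <- train_dqn(toy, val, training_config(total_steps = 800L, hidden = 8L,
                                             batch_size = 32L, seed = 1L))
  expect_true(all(diff(fit$log$episode) >= 0))
  expect_s3_class(fit$validation_log, "data.frame")
  expect_true(all(fit$validation_log$auroc > 0.5))
  expect_warning(train_dqn(toy, NULL,
                           training_config(total_steps = 50L, hidden = 4L,
                                           batch_size = 16L)),
                 "validation")
})

test_that("grid search returns the best point deterministically", {
  toy <- tiny_toy(n_per_class = 60, margin = 5, seed = 5)
  base <- training_config(total_steps = 300L, hidden = 8L, batch_size = 32L,
                          memory_capacity = 500L, seed = 3L)
  single <- grid_search_cv(toy, list(learning_rate = 0.003), folds = 3L,
                           config = base)
  expect_equal(single$best$learning_rate, 0.003)
  expect_equal(nrow(single$scores), 1L)
  expect_equal(sum(!is.na(single$scores[, c("fold1", "fold2", "fold3")])), 3L)

  # a wildly unstable learning rate loses to a sane one
  two <- grid_search_cv(toy, list(learning_rate = c(0.003, 500)), folds = 3L,
                        config = base)
  expect_equal(two$best$learning_rate, 0.003)
  two_again <- grid_search_cv(toy, list(learning_rate = c(0.003, 500)),
                              folds = 3L, config = base)
  expect_identical(two$scores, two_again$scores)
  expect_equal(two$config$learning_rate, 0.003)
})
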