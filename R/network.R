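# Internal neural-network primitives: a one-hidden-layer ReLU trunk with
# either a dueling head (scalar value stream + advantage stream) or a softmax
# head, trained by Adam on hand-derived gradients. The networks here are
# small (tens of inputs, <= a few hundred hidden units), so plain R matrix
# algebra is both fast enough and fully deterministic given the RNG.

# Row-wise softmax with max-subtraction for overflow safety.
softmax_rows <- function(a) {
  a <- a - apply(a, 1L, max)
  e <- exp(a)
  e / rowSums(e)
}

# He-style initialization for a dense layer (fan_in inputs).
init_dense <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

#' Initialize dueling Q-network parameters
#'
#' One fully connected hidden layer (ReLU, dropout during training) feeding
#' two streams: a value stream producing the scalar V(s) and an advantage
#' stream producing the length-K vector A(s, .). The head weights start at
#' zero so an untrained network scores all actions equally.
#'
#' @param n_inputs feature dimension D.
#' @param n_actions number of classes K (>= 2).
#' @param hidden hidden-layer width.
#' @param dropout dropout probability applied to the hidden layer during
#'   training forward passes only; scoring is always deterministic.
#' @return an object of class `dueling_net`.
#' @export
dueling_net <- function(n_inputs, n_actions, hidden = 128L, dropout = 0.2) {
  if (n_actions < 2L) stop("a Q-network needs at least 2 actions")
  structure(
    list(W1 = init_dense(n_inputs, hidden), b1 = numeric(hidden),
         Wv = matrix(0, hidden, 1L), bv = 0,
         Wa = matrix(0, hidden, n_actions), ba = numeric(n_actions),
         n_inputs = as.integer(n_inputs), n_actions = as.integer(n_actions),
         hidden = as.integer(hidden), dropout = dropout),
    class = "dueling_net"
  )
}

#' Combine value and advantages into Q-values
#'
#' `Q_a = V + A_a - softmax(A)_a`. Subtracting the softmax of the advantage
#' vector lets V and A be recovered uniquely from Q, and — being a
#' rank-preserving correction — never changes which action is greedy.
#'
#' @param value scalar state value V.
#' @param advantages length-K advantage vector A.
#' @return length-K vector of Q-values.
#' @export
dueling_combine <- function(value, advantages) {
  if (!all(is.finite(value)) || !all(is.finite(advantages))) {
    stop("dueling_combine requires finite inputs")
  }
  if (length(advantages) < 2L) stop("need at least 2 actions")
  a <- matrix(advantages, 1L)
  drop(value + a - softmax_rows(a))
}

# Forward pass through the trunk + dueling heads for a batch of states.
# When `train` is TRUE an inverted-dropout mask is drawn from the current
# RNG; scoring passes (train = FALSE) are deterministic.
dueling_forward <- function(net, x, train = FALSE) {
  pre <- x %*% net$W1
  pre <- sweep(pre, 2L, net$b1, "+")
  h <- pmax(pre, 0)
  mask <- NULL
  if (train && net$dropout > 0) {
    mask <- matrix(
      (stats::runif(length(h)) >= net$dropout) / (1 - net$dropout),
      nrow(h), ncol(h)
    )
    h <- h * mask
  }
  v <- drop(h %*% net$Wv) + net$bv
  a <- sweep(h %*% net$Wa, 2L, net$ba, "+")
  s <- softmax_rows(a)
  list(x = x, pre = pre, h = h, mask = mask, v = v, a = a, s = s,
       q = v + a - s)
}

#' Q-values for one or more states
#'
#' Deterministic scoring-mode forward pass (dropout disabled).
#'
#' @param net a [dueling_net()].
#' @param state a length-D feature vector or an N x D matrix of states.
#' @return a length-K vector, or an N x K matrix for matrix input.
#' @export
q_values <- function(net, state) {
  stopifnot(inherits(net, "dueling_net"))
  single <- is.null(dim(state))
  x <- if (single) matrix(state, 1L) else as.matrix(state)
  if (ncol(x) != net$n_inputs) {
    stop(sprintf("state has %d features but the network expects %d",
                 ncol(x), net$n_inputs))
  }
  q <- dueling_forward(net, x)$q
  if (single) drop(q) else q
}

#' Exploration schedule configuration
#'
#' @param epsilon_start exploration probability at step 0.
#' @param epsilon_end exploration probability at `total_steps` and beyond.
#' @param total_steps length of the linear annealing schedule.
#' @return an object of class `policy_config`.
#' @export
policy_config <- function(epsilon_start = 1.0, epsilon_end = 0.01,
                          total_steps = 120000L) {
  if (epsilon_start < epsilon_end || epsilon_end < 0) {
    stop("need epsilon_start >= epsilon_end >= 0")
  }
  structure(list(epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 total_steps = as.integer(total_steps)),
            class = "policy_config")
}

#' Exploration probability at a training step
#'
#' Linear attenuation from `epsilon_start` at step 0 to `epsilon_end` at
#' `total_steps`, clamped thereafter.
#'
#' @param step non-negative step count.
#' @param config a [policy_config()].
#' @return the exploration probability.
#' @export
epsilon_at <- function(step, config) {
  stopifnot(inherits(config, "policy_config"))
  frac <- pmin(pmax(step / config$total_steps, 0), 1)
  config$epsilon_start + frac * (config$epsilon_end - config$epsilon_start)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random class; otherwise the argmax
#' of the Q-values, breaking ties toward the lowest index. Consumes the
#' current RNG stream, so it is deterministic given the RNG state.
#'
#' @param q length-K Q-value vector.
#' @param epsilon exploration probability in [0,1].
#' @return the selected class (0-based).
#' @export
select_action <- function(q, epsilon) {
  if (!length(q)) stop("empty Q-value vector")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0,1]")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(length(q), 1L) - 1L
  } else {
    which.max(q) - 1L
  }
}

#' Positive-class score from Q-values
#'
#' Maps Q-values to (0,1) via a softmax and returns the positive class's
#' share. Strictly increasing in `q[positive]` with the others held fixed,
#' and for two classes a strictly monotone transform of the Q-margin — so
#' rank metrics such as AUROC agree between the score and the raw margin.
#' Bridges Q-values to decision-threshold calibration.
#'
#' @param q length-K Q-value vector or an N x K matrix.
#' @param positive_class 0-based index of the positive class (default 1).
#' @return scalar score in (0,1), or a vector for matrix input.
#' @export
positive_score <- function(q, positive_class = 1L) {
  single <- is.null(dim(q))
  m <- if (single) matrix(q, 1L) else as.matrix(q)
  if (positive_class < 0 || positive_class >= ncol(m)) {
    stop("positive_class out of range")
  }
  s <- softmax_rows(m)[, positive_class + 1L]
  if (single) unname(s) else s
}

# ---- Adam optimizer (internal) ----------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam update; `params` and `grads` are parallel named lists of arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Gradient of sum((y - Q[i, a_i])^2) wrt the dueling-net parameters, given a
# cached training-mode forward pass `fw` on the batch states.
# dQ_a/dA_b = 1[a=b] - s_a (1[a=b] - s_b); dQ_a/dV = 1.
dueling_backward <- function(net, fw, actions1, y) {
  n <- nrow(fw$q)
  qa <- fw$q[cbind(seq_len(n), actions1)]
  gq <- -2 * (y - qa)                       # dL/dQ[i, a_i]
  sa <- fw$s[cbind(seq_len(n), actions1)]   # softmax at the taken action
  # gA[i, b] = gq_i * (1[b=a_i](1 - sa_i) + sa_i * s_ib)
  ga <- (gq * sa) * fw$s
  ga[cbind(seq_len(n), actions1)] <- ga[cbind(seq_len(n), actions1)] +
    gq * (1 - sa)
  gv <- gq                                   # dQ/dV = 1
  gh <- tcrossprod(gv, net$Wv[, 1L]) + ga %*% t(net$Wa)
  if (!is.null(fw$mask)) gh <- gh * fw$mask
  gh <- gh * (fw$pre > 0)
  list(W1 = crossprod(fw$x, gh), b1 = colSums(gh),
       Wv = crossprod(fw$h, gv), bv = sum(gv),
       Wa = crossprod(fw$h, ga), ba = colSums(ga))
}
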