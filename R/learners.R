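#' Learner state constructors
#'
#' The trial-by-trial predictive models all track some evolving estimate of
#' upcoming-node probability: a recency-weighted node-frequency vector `W`,
#' a one-step transition matrix `T`, or the successor-representation (SR)
#' matrix `M` learned by TD(lambda) with a dutch eligibility trace `e`.
#'
#' @param n_states number of nodes (default 15).
#' @param alpha learning rate in \[0, 1\].
#' @param gamma discount factor in \[0, 1).
#' @param lambda eligibility-trace decay in \[0, 1\].
#' @return a named list holding the state and its parameters.
#' @name learner_states
NULL

#' @rdname learner_states
#' @export
recency_state <- function(n_states = 15L, alpha) {
  list(W = rep(1 / n_states, n_states), alpha = alpha)
}

#' @rdname learner_states
#' @export
onestep_state <- function(n_states = 15L, alpha) {
  list(T = matrix(1 / n_states, n_states, n_states), alpha = alpha)
}

#' @rdname learner_states
#' @export
srtd_state <- function(n_states = 15L, alpha, gamma, lambda) {
  T_unif <- matrix(1 / n_states, n_states, n_states)
  list(M = sr_closed_form(T_unif, gamma), e = rep(0, n_states),
       alpha = alpha, gamma = gamma, lambda = lambda)
}

#' Recency (node-frequency) update
#'
#' `W <- (1 - alpha) * W + alpha * onehot(s)`; the elementwise decay plus
#' unit increment preserves the sum of `W` exactly.
#'
#' @param state a [recency_state()].
#' @param s observed node (1-based).
#' @return updated state.
#' @export
recency_update <- function(state, s) {
  n <- length(state$W)
  stopifnot(s >= 1, s <= n)
  state$W <- (1 - state$alpha) * state$W
  state$W[s] <- state$W[s] + state$alpha
  state
}

#' One-step transition-matrix update
#'
#' Only the row of the predecessor state changes: it is decayed by
#' `1 - alpha` and the entry of the observed successor incremented by
#' `alpha`, preserving the row sum.
#'
#' @param state a [onestep_state()].
#' @param s_prev,s predecessor and observed node (1-based).
#' @return updated state.
#' @export
onestep_update <- function(state, s_prev, s) {
  n <- nrow(state$T)
  stopifnot(s_prev >= 1, s_prev <= n, s >= 1, s <= n)
  state$T[s_prev, ] <- (1 - state$alpha) * state$T[s_prev, ]
  state$T[s_prev, s] <- state$T[s_prev, s] + state$alpha
  state
}

#' SR-TD(lambda) update with a dutch eligibility trace
#'
#' Executes, in order: (i) dutch trace increment
#' `e[s_prev] <- (1 - alpha) * e[s_prev] + 1`; (ii) TD error
#' `delta <- onehot(s) + gamma * M[s, ] - M[s_prev, ]`; (iii) sweep
#' `M[k, ] <- M[k, ] + alpha * e[k] * delta` for every state `k`;
#' (iv) trace decay `e <- gamma * lambda * e`. With `lambda = 0` only the
#' predecessor row is ever modified (TD(0) bootstrapping); with
#' `lambda = 1` the trace broadcasts each update over the recent past and
#' successive bootstrap terms cancel, approximating Monte-Carlo/Hebbian
#' learning.
#'
#' @param state an [srtd_state()].
#' @param s_prev,s predecessor and observed node (1-based).
#' @return updated state.
#' @export
srtd_update <- function(state, s_prev, s) {
  n <- nrow(state$M)
  stopifnot(s_prev >= 1, s_prev <= n, s >= 1, s <= n)
  state$e[s_prev] <- (1 - state$alpha) * state$e[s_prev] + 1
  delta <- state$gamma * state$M[s, ] - state$M[s_prev, ]
  delta[s] <- delta[s] + 1
  state$M <- state$M + state$alpha * outer(state$e, delta)
  state$e <- state$gamma * state$lambda * state$e
  state
}

#' Closed-form one-step-ahead successor representation
#'
#' Returns `T (I - gamma T)^(-1)`, the discounted future-occupancy matrix
#' `T + gamma T^2 + gamma^2 T^3 + ...` that starts counting at the next
#' step. For row-stochastic `T` every row of the result sums to
#' `1 / (1 - gamma)`.
#'
#' @param T row-stochastic transition matrix.
#' @param gamma discount factor in \[0, 1).
#' @return the SR matrix `M`.
#' @export
sr_closed_form <- function(T, gamma) {
  if (gamma < 0 || gamma >= 1) {
    stop("gamma must be in [0, 1): the discounted series diverges otherwise")
  }
  n <- nrow(T)
  T %*% solve(diag(n) - gamma * T)
}

#' Prediction horizon implied by a discount factor
#'
#' The SR aggregates expected occupancy over future steps with geometric
#' weights; its effective temporal horizon is the total discounted weight
#' `1 / (1 - gamma)` timesteps.
#'
#' @param gamma discount factor in \[0, 1).
#' @return horizon in timesteps.
#' @export
#' @examples
#' sr_horizon(0.717) # about 3.5 steps
sr_horizon <- function(gamma) {
  stopifnot(all(gamma >= 0), all(gamma < 1))
  1 / (1 - gamma)
}

#' Empirical transition matrix of a node sequence
#'
#' `T[i, j]` is the number of observed `i -> j` transitions divided by the
#' number of departures from `i`; rows of nodes never observed as a source
#' are set to uniform.
#'
#' @param nodes integer vector of 1-based node ids, length >= 2.
#' @param n_states number of nodes.
#' @return row-stochastic matrix.
#' @export
empirical_transition_matrix <- function(nodes, n_states = 15L) {
  stopifnot(length(nodes) >= 2)
  counts <- matrix(0, n_states, n_states)
  from <- nodes[-length(nodes)]
  to <- nodes[-1]
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  dep <- rowSums(counts)
  T <- counts / ifelse(dep == 0, 1, dep)
  T[dep == 0, ] <- 1 / n_states
  T
}

#' Predictor value of a learner state for an observed transition
#'
#' Recency: `W[s]`. One-step: `T[s_prev, s]`. SR (learned or static):
#' `M[s_prev, s]` normalized by the row sum of `M[s_prev, ]`, computed at
#' prediction time without mutating `M`.
#'
#' @param state a learner state (recency, one-step, or SR).
#' @param s_prev,s predecessor and upcoming node (1-based); `s_prev` is
#'   ignored for recency.
#' @return scalar predictor value.
#' @export
predictor_value <- function(state, s_prev, s) {
  if (!is.null(state$W)) return(state$W[s])
  if (!is.null(state$T)) return(state$T[s_prev, s])
  rs <- sum(state$M[s_prev, ])
  if (rs <= 0) stop("zero row sum in M: predictor undefined")
  state$M[s_prev, s] / rs
}

#' Static (non-learning) SR from a whole sequence
#'
#' Computes the SR for the empirical transition probabilities across the
#' entire sequence, used by the model variant without trial-by-trial
#' learning.
#'
#' @inheritParams empirical_transition_matrix
#' @param gamma discount factor in \[0, 1).
#' @return a list with the `M` matrix and `gamma`.
#' @export
static_sr_state <- function(nodes, gamma, n_states = 15L) {
  T <- empirical_transition_matrix(nodes, n_states)
  list(M = sr_closed_form(T, gamma), gamma = gamma)
}

#' Fast forward pass of a learner over a node sequence
#'
#' Runs the requested learner across a full sequence and returns the
#' per-trial predictor value computed from the state before each trial's
#' update (i.e. the expectancy of the upcoming node at stimulus onset).
#' This is the engine behind the likelihood and the generative simulator.
#'
#' @param nodes integer vector of 1-based node ids.
#' @param kind one of `"recency"`, `"onestep"`, `"srtd"`.
#' @param alpha learning rate.
#' @param gamma,lambda SR-TD parameters (ignored otherwise).
#' @param n_states number of nodes.
#' @return numeric vector of predictor values (`NA` at trial 1 for the
#'   conditional learners, which need a predecessor).
#' @export
learner_predictors <- function(nodes, kind, alpha, gamma = NULL,
                               lambda = NULL, n_states = 15L) {
  nodes0 <- as.integer(nodes) - 1L
  switch(kind,
    recency = recency_predictors_cpp(nodes0, n_states, alpha),
    onestep = onestep_predictors_cpp(nodes0, n_states, alpha),
    srtd = srtd_run_cpp(nodes0, n_states, alpha, gamma, lambda)$pred,
    stop("unknown learner kind: ", kind)
  )
}

#' Run SR-TD(lambda) over a sequence and return the final state
#'
#' @inheritParams learner_predictors
#' @param M_init optional initial `M` (default: closed form under a uniform
#'   transition matrix).
#' @return list with final `M`, final trace `e`, and per-trial `pred`.
#' @export
srtd_run <- function(nodes, alpha, gamma, lambda, n_states = 15L,
                     M_init = NULL) {
  srtd_run_cpp(as.integer(nodes) - 1L, n_states, alpha, gamma, lambda, M_init)
}
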