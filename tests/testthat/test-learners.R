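test_that("recency update does exact delta-rule arithmetic and conserves mass", {
  st <- recency_state(15, alpha = 0.1)
  st <- recency_update(st, 3)
  expect_equal(st$W[3], 0.1 + 0.9 / 15)
  expect_equal(st$W[-3], rep(0.9 / 15, 14))
  st0 <- recency_state(15, alpha = 0)
  expect_equal(recency_update(st0, 5)$W, st0$W)
  st1 <- recency_state(15, alpha = 1)
  expect_equal(recency_update(st1, 5)$W, as.numeric(1:15 == 5))
  # conservation over a random update sequence
  set.seed(1)
  st <- recency_state(15, alpha = 0.37)
  for (s in sample.int(15, 200, TRUE)) st <- recency_update(st, s)
  expect_equal(sum(st$W), 1, tolerance = 1e-12)
  expect_true(all(st$W >= 0))
})

test_that("one-step update touches only the predecessor row and keeps it stochastic", {
  st <- onestep_state(15, alpha = 0.1)
  st <- onestep_update(st, 1, 2)
  expect_equal(st$T[1, 2], 0.1 + 0.9 / 15)
  expect_equal(st$T[1, -2], rep(0.9 / 15, 14))
  expect_equal(st$T[-1, ], matrix(1 / 15, 14, 15))
  st1 <- onestep_state(15, alpha = 1)
  expect_equal(onestep_update(st1, 4, 9)$T[4, ], as.numeric(1:15 == 9))
  # repeating 1 -> 2 follows the geometric closed form
  st <- onestep_state(15, alpha = 0.25)
  for (k in 1:12) {
    st <- onestep_update(st, 1, 2)
    expect_equal(st$T[1, 2], 1 - 0.75^k * (1 - 1 / 15), tolerance = 1e-12)
  }
  set.seed(2)
  st <- onestep_state(15, alpha = 0.6)
  for (k in 1:200) st <- onestep_update(st, sample.int(15, 1), sample.int(15, 1))
  expect_equal(rowSums(st$T), rep(1, 15), tolerance = 1e-12)
})

test_that("SR-TD update follows the dutch-trace order on a hand-stepped case", {
  st <- list(M = matrix(0, 2, 2), e = c(0, 0), alpha = 0.5, gamma = 0.5,
             lambda = 1)
  st <- srtd_update(st, 1, 2)
  expect_equal(st$M, rbind(c(0, 0.5), c(0, 0)))
  expect_equal(st$e, c(0.5, 0))
})

test_that("lambda = 0 reduces SR-TD to pure TD(0) bootstrapping", {
  set.seed(3)
  st <- srtd_state(15, alpha = 0.2, gamma = 0.6, lambda = 0)
  M0 <- st$M
  nodes <- random_walk(modular_graph, 50, seed = 4)
  for (t in 2:50) {
    prev <- st$M
    st <- srtd_update(st, nodes[t - 1], nodes[t])
    changed <- which(rowSums(abs(st$M - prev)) > 0)
    expect_true(all(changed == nodes[t - 1]))
    expect_equal(st$e, rep(0, 15))
  }
  # alpha = 0 leaves M untouched but the trace still accumulates and decays
  st <- list(M = M0, e = rep(0, 15), alpha = 0, gamma = 0.6, lambda = 1)
  st <- srtd_update(st, 2, 3)
  expect_equal(st$M, M0)
  expect_equal(st$e[2], 0.6)
})

test_that("closed-form SR matches the discounted power series and row sums", {
  T2 <- rbind(c(0, 1), c(1, 0))
  expect_equal(sr_closed_form(T2, 0.5),
               rbind(c(2 / 3, 4 / 3), c(4 / 3, 2 / 3)))
  T15 <- rand_stochastic(15, seed = 7)
  expect_equal(sr_closed_form(T15, 0), T15)
  gamma <- 0.8
  M <- sr_closed_form(T15, gamma)
  expect_equal(rowSums(M), rep(1 / (1 - gamma), 15), tolerance = 1e-10)
  series <- matrix(0, 15, 15)
  P <- diag(15)
  K <- 120
  for (k in 1:K) {
    P <- P %*% T15
    series <- series + gamma^(k - 1) * P
  }
  expect_lt(max(abs(M - series)), gamma^K / (1 - gamma) + 1e-12)
  expect_error(sr_closed_form(T15, 1))
})

test_that("discount horizon is the total discounted weight", {
  expect_equal(sr_horizon(0), 1)
  expect_equal(sr_horizon(0.9), 10)
  expect_error(sr_horizon(1))
})

test_that("empirical transition matrix counts transitions with uniform fallback", {
  T <- empirical_transition_matrix(c(1, 2, 1, 2), n_states = 3)
  expect_equal(T[1, 2], 1)
  expect_equal(T[2, 1], 1)
  expect_equal(T[3, ], rep(1 / 3, 3)) # never a source
  T <- empirical_transition_matrix(c(1, 2, 1, 3), n_states = 3)
  expect_equal(T[1, ], c(0, 0.5, 0.5))
  expect_equal(rowSums(T), rep(1, 3))
})

test_that("predictor values read out each learner correctly", {
  st <- onestep_state(15, alpha = 0.3)
  expect_equal(predictor_value(st, 4, 7), 1 / 15)
  st <- recency_update(recency_state(15, alpha = 1), 9)
  expect_equal(predictor_value(st, 1, 9), 1)
  # at the closed-form fixed point the normalized SR is (1 - gamma) * M
  T15 <- rand_stochastic(15, seed = 8)
  M <- sr_closed_form(T15, 0.7)
  st <- list(M = M, e = rep(0, 15), alpha = 0.1, gamma = 0.7, lambda = 0.5)
  expect_equal(predictor_value(st, 2, 5), (1 - 0.7) * M[2, 5],
               tolerance = 1e-10)
  expect_error(predictor_value(list(M = matrix(0, 2, 2)), 1, 2), "row sum")
})

test_that("compiled forward passes agree with stepwise R updates", {
  nodes <- random_walk(modular_graph, 300, seed = 10)
  # recency
  pr <- learner_predictors(nodes, "recency", alpha = 0.3)
  st <- recency_state(15, alpha = 0.3)
  for (t in seq_along(nodes)) {
    expect_equal(pr[t], predictor_value(st, NA, nodes[t]))
    st <- recency_update(st, nodes[t])
  }
  # one-step
  pa <- learner_predictors(nodes, "onestep", alpha = 0.2)
  st <- onestep_state(15, alpha = 0.2)
  expect_true(is.na(pa[1]))
  for (t in 2:length(nodes)) {
    expect_equal(pa[t], predictor_value(st, nodes[t - 1], nodes[t]))
    st <- onestep_update(st, nodes[t - 1], nodes[t])
  }
  # SR-TD, all three trace regimes
  for (lam in c(0, 0.5, 1)) {
    ps <- learner_predictors(nodes, "srtd", alpha = 0.15, gamma = 0.8,
                             lambda = lam)
    run <- srtd_run(nodes, alpha = 0.15, gamma = 0.8, lambda = lam)
    st <- srtd_state(15, alpha = 0.15, gamma = 0.8, lambda = lam)
    for (t in 2:length(nodes)) {
      expect_equal(ps[t], predictor_value(st, nodes[t - 1], nodes[t]),
                   tolerance = 1e-9)
      st <- srtd_update(st, nodes[t - 1], nodes[t])
    }
    expect_equal(run$M, st$M, tolerance = 1e-9)
  }
})

test_that("expected TD error vanishes at the closed-form fixed point", {
  T3 <- rand_stochastic(3, seed = 12)
  gamma <- 0.6
  M <- sr_closed_form(T3, gamma)
  for (i in 1:3) {
    # enumerate successors of i and average delta under T3
    exp_delta <- rep(0, 3)
    for (j in 1:3) {
      delta <- gamma * M[j, ] - M[i, ]
      delta[j] <- delta[j] + 1
      exp_delta <- exp_delta + T3[i, j] * delta
    }
    expect_equal(exp_delta, rep(0, 3), tolerance = 1e-10)
  }
})

test_that("with lambda = 1 the bootstrap term cancels across consecutive updates", {
  # two transitions A -> B -> C with distinct states: the gamma * M[B, ]
  # bootstrap contributed by the first update is removed by the second
  # because the trace has decayed by exactly gamma, leaving the composite
  # M[A, ] <- M[A, ] + alpha * (I_B + gamma * I_C + gamma^2 M[C, ] - M[A, ])
  set.seed(13)
  M0 <- matrix(rexp(9), 3, 3)
  alpha <- 0.3; gamma <- 0.7
  st <- list(M = M0, e = rep(0, 3), alpha = alpha, gamma = gamma, lambda = 1)
  st <- srtd_update(st, 1, 2)
  st <- srtd_update(st, 2, 3)
  composite <- M0[1, ] + alpha * (c(0, 1, 0) + gamma * c(0, 0, 1) +
                                    gamma^2 * M0[3, ] - M0[1, ])
  expect_equal(st$M[1, ], composite, tolerance = 1e-12)
})
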