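test_that("nuisance regressors follow the lag and windowed-count conventions", {
  expect_equal(compute_nuisance(c(1, 2, 1), 3)[["r_ntrials"]], 2)
  expect_equal(compute_nuisance(c(1, 2, 3), 3)[["r_ntrials"]], 100) # first occurrence
  expect_equal(compute_nuisance(c(1, 2, 1), 3)[["r_lag10"]], log(2))
  expect_equal(compute_nuisance(c(1, 2, 3), 3)[["r_lag10"]], 0)
  # cap binds
  nodes <- c(1, rep(2, 150), 1)
  expect_equal(compute_nuisance(nodes, length(nodes))[["r_ntrials"]], 100)
  # vectorized version agrees with the per-trial definition
  set.seed(4)
  nodes <- sample.int(15, 400, TRUE)
  nr <- nuisance_regressors(nodes)
  for (t in c(1, 2, 17, 100, 399, 400)) {
    ref <- compute_nuisance(nodes, t)
    expect_equal(nr$r_ntrials[t], ref[["r_ntrials"]])
    expect_equal(nr$r_lag10[t], ref[["r_lag10"]])
  }
})

test_that("predicted mean is the stated linear combination", {
  p <- list(mu0 = 6, target_offsets = c(0, rep(0.2, 14)))
  expect_equal(predicted_mu(p, target = 1, trial_scaled = 0.7), 6)
  expect_equal(predicted_mu(p, target = 5, trial_scaled = 0), 6.2)
  p <- list(mu0 = 6, beta_trial = -0.1, beta_A = -1,
            target_offsets = rep(0, 15))
  expect_equal(predicted_mu(p, 1, trial_scaled = 0.5, A = 0.2), 5.75)
  # linearity: two models sharing regressors differ by beta_A * delta-predictor
  d <- predicted_mu(p, 1, 0.5, A = 0.3) - predicted_mu(p, 1, 0.5, A = 0.2)
  expect_equal(d, -1 * 0.1)
})

test_that("shifted log-normal density is correct, normalized, and guards support", {
  expect_equal(shifted_lognormal_loglik(1, mu = 0, sigma = 1, shift = 0),
               -0.5 * log(2 * pi))
  rt <- c(250, 400, 801)
  expect_equal(shifted_lognormal_loglik(rt, 5.5, 0.4, shift = 0),
               dlnorm(rt, 5.5, 0.4, log = TRUE))
  # integrates to 1 over (shift, Inf)
  dens <- function(x) exp(shifted_lognormal_loglik(x, mu = 5.5, sigma = 0.4,
                                                   shift = 120))
  total <- integrate(Vectorize(dens), 120, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_warning(out <- shifted_lognormal_loglik(100, 5, 0.4, shift = 150),
                 "below the shift")
  expect_identical(out, -Inf)
})

test_that("sequence likelihood matches an independent trial-by-trial recomputation", {
  g <- modular_graph
  params <- default_group_means()
  tab <- simulate_subject(g, params, seed = 21, n_trials = 700)
  spec <- model_spec("recency_srtd")
  pl <- srtrace:::params_to_list(spec, params)
  ll <- sequence_loglik(spec, pl, tab)
  # recompute with the R-level stepping learners and density
  cfg <- default_run_config()
  nodes <- tab$node
  W <- learner_predictors(nodes, "recency", pl$alpha_W)
  A <- learner_predictors(nodes, "srtd", pl$alpha_A, pl$gamma, pl$lambda)
  nr <- nuisance_regressors(nodes)
  keep <- which(tab$trial > cfg$equilibration & tab$correct &
                  tab$rt_ms >= cfg$min_rt_ms & seq_along(nodes) >= 2)
  shift <- pl$shift_frac * min(tab$rt_ms[tab$correct & tab$rt_ms >= 30])
  mu <- predicted_mu(
    list(mu0 = pl$mu0, beta_trial = pl$beta_trial,
         target_offsets = c(0, pl$target_offsets2_15),
         beta_W = pl$beta_W, beta_A = pl$beta_A,
         beta_ntrials = pl$beta_ntrials, beta_lag10 = pl$beta_lag10),
    tab$target[keep], (tab$trial[keep] - 1) / (nrow(tab) - 1),
    W = W[keep], A = A[keep],
    r_ntrials = nr$r_ntrials[keep], r_lag10 = nr$r_lag10[keep]
  )
  ref <- sum(shifted_lognormal_loglik(tab$rt_ms[keep], mu, pl$sigma, shift))
  expect_equal(ll, ref, tolerance = 1e-8)
})

test_that("equilibration-period RTs do not affect the likelihood", {
  params <- default_group_means()
  tab <- simulate_subject(modular_graph, params, seed = 22, n_trials = 900)
  spec <- model_spec("recency_srtd")
  pl <- srtrace:::params_to_list(spec, params)
  ll1 <- sequence_loglik(spec, pl, tab)
  tab2 <- tab
  # perturb early RTs upwards (keeps the session minimum intact)
  tab2$rt_ms[tab2$trial <= 500] <- tab2$rt_ms[tab2$trial <= 500] + 250
  expect_equal(sequence_loglik(spec, pl, tab2), ll1)
  # an all-equilibration session yields zero log-likelihood with a warning
  short <- tab[tab$trial <= 400, ]
  expect_warning(ll0 <- sequence_loglik(spec, pl, short), "no trials")
  expect_identical(ll0, 0)
})

test_that("predictor caching never changes the objective", {
  params <- default_group_means()
  tab <- simulate_subject(modular_graph, params, seed = 23, n_trials = 800)
  spec <- model_spec("recency_srtd")
  sess <- srtrace:::prep_session(tab)
  pm <- transform_params(spec, params)
  f_cached <- srtrace:::make_nlpost(spec, sess, pm)
  f_plain <- function(theta) {
    nat <- untransform_params(spec, setNames(theta, names(pm)))
    srtrace:::session_negloglik(spec, srtrace:::params_to_list(spec, nat),
                                sess) +
      0.5 * length(pm) * log(2 * pi) + 0.5 * sum((theta - pm)^2)
  }
  set.seed(6)
  for (i in 1:25) {
    theta <- pm + rnorm(length(pm), sd = 0.3)
    expect_equal(f_cached(theta), f_plain(theta), tolerance = 1e-10)
  }
})

test_that("trial tables round-trip through delimited text with schema checks", {
  tab <- simulate_subject(modular_graph, default_group_means(), seed = 24,
                          n_trials = 60)
  path <- file.path(tempdir(), "trials.csv")
  write_trials(tab, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  bad <- tab[, setdiff(names(tab), "rt_ms")]
  expect_error(write_trials(bad, path), "rt_ms")
  readr::write_csv(bad, path)
  expect_error(read_trials(path), "rt_ms")
})
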