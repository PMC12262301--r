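# conjugate-Gaussian toy problem: likelihood N(y | theta, s2), prior N(0, 1).
# The posterior is Gaussian, so the Laplace marginal must equal the analytic
# marginal N(y | 0, s2 + 1) exactly.
test_that("Laplace marginal is exact for a Gaussian toy posterior", {
  y <- 1.3
  s2 <- 0.5^2
  f <- function(theta) {
    -dnorm(y, theta, sqrt(s2), log = TRUE) - dnorm(theta, 0, 1, log = TRUE)
  }
  map <- y / (s2 + 1) * 1 # posterior mean with prior variance 1
  H <- matrix(1 / s2 + 1, 1, 1)
  nlm <- laplace_marginal(list(par = map, value = f(map)), H)
  expect_equal(nlm, -dnorm(y, 0, sqrt(s2 + 1), log = TRUE), tolerance = 1e-10)
  # zero-information likelihood: marginal equals the prior normalization (= 1)
  g <- function(theta) -dnorm(theta, 0, 1, log = TRUE)
  nlm0 <- laplace_marginal(list(par = 0, value = g(0)), matrix(1, 1, 1))
  expect_equal(nlm0, 0, tolerance = 1e-10)
})

test_that("Laplace marginal tracks 1-D quadrature for a non-Gaussian posterior", {
  set.seed(41)
  y <- rnorm(25, mean = exp(0.4), sd = 1)
  nll <- function(theta) sum(-dnorm(y, exp(theta), 1, log = TRUE))
  f <- function(theta) nll(theta) - dnorm(theta, 0, 1, log = TRUE)
  opt <- optimize(f, c(-3, 3))
  H <- pracma::hessian(f, opt$minimum)
  lap <- laplace_marginal(list(par = opt$minimum, value = opt$objective), H)
  quad <- -log(integrate(Vectorize(function(t) exp(-f(t))), -8, 8,
                         rel.tol = 1e-10)$value)
  expect_equal(lap, quad, tolerance = 1e-3)
})

test_that("Hessian repair path is flagged for non-positive-definite curvature", {
  H <- diag(c(2, -1))
  expect_warning(
    out <- laplace_marginal(list(par = c(0, 0), value = 5), H),
    "not positive definite"
  )
  expect_true(is.finite(out))
})

test_that("MAP estimation improves on the prior mean and responds to the prior", {
  tab <- simulate_subject(modular_graph, default_group_means("recency"),
                          model = "recency", seed = 43, n_trials = 800)
  spec <- model_spec("recency")
  pm <- transform_params(spec, default_start(spec))
  fit <- map_estimate_subject(tab, spec, pm,
                              em_control(n_restarts = 2, optim_maxit = 60))
  f <- srtrace:::make_nlpost(spec, srtrace:::prep_session(tab), pm)
  expect_lt(fit$value, f(pm))
  expect_named(fit$par, spec$params$name)
  # prior-dominated limit: with a huge prior pull (via an empty-information
  # subset this is impractical; instead verify the prior term is active by
  # shifting the prior mean and observing the MAP move in that direction)
  pm2 <- pm
  pm2["beta_trial"] <- pm["beta_trial"] + 3
  fit2 <- map_estimate_subject(tab, spec, pm2,
                               em_control(n_restarts = 1, optim_maxit = 60))
  expect_gt(fit2$par["beta_trial"], fit$par["beta_trial"])
})

test_that("EM recovers stage-difference coefficients and decreases its objective", {
  # the built-in stage difference goes on beta_trial, which the likelihood
  # identifies directly (a stage offset on mu0 can trade off against the
  # shift fraction)
  cfg <- generative_config(
    n_subjects = 8L, n_trials = 700L, model = "recency",
    group_means = default_group_means("recency"),
    stage_coefs = setNames(
      ifelse(model_spec("recency")$params$name == "beta_trial", 0.3, 0),
      model_spec("recency")$params$name
    ),
    subject_sd = 0.05, seed = 51L
  )
  pop <- simulate_population(cfg)
  fit <- em_fit(pop$trials, "recency",
                em_control(max_iter = 4, tol = 1e-3, n_restarts = 1,
                           optim_maxit = 60, seed = 2))
  expect_lt(abs(fit$group$stage_coefs[["beta_trial"]] - 0.3), 0.1)
  expect_lt(max(abs(fit$group$stage_coefs[paste0("target", 2:15)])), 0.1)
  # objective is non-increasing across sweeps (small tolerance for
  # optimizer noise)
  expect_true(all(diff(fit$objective_trace) < 1e-2))
  # group mean mu0 near truth
  expect_equal(unname(fit$group$natural_means["mu0"]), log(500),
               tolerance = 0.1)
})

test_that("model scores apply the shared AIC penalty and compare correctly", {
  fake <- structure(
    list(subjects = tibble::tibble(
      session = c("a", "b", "c", "d"), subject = c("a", "b", "c", "d"),
      stage = c(-1, 1, -1, 1), neg_log_marginal = c(10, 12, 9, 11)
    ), n_group_params = 8L),
    class = "srtrace_fit"
  )
  sc <- model_score(fake)
  expect_equal(sc$score, c(10, 12, 9, 11) + 2)
  expect_equal(model_score(fake, n_group_params = 0)$score, c(10, 12, 9, 11))
  # adding k unused group parameters worsens every score by k/N
  expect_equal(model_score(fake, n_group_params = 12L)$score - sc$score,
               rep(1, 4))
  # paired comparison identities
  same <- compare_models(sc, sc)
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_true(same$degenerate)
  a <- c(0, 0, 0, 0); b <- c(1, 2, 3, 4)
  cmp <- compare_models(a, b, alternative = "less")
  d <- a - b
  expect_equal(cmp$t, mean(d) / (sd(d) / sqrt(4)))
  expect_equal(cmp$t, -compare_models(b, a, alternative = "greater")$t)
  expect_lt(cmp$p, 0.05)
})

test_that("fitted parameters export as a tidy table", {
  spec <- model_spec("recency")
  maps <- rbind(transform_params(spec, default_group_means("recency")),
                transform_params(spec, default_group_means("recency")) + 0.1)
  fake <- structure(
    list(spec = spec, maps = maps,
         subjects = tibble::tibble(session = c("s1", "s2"),
                                   subject = c("s1", "s2"),
                                   stage = c(-1, 1))),
    class = "srtrace_fit"
  )
  tab <- fit_parameters_table(fake)
  expect_equal(nrow(tab), 2 * nrow(spec$params))
  row <- tab[tab$session == "s1" & tab$parameter == "alpha_W", ]
  expect_equal(row$natural, 0.3, tolerance = 1e-10)
})
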