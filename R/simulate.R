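#' Default generative group-level parameters
#'
#' Natural-scale group means used by the simulator. Values emulate a
#' serial reaction time task: baseline RT near 500 ms, moderate log-scale
#' noise, a mild practice effect, two-key motor codes slower than
#' single-key ones, and negative predictor weights (higher expectancy of
#' the upcoming node speeds the response) of a size detectable in a group
#' of about 40 subjects. The SR-TD component defaults to gamma = 0.8 and
#' lambda = 0.6.
#'
#' @param model model name or specification (subsets the parameter list).
#' @return named natural-scale numeric vector over the model's parameters.
#' @export
default_group_means <- function(model = "recency_srtd") {
  spec <- as_model_spec(model)
  vals <- c(
    mu0 = log(500), beta_trial = -0.1,
    setNames(c(rep(0, 4), rep(0.12, 10)), paste0("target", 2:15)),
    beta_ntrials = 0.001, beta_lag10 = -0.03,
    shift_frac = 0.5, sigma = 0.2,
    beta_W = -0.8, alpha_W = 0.3,
    beta_A = -1.0, alpha_A = 0.15,
    gamma = 0.8, lambda = 0.6
  )
  vals[spec$params$name]
}

#' Default subject-level heterogeneity of the generator
#'
#' Standard deviations of the unconstrained-scale subject draw. Most
#' parameters use a moderate 0.5 (baseline RTs spanning roughly 300-800 ms
#' across subjects, learning rates spanning a few-fold range). The two
#' lag-count nuisance slopes are exceptions: their regressors reach 100
#' (trials since the node was last seen), so their subject spread is kept
#' proportionally small — a unit-scale draw there would generate
#' physically impossible reaction times.
#'
#' @param model model name or specification.
#' @return named numeric vector of standard deviations.
#' @export
default_subject_sd <- function(model = "recency_srtd") {
  spec <- as_model_spec(model)
  sd <- setNames(rep(0.5, nrow(spec$params)), spec$params$name)
  if ("beta_ntrials" %in% names(sd)) sd["beta_ntrials"] <- 0.002
  if ("beta_lag10" %in% names(sd)) sd["beta_lag10"] <- 0.03
  sd
}

#' Generative configuration for a synthetic experiment
#'
#' @param graph_kind graph topology, see [build_graph()].
#' @param n_subjects number of simulated subjects (one session each).
#' @param n_trials trials per session.
#' @param model generating model.
#' @param group_means natural-scale group means (defaults to
#'   [default_group_means()]).
#' @param stage_coefs unconstrained-scale stage-difference coefficients
#'   (default all zero).
#' @param subject_sd standard deviation of the subject-level draw on the
#'   unconstrained scale: a scalar, a named per-parameter vector, or the
#'   default [default_subject_sd()]. A value of 0 makes all subjects
#'   identical.
#' @param shift_ms generative RT floor in ms.
#' @param contamination fraction of trials flagged as errors (exercises
#'   the exclusion filters; default off).
#' @param seed master seed.
#' @return named list of class `generative_config`.
#' @export
generative_config <- function(graph_kind = "modular", n_subjects = 40L,
                              n_trials = 1500L, model = "recency_srtd",
                              group_means = default_group_means(model),
                              stage_coefs = NULL,
                              subject_sd = default_subject_sd(model),
                              shift_ms = 150, contamination = 0,
                              seed = 1L) {
  spec <- as_model_spec(model)
  stopifnot(setequal(names(group_means), spec$params$name))
  if (is.null(stage_coefs)) {
    stage_coefs <- setNames(rep(0, nrow(spec$params)), spec$params$name)
  }
  structure(
    list(graph_kind = graph_kind, n_subjects = as.integer(n_subjects),
         n_trials = as.integer(n_trials), model = spec,
         group_means = group_means[spec$params$name],
         stage_coefs = stage_coefs[spec$params$name],
         subject_sd = subject_sd, shift_ms = shift_ms,
         contamination = contamination, seed = as.integer(seed)),
    class = "generative_config"
  )
}

#' Simulate one session of the RT task
#'
#' Walks the graph, updates the model's learners trial by trial, forms the
#' per-trial predicted mean ([predicted_mu()]) and draws
#' `log(rt - shift) ~ Normal(mu_t, sigma^2)`. All responses are correct
#' unless a contamination rate is requested.
#'
#' @param graph a `walk_graph`.
#' @param params named natural-scale parameter vector for `model`.
#' @param model model name or specification (generative component set).
#' @param n_trials number of trials.
#' @param seed integer seed (walk, motor map and noise derive from it).
#' @param subject subject id label.
#' @param stage stage covariate (-1 or +1).
#' @param shift_ms generative RT floor (ms).
#' @param contamination probability a trial is flagged incorrect.
#' @return a trial table tibble (see [read_trials()] for the schema).
#' @export
simulate_subject <- function(graph, params, model = "recency_srtd",
                             n_trials = 1500L, seed = 1L, subject = "S01",
                             stage = -1L, shift_ms = 150,
                             contamination = 0) {
  spec <- as_model_spec(model)
  pl <- params_to_list(spec, params[spec$params$name])
  nodes <- random_walk(graph, n_trials, seed = seed)
  target_map <- assign_motor_targets(graph$n_nodes, seed = seed + 1L)
  target <- target_map[nodes]
  nuis <- nuisance_regressors(nodes)
  trial_scaled <- (seq_len(n_trials) - 1) / max(1, n_trials - 1)

  W <- if (spec$use_recency) {
    learner_predictors(nodes, "recency", pl$alpha_W, n_states = graph$n_nodes)
  } else 0
  A <- if (spec$higher == 1L) {
    learner_predictors(nodes, "onestep", pl$alpha_A, n_states = graph$n_nodes)
  } else if (spec$higher == 2L) {
    learner_predictors(nodes, "srtd", pl$alpha_A, pl$gamma, pl$lambda,
                       n_states = graph$n_nodes)
  } else if (spec$higher == 3L) {
    st <- static_sr_state(nodes, pl$gamma, graph$n_nodes)
    rs <- rowSums(st$M)
    c(NA, st$M[cbind(nodes[-n_trials], nodes[-1])] / rs[nodes[-n_trials]])
  } else 0
  if (length(A) > 1) A[is.na(A)] <- 0

  mu <- predicted_mu(
    list(mu0 = pl$mu0, beta_trial = pl$beta_trial,
         target_offsets = c(0, pl$target_offsets2_15),
         beta_W = pl$beta_W, beta_A = pl$beta_A,
         beta_ntrials = pl$beta_ntrials, beta_lag10 = pl$beta_lag10),
    target = target, trial_scaled = trial_scaled, W = W, A = A,
    r_ntrials = nuis$r_ntrials, r_lag10 = nuis$r_lag10
  )
  rt <- with_seed(seed + 2L, shift_ms + exp(mu + pl$sigma * rnorm(n_trials)))
  correct <- rep(TRUE, n_trials)
  if (contamination > 0) {
    correct <- with_seed(seed + 3L, runif(n_trials) >= contamination)
  }
  tibble::tibble(
    subject = subject, stage = as.integer(stage), trial = seq_len(n_trials),
    node = nodes, target = target, rt_ms = rt, correct = correct
  )
}

#' Simulate a hierarchical population of subjects
#'
#' Subject-level parameters are drawn on the unconstrained scale from
#' `Normal(group_mean + stage_coef * covariate, subject_sd^2 I)` and
#' untransformed; each subject then runs one session via
#' [simulate_subject()]. Stage covariates alternate -1 / +1 across
#' subjects. The returned manifest records every draw, providing exact
#' ground truth for recovery studies.
#'
#' @param config a [generative_config()].
#' @return list with `trials` (all sessions bound), `graph`, `truth`
#'   (tidy tibble of generating parameters per session, natural and
#'   unconstrained), and `config`.
#' @export
simulate_population <- function(config = generative_config()) {
  spec <- config$model
  graph <- build_graph(config$graph_kind, seed = config$seed)
  means_u <- transform_params(spec, config$group_means)
  k <- length(means_u)
  sd_vec <- config$subject_sd
  if (!is.null(names(sd_vec))) {
    sd_vec <- sd_vec[spec$params$name]
  } else {
    sd_vec <- rep_len(sd_vec, k)
  }
  trials <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    cov_i <- if (i %% 2L == 1L) -1L else 1L
    theta_u <- with_seed(
      config$seed + 1000L * i,
      means_u + config$stage_coefs * cov_i + sd_vec * rnorm(k)
    )
    nat <- untransform_params(spec, theta_u)
    id <- sprintf("S%03d", i)
    trials[[i]] <- simulate_subject(
      graph, nat, spec, config$n_trials, seed = config$seed + 1000L * i + 1L,
      subject = id, stage = cov_i, shift_ms = config$shift_ms,
      contamination = config$contamination
    )
    truth[[i]] <- tibble::tibble(
      subject = id, stage = cov_i, parameter = spec$params$name,
      natural = unname(nat), unconstrained = unname(theta_u)
    )
  }
  list(trials = dplyr::bind_rows(trials), graph = graph,
       truth = dplyr::bind_rows(truth), config = config)
}

#' Simulate pure trace or bootstrap learner agents
#'
#' Agents learn with SR-TD(lambda) at lambda = 1 (`"trace"`) or lambda = 0
#' (`"bootstrap"`); all other parameters are fixed mid-range defaults
#' (alpha 0.4, gamma 0.7, beta_A -2, sigma 0.15, no recency component, no
#' nuisance effects). Used by the model-agnostic signature analyses to
#' establish what each learning rule predicts.
#'
#' @param graph a `walk_graph`.
#' @param rule `"trace"` or `"bootstrap"`.
#' @param n_agents number of agents.
#' @param n_trials trials per agent.
#' @param seed master seed.
#' @return a trial table tibble covering all agents.
#' @export
simulate_signature_agents <- function(graph, rule = c("trace", "bootstrap"),
                                      n_agents = 40L, n_trials = 1500L,
                                      seed = 1L) {
  rule <- match.arg(rule)
  lambda <- if (rule == "trace") 1 else 0
  spec <- model_spec("srtd")
  params <- c(
    mu0 = log(500), beta_trial = 0,
    setNames(rep(0, 14), paste0("target", 2:15)),
    beta_ntrials = 0, beta_lag10 = 0, shift_frac = 0.5, sigma = 0.15,
    beta_A = -2, alpha_A = 0.4, gamma = 0.7, lambda = lambda
  )
  out <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    out[[i]] <- simulate_subject(
      graph, params, spec, n_trials, seed = seed + 1000L * i,
      subject = sprintf("%s%03d", toupper(substr(rule, 1, 1)), i),
      stage = -1L
    )
  }
  dplyr::bind_rows(out)
}
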