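#' Default analysis configuration
#'
#' Collects the fixed constants of the analysis: the equilibration length
#' (trials run through the learners but excluded from likelihood), the
#' implausible-RT floor, the cap on the trials-since-last-seen regressor and
#' the window of the recent-occurrence regressor.
#'
#' @param equilibration number of initial trials excluded from likelihood.
#' @param min_rt_ms minimum plausible RT in ms; faster trials are excluded.
#' @param ntrials_cap cap on the trials-since-node-last-seen regressor; also
#'   its value at a node's first occurrence.
#' @param lag_window window (in trials) of the recent-occurrence regressor.
#' @return a named list.
#' @export
default_run_config <- function(equilibration = 500L, min_rt_ms = 30,
                               ntrials_cap = 100L, lag_window = 10L) {
  list(equilibration = as.integer(equilibration), min_rt_ms = min_rt_ms,
       ntrials_cap = as.integer(ntrials_cap),
       lag_window = as.integer(lag_window))
}

#' Recency nuisance regressors at a single trial
#'
#' `r_ntrials` is the number of trials elapsed since the current node last
#' occurred, capped at `cap` and set to the cap when the node has not yet
#' occurred. `r_lag10` is `log(1 + k)` where `k` is the number of
#' occurrences of the current node among the previous `window` trials (the
#' `log1p` form keeps the regressor finite at zero occurrences).
#'
#' @param nodes integer vector of node ids.
#' @param t trial index (1-based).
#' @param cap cap for `r_ntrials`.
#' @param window lookback window for `r_lag10`.
#' @return named numeric vector `c(r_ntrials, r_lag10)`.
#' @export
compute_nuisance <- function(nodes, t, cap = 100L, window = 10L) {
  stopifnot(t >= 1, t <= length(nodes))
  prev <- which(nodes[seq_len(t - 1L)] == nodes[t])
  r_ntrials <- if (length(prev)) min(t - max(prev), cap) else cap
  recent <- nodes[seq(max(1L, t - window), length.out = min(t - 1L, window))]
  r_lag10 <- log1p(sum(recent == nodes[t]))
  c(r_ntrials = r_ntrials, r_lag10 = r_lag10)
}

#' Nuisance regressors for a whole sequence
#'
#' Vectorized version of [compute_nuisance()] over all trials.
#'
#' @inheritParams compute_nuisance
#' @return tibble with columns `r_ntrials` and `r_lag10`.
#' @export
nuisance_regressors <- function(nodes, cap = 100L, window = 10L) {
  n <- length(nodes)
  r_nt <- numeric(n)
  r_l10 <- numeric(n)
  last_seen <- rep(NA_integer_, max(nodes))
  for (t in seq_len(n)) {
    s <- nodes[t]
    r_nt[t] <- if (is.na(last_seen[s])) cap else min(t - last_seen[s], cap)
    lo <- max(1L, t - window)
    r_l10[t] <- log1p(if (t > 1L) sum(nodes[lo:(t - 1L)] == s) else 0L)
    last_seen[s] <- t
  }
  tibble::tibble(r_ntrials = r_nt, r_lag10 = r_l10)
}

#' Per-trial predicted mean of log shifted RT
#'
#' The linear model
#' `mu = mu0 + beta_trial * trial + target_offset + beta_W * W +
#' beta_A * A + beta_ntrials * r_ntrials + beta_lag10 * r_lag10`,
#' where `trial` is the trial index rescaled to \[0, 1\], `target_offset`
#' is a per-motor-code offset with code 1 as the reference level (offset
#' 0), `W` is the recency predictor and `A` the higher-order (one-step /
#' SR) predictor. Single-component models are the same formula with the
#' absent beta fixed at 0.
#'
#' @param params list with `mu0`, `beta_trial`, `target_offsets` (length-15
#'   vector, first entry 0), `beta_W`, `beta_A`, `beta_ntrials`,
#'   `beta_lag10` (missing entries default to 0).
#' @param target integer motor codes (1-15).
#' @param trial_scaled trial index rescaled to \[0, 1\].
#' @param W,A predictor values (scalars or vectors; default 0).
#' @param r_ntrials,r_lag10 nuisance regressors.
#' @return numeric vector of predicted means on the log-ms scale.
#' @export
predicted_mu <- function(params, target, trial_scaled, W = 0, A = 0,
                         r_ntrials = 0, r_lag10 = 0) {
  p <- function(nm) if (is.null(params[[nm]])) 0 else params[[nm]]
  offs <- params$target_offsets
  if (is.null(offs)) offs <- rep(0, 15)
  p("mu0") + p("beta_trial") * trial_scaled + offs[target] +
    p("beta_W") * W + p("beta_A") * A +
    p("beta_ntrials") * r_ntrials + p("beta_lag10") * r_lag10
}

#' Shifted log-normal log-density
#'
#' `log(rt - shift) ~ Normal(mu, sigma^2)`; the returned value includes the
#' Jacobian term `-log(rt - shift)` so it is a proper density over RT.
#' Observations at or below the shift are outside the support; they yield
#' `-Inf` with a warning rather than being silently dropped.
#'
#' @param rt reaction times (ms).
#' @param mu,sigma mean and standard deviation on the log scale.
#' @param shift shift (minimum possible RT) in ms.
#' @return vector of log-densities.
#' @export
shifted_lognormal_loglik <- function(rt, mu, sigma, shift = 0) {
  stopifnot(sigma > 0, shift >= 0)
  x <- rt - shift
  bad <- x <= 0
  if (any(bad)) {
    warning(sum(bad), " observation(s) at or below the shift: log-density -Inf")
  }
  mu <- rep_len(mu, length(x))
  out <- rep(-Inf, length(x))
  out[!bad] <- dnorm(log(x[!bad]), mu[!bad], sigma, log = TRUE) - log(x[!bad])
  out
}

# --- session preparation -----------------------------------------------------

# Precompute everything about one session (one subject x stage) that does not
# depend on parameters: node sequence, regressors, inclusion mask, minimum
# observed RT, empirical transition matrix (for the static SR model).
prep_session <- function(table, n_states = 15L, config = default_run_config()) {
  stopifnot(all(diff(table$trial) > 0))
  nodes <- as.integer(table$node)
  n <- nrow(table)
  nuis <- nuisance_regressors(nodes, config$ntrials_cap, config$lag_window)
  ok <- table$correct & table$rt_ms >= config$min_rt_ms
  include <- ok & table$trial > config$equilibration & seq_len(n) >= 2L
  if (!any(ok)) stop("session has no valid trials")
  inc_idx <- which(include)
  trial_scaled <- (table$trial - min(table$trial)) /
    max(1, (max(table$trial) - min(table$trial)))
  list(
    inc_idx = inc_idx,
    trial_scaled_inc = trial_scaled[inc_idx],
    target_inc = as.integer(table$target)[inc_idx],
    r_ntrials_inc = nuis$r_ntrials[inc_idx],
    r_lag10_inc = nuis$r_lag10[inc_idx],
    rt_inc = as.numeric(table$rt_ms)[inc_idx],
    subject = table$subject[1],
    stage = table$stage[1],
    nodes = nodes,
    nodes0 = nodes - 1L,
    rt = as.numeric(table$rt_ms),
    target0 = as.integer(table$target) - 1L,
    target = as.integer(table$target),
    trial_scaled = trial_scaled,
    r_ntrials = nuis$r_ntrials,
    r_lag10 = nuis$r_lag10,
    include = include,
    min_rt = min(table$rt_ms[ok]),
    n_states = n_states,
    emp_T = empirical_transition_matrix(nodes, n_states)
  )
}

#' Total log-likelihood of one session under a model
#'
#' Iterates the model's learners over every trial of the session (learner
#' states update on all trials, including excluded ones — the stimulus was
#' seen) and sums the shifted log-normal log-density over included trials
#' only: trials after the equilibration period, with a correct response,
#' RT at or above the plausibility floor, and a defined predecessor. The
#' shift is `shift_frac` times the session's minimum observed RT.
#'
#' @param model a model specification (see [model_spec()]) or its name.
#' @param params named list of natural-scale parameters (see [model_spec()]
#'   for the parameter set of each model).
#' @param table a trial table for a single session, or a prepared session
#'   object.
#' @param config analysis configuration, see [default_run_config()].
#' @return total log-likelihood (scalar). Zero, with a warning, when no
#'   trial qualifies.
#' @export
sequence_loglik <- function(model, params, table,
                            config = default_run_config()) {
  spec <- as_model_spec(model)
  sess <- if (is.data.frame(table)) prep_session(table, config = config) else table
  if (!any(sess$include)) {
    warning("no trials enter the likelihood; returning 0")
    return(0)
  }
  -session_negloglik(spec, params, sess)
}

# Negative log-likelihood over included trials. The learner forward passes
# (the expensive part) depend only on the learner parameters, not on the
# regression weights, so they are memoized in `cache` — during
# finite-difference gradients most perturbations leave them untouched.
session_negloglik <- function(spec, params, sess, cache = NULL) {
  n <- length(sess$nodes)
  W <- 0
  if (spec$use_recency) {
    W <- cached_predictor(cache, "W", params$alpha_W, function() {
      recency_predictors_cpp(sess$nodes0, sess$n_states, params$alpha_W)
    })
  }
  A <- 0
  if (spec$higher == 1L) {
    A <- cached_predictor(cache, "A", params$alpha_A, function() {
      onestep_predictors_cpp(sess$nodes0, sess$n_states, params$alpha_A)
    })
  } else if (spec$higher == 2L) {
    key <- c(params$alpha_A, params$gamma, params$lambda)
    A <- cached_predictor(cache, "A", key, function() {
      srtd_run_cpp(sess$nodes0, sess$n_states, params$alpha_A, params$gamma,
                   params$lambda)$pred
    })
  } else if (spec$higher == 3L) {
    A <- cached_predictor(cache, "A", params$gamma, function() {
      M <- sr_closed_form(sess$emp_T, params$gamma)
      rs <- rowSums(M)
      idx <- 2:n
      c(NA, M[cbind(sess$nodes[idx - 1L], sess$nodes[idx])] /
          rs[sess$nodes[idx - 1L]])
    })
  }
  inc <- sess$inc_idx
  mu <- params$mu0 + params$beta_trial * sess$trial_scaled_inc +
    c(0, params$target_offsets2_15)[sess$target_inc] +
    params$beta_ntrials * sess$r_ntrials_inc +
    params$beta_lag10 * sess$r_lag10_inc
  if (spec$use_recency) mu <- mu + params$beta_W * W[inc]
  if (spec$higher > 0L) mu <- mu + params$beta_A * A[inc]
  x <- sess$rt_inc - params$shift_frac * sess$min_rt
  if (any(x <= 0) || params$sigma <= 0) return(Inf)
  lx <- log(x)
  z <- (lx - mu) / params$sigma
  length(x) * (0.5 * log(2 * pi) + log(params$sigma)) +
    0.5 * sum(z * z) + sum(lx)
}

cached_predictor <- function(cache, slot, key, compute) {
  if (is.null(cache)) return(compute())
  kslot <- paste0(slot, "_key")
  if (!is.null(cache[[kslot]]) && identical(cache[[kslot]], key)) {
    return(cache[[slot]])
  }
  val <- compute()
  cache[[kslot]] <- key
  cache[[slot]] <- val
  val
}

# --- trial table I/O ---------------------------------------------------------

TRIAL_COLUMNS <- c("subject", "stage", "trial", "node", "target", "rt_ms",
                   "correct")

#' Read / write trial tables
#'
#' Trial tables are delimited text (CSV or TSV inferred from the extension)
#' with one row per trial and fixed columns `subject`, `stage`, `trial`,
#' `node`, `target`, `rt_ms`, `correct`. Node and target ids are 1-based.
#'
#' @param path file path (`.csv` or `.tsv`).
#' @return a tibble with the columns above.
#' @export
read_trials <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  out <- reader(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out$correct <- as.logical(out$correct)
  out[TRIAL_COLUMNS]
}

#' @rdname read_trials
#' @param table a trial table.
#' @export
write_trials <- function(table, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(table))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(table[TRIAL_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Split a multi-session trial table into sessions
#'
#' @param table a trial table (possibly many subjects/stages).
#' @return named list of single-session tibbles, keyed `subject.stage`.
#' @export
split_sessions <- function(table) {
  split(table, interaction(table$subject, table$stage, drop = TRUE,
                           lex.order = TRUE))
}
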