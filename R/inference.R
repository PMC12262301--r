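#' EM control settings
#'
#' @param max_iter maximum EM sweeps.
#' @param tol stop when the total objective improves by less than this.
#' @param n_restarts optimizer restarts per session on the first sweep
#'   (warm starts are used afterwards).
#' @param restart_sd standard deviation of the unconstrained-scale jitter
#'   applied to restart starting points.
#' @param optim_maxit iteration cap for each L-BFGS-B run.
#' @param seed master seed; per-session, per-restart seeds are derived from
#'   it by a counter scheme.
#' @return named list.
#' @export
em_control <- function(max_iter = 200L, tol = 1e-3, n_restarts = 3L,
                       restart_sd = 0.5, optim_maxit = 100L, seed = 1L) {
  list(max_iter = as.integer(max_iter), tol = tol,
       n_restarts = as.integer(n_restarts), restart_sd = restart_sd,
       optim_maxit = as.integer(optim_maxit), seed = as.integer(seed))
}

# negative log posterior (including the Gaussian normalizer, so the Laplace
# marginal can be read off directly) on the unconstrained scale. Index
# positions and transform masks are resolved once so the closure stays cheap
# inside finite-difference loops.
make_nlpost <- function(spec, sess, prior_mean) {
  k <- length(prior_mean)
  const <- 0.5 * k * log(2 * pi)
  cache <- new.env(parent = emptyenv())
  nm <- spec$params$name
  is_logit <- spec$params$transform == "logit"
  is_log <- spec$params$transform == "log"
  i_targets <- match(paste0("target", 2:15), nm)
  scalars <- c("mu0", "beta_trial", "beta_ntrials", "beta_lag10",
               "shift_frac", "sigma", "beta_W", "alpha_W", "beta_A",
               "alpha_A", "gamma", "lambda")
  i_scalar <- match(scalars, nm)
  present <- !is.na(i_scalar)
  lambda_pin <- if (spec$higher == 2L && !("lambda" %in% nm)) {
    if (spec$lambda_fixed >= 1) LAMBDA_PIN_HIGH else max(spec$lambda_fixed, 0)
  } else {
    NULL
  }
  function(theta) {
    nat <- theta
    nat[is_logit] <- plogis(theta[is_logit])
    nat[is_log] <- exp(theta[is_log])
    pl <- setNames(as.list(nat[i_scalar[present]]), scalars[present])
    pl$target_offsets2_15 <- nat[i_targets]
    if (!is.null(lambda_pin)) pl$lambda <- lambda_pin
    nll <- session_negloglik(spec, pl, sess, cache)
    v <- nll + const + 0.5 * sum((theta - prior_mean)^2)
    if (!is.finite(v)) 1e10 else v
  }
}

# Profiled negative log posterior: conditional on the nonlinear parameters
# (learning rates, discount, trace decay, shift fraction, sigma) the RT model
# is linear-Gaussian in the regression weights, whose MAP under the identity
# Gaussian prior is a ridge solve. The outer optimizer then works in ~6
# dimensions instead of ~26, which matters because gamma and beta_A trade off
# along a curved ridge that defeats slow coordinate-wise progress.
make_profiled_nlpost <- function(spec, sess, prior_mean) {
  nm <- spec$params$name
  lin_names <- c("mu0", "beta_trial", paste0("target", 2:15),
                 "beta_ntrials", "beta_lag10",
                 intersect(c("beta_W", "beta_A"), nm))
  i_lin <- match(lin_names, nm)
  i_nl <- setdiff(seq_along(nm), i_lin)
  nl_names <- nm[i_nl]
  is_logit_nl <- spec$params$transform[i_nl] == "logit"
  is_log_nl <- spec$params$transform[i_nl] == "log"
  k <- length(nm)
  const <- 0.5 * k * log(2 * pi)
  lambda_pin <- if (spec$higher == 2L && !("lambda" %in% nm)) {
    if (spec$lambda_fixed >= 1) LAMBDA_PIN_HIGH else max(spec$lambda_fixed, 0)
  } else {
    NULL
  }

  n_inc <- length(sess$inc_idx)
  # fixed design columns: intercept, trial, 14 target dummies, two nuisances
  tgt <- matrix(0, n_inc, 14)
  hit <- sess$target_inc >= 2
  tgt[cbind(which(hit), sess$target_inc[hit] - 1L)] <- 1
  X_fixed <- cbind(1, sess$trial_scaled_inc, tgt, sess$r_ntrials_inc,
                   sess$r_lag10_inc)
  cache <- new.env(parent = emptyenv())
  m_lin <- prior_mean[i_lin]
  m_nl <- prior_mean[i_nl]

  design <- function(nat) {
    X <- X_fixed
    if (spec$use_recency) {
      W <- cached_predictor(cache, "W", nat[["alpha_W"]], function() {
        recency_predictors_cpp(sess$nodes0, sess$n_states,
                               nat[["alpha_W"]])[sess$inc_idx]
      })
      X <- cbind(X, W)
    }
    if (spec$higher == 1L) {
      A <- cached_predictor(cache, "A", nat[["alpha_A"]], function() {
        onestep_predictors_cpp(sess$nodes0, sess$n_states,
                               nat[["alpha_A"]])[sess$inc_idx]
      })
      X <- cbind(X, A)
    } else if (spec$higher == 2L) {
      lam <- if (is.null(lambda_pin)) nat[["lambda"]] else lambda_pin
      key <- c(nat[["alpha_A"]], nat[["gamma"]], lam)
      A <- cached_predictor(cache, "A", key, function() {
        srtd_run_cpp(sess$nodes0, sess$n_states, nat[["alpha_A"]],
                     nat[["gamma"]], lam)$pred[sess$inc_idx]
      })
      X <- cbind(X, A)
    } else if (spec$higher == 3L) {
      A <- cached_predictor(cache, "A", nat[["gamma"]], function() {
        M <- sr_closed_form(sess$emp_T, nat[["gamma"]])
        rs <- rowSums(M)
        prev <- sess$nodes[sess$inc_idx - 1L]
        M[cbind(prev, sess$nodes[sess$inc_idx])] / rs[prev]
      })
      X <- cbind(X, A)
    }
    X
  }

  value_and_lin <- function(theta_nl) {
    nat <- theta_nl
    nat[is_logit_nl] <- plogis(theta_nl[is_logit_nl])
    nat[is_log_nl] <- exp(theta_nl[is_log_nl])
    names(nat) <- nl_names
    sigma <- nat[["sigma"]]
    x <- sess$rt_inc - nat[["shift_frac"]] * sess$min_rt
    if (any(x <= 0) || sigma <= 0) return(list(value = 1e10))
    y <- log(x)
    X <- design(nat)
    key_X <- nat[setdiff(nl_names, c("sigma", "shift_frac"))]
    XtX <- cached_predictor(cache, "XtX", key_X, function() crossprod(X))
    b <- tryCatch(
      solve(XtX / sigma^2 + diag(ncol(X)),
            crossprod(X, y) / sigma^2 + m_lin),
      error = function(e) NULL
    )
    if (is.null(b)) return(list(value = 1e10))
    r <- y - drop(X %*% b)
    nll <- n_inc * (0.5 * log(2 * pi) + log(sigma)) +
      0.5 * sum(r * r) / sigma^2 + sum(y)
    v <- nll + const + 0.5 * sum((drop(b) - m_lin)^2) +
      0.5 * sum((theta_nl - m_nl)^2)
    if (!is.finite(v)) return(list(value = 1e10))
    list(value = v, lin = drop(b))
  }

  list(
    fn = function(theta_nl) value_and_lin(theta_nl)$value,
    value_and_lin = value_and_lin,
    i_lin = i_lin, i_nl = i_nl, nl_names = nl_names
  )
}

#' MAP estimate of one session's parameters
#'
#' Maximizes the session log-likelihood plus the log of a Gaussian prior
#' with identity covariance on the unconstrained scale. Conditional on the
#' nonlinear parameters the regression weights have a closed-form ridge
#' solution, so the numerical optimizer (quasi-Newton with numerical
#' gradients and multiple seeded restarts — the profiled surface still has
#' plateaus in gamma and lambda) runs on the nonlinear block only.
#'
#' @param table single-session trial table or prepared session.
#' @param model model name or specification.
#' @param prior_mean named unconstrained-scale prior mean (defaults to the
#'   transformed [default_start()]).
#' @param control see [em_control()].
#' @param start optional warm-start vector; when given, restarts are
#'   jittered around it instead of the prior mean.
#' @param config analysis configuration.
#' @return list with `par` (unconstrained MAP), `value` (negative log
#'   posterior at the MAP, Gaussian normalizer included), `converged`, and
#'   `spec`.
#' @export
map_estimate_subject <- function(table, model, prior_mean = NULL,
                                 control = em_control(), start = NULL,
                                 config = default_run_config()) {
  spec <- as_model_spec(model)
  sess <- if (is.data.frame(table)) prep_session(table, config = config) else table
  if (is.null(prior_mean)) {
    prior_mean <- transform_params(spec, default_start(spec))
  }
  prof <- make_profiled_nlpost(spec, sess, prior_mean)
  base <- if (is.null(start)) prior_mean[prof$i_nl] else start[prof$i_nl]
  starts <- list(base)
  for (r in seq_len(max(0L, control$n_restarts - 1L))) {
    starts[[r + 1L]] <- base + with_seed(
      control$seed + 7919L * r,
      rnorm(length(base), sd = control$restart_sd)
    )
  }
  best <- NULL
  for (s0 in starts) {
    opt <- tryCatch(
      optim(s0, prof$fn, method = "L-BFGS-B",
            control = list(maxit = control$optim_maxit)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  sol <- prof$value_and_lin(best$par)
  par <- prior_mean
  par[prof$i_nl] <- best$par
  par[prof$i_lin] <- sol$lin
  list(par = setNames(par, names(prior_mean)), value = best$value,
       converged = best$convergence == 0, spec = spec)
}

#' Laplace approximation to a session's negative log marginal likelihood
#'
#' With `h(theta)` the negative log posterior (negative log-likelihood
#' minus log prior, Gaussian normalizers included) minimized at `theta_hat`
#' with Hessian `H`:
#' `-log p(data) ~ h(theta_hat) - (k/2) log(2 pi) + 0.5 log det H`.
#' Non-positive-definite Hessians are repaired to the nearest positive
#' definite matrix (eigenvalue clamping) with a warning.
#'
#' @param fit a MAP fit ([map_estimate_subject()]) — a list with `par` and
#'   `value`.
#' @param hessian Hessian of the negative log posterior at the MAP.
#' @return scalar negative log marginal likelihood.
#' @export
laplace_marginal <- function(fit, hessian) {
  k <- length(fit$par)
  hessian <- (hessian + t(hessian)) / 2
  ev <- eigen(hessian, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    warning("Hessian not positive definite; clamping eigenvalues")
    eg <- eigen(hessian, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-8)
    hessian <- eg$vectors %*% (ev * t(eg$vectors))
  }
  fit$value - 0.5 * k * log(2 * pi) +
    0.5 * sum(log(eigen(hessian, symmetric = TRUE, only.values = TRUE)$values))
}

#' Hierarchical EM fit of one model to many sessions
#'
#' Alternates per-session MAP estimation under a Gaussian prior with
#' identity covariance (E-like step) with closed-form updates of the group
#' means and stage-difference coefficients by least squares of the MAP
#' estimates on the stage covariate (M step). The stage covariate is -1 for
#' first-stage sessions and +1 for second-stage sessions; stage
#' coefficients are estimated only when both levels are present. The total
#' penalized MAP objective is monitored for convergence; Laplace marginal
#' likelihoods are computed at the final iterate.
#'
#' @param tables a trial table (split into sessions by subject and stage)
#'   or a list of prepared sessions.
#' @param model model name or specification.
#' @param control see [em_control()].
#' @param config analysis configuration.
#' @param verbose print per-iteration objective.
#' @return an object of class `srtrace_fit`: list with `spec`, `group`
#'   (unconstrained `means`, `stage_coefs`, and natural-scale
#'   `natural_means`), `subjects` (tibble with per-session MAP summary,
#'   negative log marginal likelihoods and convergence flags), `maps`
#'   (sessions x parameters matrix), `n_group_params`, `objective_trace`.
#' @export
em_fit <- function(tables, model, control = em_control(),
                   config = default_run_config(), verbose = FALSE) {
  spec <- as_model_spec(model)
  sessions <- if (is.data.frame(tables)) {
    lapply(split_sessions(tables), prep_session, config = config)
  } else {
    tables
  }
  stopifnot(length(sessions) >= 2)
  covariate <- vapply(sessions, function(s) as.numeric(s$stage), 0)
  stopifnot(all(covariate %in% c(-1, 1)))
  k <- nrow(spec$params)
  two_level <- length(unique(covariate)) == 2L

  start_nat <- default_start(spec)
  # data-driven location/scale starting values stabilize the first sweep
  lrt <- unlist(lapply(sessions, function(s) log(pmax(s$rt[s$include], 1))))
  if (length(lrt) > 10) {
    start_nat["mu0"] <- mean(lrt)
    start_nat["sigma"] <- max(0.05, sd(lrt))
  }
  means <- transform_params(spec, start_nat)
  coefs <- setNames(rep(0, k), names(means))

  maps <- matrix(NA_real_, length(sessions), k,
                 dimnames = list(names(sessions), names(means)))
  values <- rep(NA_real_, length(sessions))
  conv <- rep(NA, length(sessions))
  trace <- numeric(0)
  prev_total <- Inf
  for (iter in seq_len(control$max_iter)) {
    for (i in seq_along(sessions)) {
      prior_mean <- means + coefs * covariate[i]
      ctl <- control
      ctl$seed <- control$seed + 131L * i + iter
      if (iter > 1L) ctl$n_restarts <- 1L
      fit <- map_estimate_subject(
        sessions[[i]], spec, prior_mean, ctl,
        start = if (iter > 1L) maps[i, ] else NULL
      )
      maps[i, ] <- fit$par
      values[i] <- fit$value
      conv[i] <- fit$converged
    }
    if (two_level) {
      m_hi <- colMeans(maps[covariate > 0, , drop = FALSE])
      m_lo <- colMeans(maps[covariate < 0, , drop = FALSE])
      means <- (m_hi + m_lo) / 2
      coefs <- (m_hi - m_lo) / 2
    } else {
      means <- colMeans(maps)
    }
    total <- sum(values)
    trace <- c(trace, total)
    if (verbose) message(sprintf("EM iter %d: objective %.3f", iter, total))
    if (prev_total - total < control$tol) break
    prev_total <- total
  }

  marginals <- rep(NA_real_, length(sessions))
  for (i in seq_along(sessions)) {
    prior_mean <- means + coefs * covariate[i]
    f <- make_nlpost(spec, sessions[[i]], prior_mean)
    H <- pracma::hessian(f, maps[i, ])
    marginals[i] <- laplace_marginal(
      list(par = maps[i, ], value = f(maps[i, ])), H
    )
  }

  structure(
    list(
      spec = spec,
      group = list(
        means = means, stage_coefs = coefs,
        natural_means = untransform_params(spec, means)
      ),
      subjects = tibble::tibble(
        session = names(sessions),
        subject = vapply(sessions, function(s) as.character(s$subject), ""),
        stage = covariate,
        neg_log_marginal = marginals,
        nlpost = values,
        converged = conv
      ),
      maps = maps,
      n_group_params = if (two_level) 2L * k else k,
      objective_trace = trace,
      control = control
    ),
    class = "srtrace_fit"
  )
}

#' @export
print.srtrace_fit <- function(x, ...) {
  cat(sprintf(
    "<srtrace_fit: model '%s', %d sessions, %d EM sweeps, objective %.2f>\n",
    x$spec$name, nrow(x$subjects), length(x$objective_trace),
    tail(x$objective_trace, 1)
  ))
  invisible(x)
}

#' AIC-penalized per-session model scores
#'
#' The score of a session is its Laplace negative log marginal likelihood
#' plus an AIC penalty of one nat per group-level parameter (means and any
#' stage coefficients), divided equally across sessions. Lower is better.
#'
#' @param fit an `srtrace_fit`.
#' @param n_group_params override for the group-parameter count (defaults
#'   to the fit's own).
#' @return tibble with `session`, `subject`, `stage`, `score`; the shared
#'   penalty is attached as attribute `group_penalty`.
#' @export
model_score <- function(fit, n_group_params = NULL) {
  if (is.null(n_group_params)) n_group_params <- fit$n_group_params
  n <- nrow(fit$subjects)
  out <- fit$subjects[c("session", "subject", "stage")]
  out$score <- fit$subjects$neg_log_marginal + n_group_params / n
  attr(out, "group_penalty") <- n_group_params
  out
}

#' Paired comparison of two models' scores
#'
#' One-sided paired t-test on per-session score differences
#' (`a - b`; with `alternative = "less"` the test is that model `a` scores
#' lower, i.e. fits better). Zero-variance differences are flagged as
#' degenerate rather than erroring.
#'
#' @param scores_a,scores_b numeric score vectors (same sessions, same
#'   order) or [model_score()] tibbles.
#' @param alternative `"less"`, `"greater"`, or `"two.sided"`.
#' @return list with `t`, `dof`, `p`, `ci` (95% CI of the mean
#'   difference), `mean_diff`, and `degenerate`.
#' @export
compare_models <- function(scores_a, scores_b, alternative = "less") {
  if (is.data.frame(scores_a)) scores_a <- scores_a$score
  if (is.data.frame(scores_b)) scores_b <- scores_b$score
  stopifnot(length(scores_a) == length(scores_b))
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    return(list(t = 0, dof = length(d) - 1L,
                p = if (alternative == "two.sided") 1 else 0.5,
                ci = c(mean(d), mean(d)), mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE, alternative = alternative)
  ci <- t.test(scores_a, scores_b, paired = TRUE)$conf.int
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, ci = as.numeric(ci), mean_diff = mean(d),
       degenerate = FALSE)
}

#' Tidy table of fitted parameters
#'
#' @param fit an `srtrace_fit`.
#' @return tibble with one row per session and parameter: `session`,
#'   `subject`, `stage`, `model`, `parameter`, `unconstrained`, `natural`.
#' @export
fit_parameters_table <- function(fit) {
  spec <- fit$spec
  rows <- lapply(seq_len(nrow(fit$maps)), function(i) {
    nat <- untransform_params(spec, fit$maps[i, ])
    tibble::tibble(
      session = fit$subjects$session[i],
      subject = fit$subjects$subject[i],
      stage = fit$subjects$stage[i],
      model = spec$name,
      parameter = spec$params$name,
      unconstrained = unname(fit$maps[i, ]),
      natural = unname(nat)
    )
  })
  dplyr::bind_rows(rows)
}
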