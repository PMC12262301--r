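#' Find trace-signature windows in a node sequence
#'
#' Scans every 5-trial window `(a, b, c, d, e)`. A *trace* window
#' (`S X T S T`) has `a = d` (the source S), `c = e` (the target T), with
#' S, X (= `b`) and T pairwise distinct: the initial `S X T` lets a trace
#' learner strengthen the S -> T expectation even though X intervened, and
#' the final T reads it out on the second S -> T transition. A *control*
#' window (`X1 X2 T S T`) has `c = e` and the test S (= `d`) appearing for
#' the first time in the window (`d` distinct from `a`, `b` and `c`), so
#' recency of T is matched but no trace update for S -> T could have
#' occurred. Trace and control sets are disjoint by construction.
#'
#' @param nodes integer vector of node ids.
#' @return tibble with `kind` (`"trace"` / `"trace_control"`), `start`,
#'   and `final` (index of the terminal T, whose RT is the readout).
#' @export
find_trace_sequences <- function(nodes) {
  n <- length(nodes)
  if (n < 5) {
    return(tibble::tibble(kind = character(), start = integer(),
                          final = integer()))
  }
  t0 <- seq_len(n - 4L)
  a <- nodes[t0]; b <- nodes[t0 + 1L]; c <- nodes[t0 + 2L]
  d <- nodes[t0 + 3L]; e <- nodes[t0 + 4L]
  trace <- a == d & c == e & a != b & b != c & a != c
  ctrl <- c == e & d != a & d != b & d != c
  tibble::tibble(
    kind = c(rep("trace", sum(trace)), rep("trace_control", sum(ctrl))),
    start = c(t0[trace], t0[ctrl]),
    final = start + 4L
  )
}

#' Find bootstrap-signature windows in a node sequence
#'
#' Scans every 6-trial window `(a, b, c, d, e, f)`. A *bootstrap* window
#' (`B T S B S T`) has `a = d` (= B), `b = f` (= T), `c = e` (= S) with B,
#' T, S pairwise distinct: the initial `B T` strengthens T-from-B, the
#' later `S B` lets a bootstrapping learner chain that prediction back to
#' S, and the final `S T` reads it out. The *control* (`X T S B S T`)
#' replaces the initial B by an X outside \{B, T, S\}, so no such chain
#' could have been seeded. Bootstrap and control sets are disjoint.
#'
#' @param nodes integer vector of node ids.
#' @return tibble with `kind` (`"bootstrap"` / `"bootstrap_control"`),
#'   `start`, and `final`.
#' @export
find_bootstrap_sequences <- function(nodes) {
  n <- length(nodes)
  if (n < 6) {
    return(tibble::tibble(kind = character(), start = integer(),
                          final = integer()))
  }
  t0 <- seq_len(n - 5L)
  a <- nodes[t0]; b <- nodes[t0 + 1L]; c <- nodes[t0 + 2L]
  d <- nodes[t0 + 3L]; e <- nodes[t0 + 4L]; f <- nodes[t0 + 5L]
  distinct <- d != b & d != c & b != c
  boot <- a == d & b == f & c == e & distinct
  ctrl <- b == f & c == e & distinct & a != d & a != b & a != c
  tibble::tibble(
    kind = c(rep("bootstrap", sum(boot)), rep("bootstrap_control", sum(ctrl))),
    start = c(t0[boot], t0[ctrl]),
    final = start + 5L
  )
}

#' Collect signature matches with final-element RTs across sessions
#'
#' Runs the pattern finders on every session of a trial table and returns
#' matches whose final element passes the usual exclusion filters (correct
#' response, RT at or above the plausibility floor).
#'
#' @param table a trial table (any number of sessions).
#' @param which `"trace"` or `"bootstrap"`.
#' @param config analysis configuration.
#' @return tibble with `subject`, `stage`, `kind`, `final_trial_index`,
#'   `rt_ms`, `target`.
#' @export
signature_matches <- function(table, which = c("trace", "bootstrap"),
                              config = default_run_config()) {
  which <- match.arg(which)
  finder <- if (which == "trace") find_trace_sequences else find_bootstrap_sequences
  out <- lapply(split_sessions(table), function(sess) {
    m <- finder(sess$node)
    if (!nrow(m)) return(NULL)
    ok <- sess$correct[m$final] & sess$rt_ms[m$final] >= config$min_rt_ms
    tibble::tibble(
      subject = sess$subject[1], stage = sess$stage[1],
      kind = m$kind[ok], final_trial_index = m$final[ok],
      rt_ms = sess$rt_ms[m$final][ok], target = sess$target[m$final][ok]
    )
  })
  dplyr::bind_rows(out)
}

#' Mixed-effects estimate of a sequence-signature effect
#'
#' Fits final-element RT (ms) on the condition indicator (1 = signature
#' window, 0 = recency-matched control) plus motor-target fixed effects,
#' with correlated random intercept and condition slope per subject (and
#' per graph instance when a `graphset` column with several levels is
#' present). A negative coefficient means faster responses in the
#' signature condition, i.e. evidence for the corresponding update rule.
#' If the random-effects fit fails, falls back to per-subject mean
#' differences and a one-sample t-test, with the fallback recorded.
#'
#' @param matches a [signature_matches()] tibble.
#' @param kind `"trace"` or `"bootstrap"` (which indicator to build).
#' @return list with `estimate_ms`, `se`, `stat`, `p`, `n_signature`,
#'   `n_control`, `method`.
#' @export
signature_effect <- function(matches, kind = c("trace", "bootstrap")) {
  kind <- match.arg(kind)
  matches$is_sig <- as.numeric(matches$kind == kind)
  if (length(unique(matches$is_sig)) < 2) {
    stop("both the signature and control conditions must be present")
  }
  form <- rt_ms ~ is_sig + (1 + is_sig | subject)
  if ("graphset" %in% names(matches) &&
      length(unique(matches$graphset)) > 1) {
    form <- stats::update(form, . ~ . + (1 + is_sig | graphset))
  }
  if (length(unique(matches$target)) > 1) {
    matches$target <- factor(matches$target)
    form <- stats::update(form, . ~ . + target)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = matches,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  n_sig <- sum(matches$is_sig == 1)
  n_ctl <- sum(matches$is_sig == 0)
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    row <- cf["is_sig", ]
    return(list(estimate_ms = unname(row["Estimate"]),
                se = unname(row["Std. Error"]),
                stat = unname(row["t value"]),
                p = unname(row["Pr(>|t|)"]),
                n_signature = n_sig, n_control = n_ctl,
                method = "lmer"))
  }
  by_subj <- tapply(seq_len(nrow(matches)), matches$subject, function(ix) {
    x <- matches[ix, ]
    mean(x$rt_ms[x$is_sig == 1]) - mean(x$rt_ms[x$is_sig == 0])
  })
  d <- by_subj[is.finite(by_subj)]
  tt <- t.test(d)
  list(estimate_ms = mean(d), se = sd(d) / sqrt(length(d)),
       stat = unname(tt$statistic), p = tt$p.value,
       n_signature = n_sig, n_control = n_ctl,
       method = "paired_means_fallback")
}

#' Residual log RTs under the nuisance-only model
#'
#' Fits, per session, an ordinary least-squares model of
#' `log(rt - shift)` on the rescaled trial index and motor-target factor
#' (no predictors of upcoming nodes; shift fixed at half the session's
#' minimum observed RT), over the usual included trials, and returns the
#' residuals.
#'
#' @param table a trial table.
#' @param config analysis configuration.
#' @return tibble with `subject`, `stage`, `trial`, `node`, `resid`.
#' @export
residualize_rts <- function(table, config = default_run_config()) {
  out <- lapply(split_sessions(table), function(sess) {
    s <- prep_session(sess, config = config)
    idx <- which(s$include)
    df <- data.frame(
      y = log(s$rt[idx] - 0.5 * s$min_rt),
      trial_scaled = s$trial_scaled[idx],
      target = factor(s$target[idx])
    )
    fit <- if (nlevels(df$target) > 1) {
      lm(y ~ trial_scaled + target, data = df)
    } else {
      lm(y ~ trial_scaled, data = df)
    }
    tibble::tibble(
      subject = sess$subject[1], stage = sess$stage[1],
      trial = sess$trial[idx], node = s$nodes[idx],
      resid = unname(stats::residuals(fit))
    )
  })
  dplyr::bind_rows(out)
}

#' First- versus second-trial contrast on cluster entry
#'
#' On the modular graph the SR predicts cross-cluster transitions weakly,
#' but once a new cluster is entered it immediately favours that cluster's
#' nodes — so the second trial inside a new cluster should be faster than
#' the first, a contrast a pure recency learner does not produce. Fits a
#' linear mixed model of residual log RT ([residualize_rts()]) on
#' `cluster_step` (0 = first trial in the new cluster, 1 = second) and the
#' trials-since-this-node-was-seen lag as an effects-coded categorical
#' control (lags capped at 100), with random intercept and `cluster_step`
#' slope per subject.
#'
#' @param table a trial table generated on a modular graph.
#' @param graph the modular `walk_graph` (cluster labels are required).
#' @param config analysis configuration.
#' @return list with `estimate`, `se`, `stat`, `p`, `n_first`, `n_second`,
#'   `method`.
#' @export
cluster_entry_analysis <- function(table, graph,
                                   config = default_run_config()) {
  if (is.null(graph$cluster_of)) {
    stop("cluster labels required: cluster-entry analysis needs a modular graph")
  }
  resid <- residualize_rts(table, config)
  rows <- lapply(split_sessions(table), function(sess) {
    nodes <- sess$node
    cl <- graph$cluster_of[nodes]
    entry <- c(FALSE, cl[-1] != cl[-length(cl)])
    first <- which(entry)
    second <- first + 1L
    second <- second[second <= length(nodes) & !entry[pmin(second, length(nodes))]]
    nuis <- nuisance_regressors(nodes, cap = config$ntrials_cap,
                                window = config$lag_window)
    mk <- function(idx, step) tibble::tibble(
      subject = sess$subject[1], stage = sess$stage[1],
      trial = sess$trial[idx], cluster_step = step,
      time_since_node = pmin(nuis$r_ntrials[idx], config$ntrials_cap)
    )
    dplyr::bind_rows(mk(first, 0), mk(second, 1))
  })
  df <- dplyr::inner_join(dplyr::bind_rows(rows), resid,
                          by = c("subject", "stage", "trial"))
  if (!nrow(df)) stop("no cluster-entry trials available after exclusions")
  df$lag <- factor(df$time_since_node)
  contrasts(df$lag) <- contr.sum(nlevels(df$lag))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(resid ~ lag + cluster_step + (1 + cluster_step | subject),
                     data = df,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    row <- summary(fit)$coefficients["cluster_step", ]
    return(list(estimate = unname(row["Estimate"]),
                se = unname(row["Std. Error"]),
                stat = unname(row["t value"]), p = unname(row["Pr(>|t|)"]),
                n_first = sum(df$cluster_step == 0),
                n_second = sum(df$cluster_step == 1), method = "lmer"))
  }
  ols <- lm(resid ~ lag + cluster_step, data = df)
  cf <- summary(ols)$coefficients["cluster_step", ]
  list(estimate = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       stat = unname(cf["t value"]), p = unname(cf["Pr(>|t|)"]),
       n_first = sum(df$cluster_step == 0),
       n_second = sum(df$cluster_step == 1), method = "ols_fallback")
}
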