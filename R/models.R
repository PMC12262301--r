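#' Model specifications
#'
#' The model family is a single linear RT model (see [predicted_mu()]) whose
#' predictor terms are switched on or off:
#'
#' * `baseline` — trial, motor target and recency nuisance regressors only
#'   (no prediction of upcoming nodes).
#' * `recency` — adds the recency node-frequency predictor `W`.
#' * `onestep` — adds the learned one-step transition predictor `T`.
#' * `srtd` — adds the SR-TD(lambda) predictor (row-normalized `M`).
#' * `static_sr` — adds the non-learning SR computed from the empirical
#'   transition matrix of the whole sequence.
#' * `recency_onestep`, `recency_srtd` — combined models learning recency
#'   alongside a higher-order model, with separate learning rates and betas.
#'
#' Every model also fits `mu0`, `beta_trial`, 14 motor-target offsets
#' (code 1 is the reference), `beta_ntrials`, `beta_lag10`, `shift_frac`
#' (logit scale) and `sigma` (log scale). `lambda_fixed` produces reduced
#' SR-TD variants with lambda pinned (a value of 1 is held at 0.999999
#' internally so the transform stays finite).
#'
#' @param name model name (see above).
#' @param lambda_fixed `NA` (lambda free) or a value in \[0, 1\] at which
#'   lambda is pinned (SR-TD models only).
#' @return an object of class `srtrace_model`: list with `name`,
#'   `use_recency`, `higher` (0 none / 1 one-step / 2 SR-TD / 3 static SR),
#'   `lambda_fixed`, and `params` (tibble of subject-level parameter names
#'   and transforms).
#' @export
model_spec <- function(name, lambda_fixed = NA_real_) {
  defs <- list(
    baseline        = list(use_recency = FALSE, higher = 0L),
    recency         = list(use_recency = TRUE,  higher = 0L),
    onestep         = list(use_recency = FALSE, higher = 1L),
    srtd            = list(use_recency = FALSE, higher = 2L),
    static_sr       = list(use_recency = FALSE, higher = 3L),
    recency_onestep = list(use_recency = TRUE,  higher = 1L),
    recency_srtd    = list(use_recency = TRUE,  higher = 2L)
  )
  if (!name %in% names(defs)) {
    stop("unknown model: ", name, " (see ?model_spec)")
  }
  d <- defs[[name]]
  if (!is.na(lambda_fixed) && d$higher != 2L) {
    stop("lambda_fixed applies only to SR-TD models")
  }
  par <- c("mu0", "beta_trial", paste0("target", 2:15),
           "beta_ntrials", "beta_lag10", "shift_frac", "sigma")
  tr <- c(rep("identity", 18), "logit", "log")
  if (d$use_recency) {
    par <- c(par, "beta_W", "alpha_W"); tr <- c(tr, "identity", "logit")
  }
  if (d$higher %in% c(1L, 2L)) {
    par <- c(par, "beta_A", "alpha_A"); tr <- c(tr, "identity", "logit")
  }
  if (d$higher == 2L) {
    par <- c(par, "gamma"); tr <- c(tr, "logit")
    if (is.na(lambda_fixed)) {
      par <- c(par, "lambda"); tr <- c(tr, "logit")
    }
  }
  if (d$higher == 3L) {
    par <- c(par, "beta_A", "gamma"); tr <- c(tr, "identity", "logit")
  }
  nm <- name
  if (!is.na(lambda_fixed)) nm <- sprintf("%s_lam%g", name, lambda_fixed)
  structure(
    list(name = nm, base_name = name, use_recency = d$use_recency,
         higher = d$higher, lambda_fixed = lambda_fixed,
         params = tibble::tibble(name = par, transform = tr)),
    class = "srtrace_model"
  )
}

as_model_spec <- function(model) {
  if (inherits(model, "srtrace_model")) model else model_spec(model)
}

#' @export
print.srtrace_model <- function(x, ...) {
  cat(sprintf("<srtrace model '%s': %d subject-level parameters>\n",
              x$name, nrow(x$params)))
  invisible(x)
}

#' Names of the available models
#' @return character vector of model names accepted by [model_spec()].
#' @export
list_models <- function() {
  c("baseline", "recency", "onestep", "srtd", "static_sr",
    "recency_onestep", "recency_srtd")
}

# --- parameter transforms ----------------------------------------------------

LOGIT_EPS <- 1e-6
LAMBDA_PIN_HIGH <- 0.999999 # lambda "fixed at 1" is held just inside (0,1)

#' Map parameters between natural and unconstrained scales
#'
#' Rates and fractions (`alpha`, `gamma`, `lambda`, `shift_frac`) live in
#' (0, 1) and are logit-transformed; `sigma` is log-transformed; location
#' and slope parameters are unconstrained. Boundary values are clamped just
#' inside the open interval with a warning.
#'
#' @param spec a model specification ([model_spec()]).
#' @param natural named numeric vector on the natural scale.
#' @return `transform_params`: named vector on the unconstrained scale;
#'   `untransform_params`: named vector on the natural scale.
#' @export
transform_params <- function(spec, natural) {
  natural <- natural[spec$params$name]
  out <- natural
  for (k in seq_len(nrow(spec$params))) {
    tr <- spec$params$transform[k]
    x <- natural[k]
    if (tr == "logit") {
      if (x <= 0 || x >= 1) {
        warning("clamping boundary value of ", spec$params$name[k])
        x <- min(max(x, LOGIT_EPS), 1 - LOGIT_EPS)
      }
      out[k] <- qlogis(x)
    } else if (tr == "log") {
      out[k] <- log(x)
    }
  }
  out
}

#' @rdname transform_params
#' @param unconstrained named numeric vector on the unconstrained scale.
#' @export
untransform_params <- function(spec, unconstrained) {
  out <- unconstrained
  for (k in seq_len(nrow(spec$params))) {
    tr <- spec$params$transform[k]
    if (tr == "logit") out[k] <- plogis(unconstrained[k])
    if (tr == "log") out[k] <- exp(unconstrained[k])
  }
  names(out) <- spec$params$name
  out
}

# natural-scale named vector -> list form consumed by the likelihood
params_to_list <- function(spec, natural) {
  p <- as.list(natural)
  out <- list(
    mu0 = p$mu0, beta_trial = p$beta_trial,
    target_offsets2_15 = unlist(p[paste0("target", 2:15)], use.names = FALSE),
    beta_ntrials = p$beta_ntrials, beta_lag10 = p$beta_lag10,
    shift_frac = p$shift_frac, sigma = p$sigma
  )
  for (nm in c("beta_W", "alpha_W", "beta_A", "alpha_A", "gamma", "lambda")) {
    if (!is.null(p[[nm]])) out[[nm]] <- p[[nm]]
  }
  if (spec$higher == 2L && is.null(out$lambda)) {
    lf <- spec$lambda_fixed
    out$lambda <- if (lf >= 1) LAMBDA_PIN_HIGH else max(lf, 0)
  }
  out
}

#' Default natural-scale starting parameters for a model
#'
#' Generic mid-range values used to initialize group means before the first
#' EM sweep: baseline log-RT near log(400 ms), moderate log-scale noise,
#' zero betas, mid-range learning rates and discount.
#'
#' @param spec a model specification.
#' @return named numeric vector on the natural scale.
#' @export
default_start <- function(spec) {
  vals <- c(
    mu0 = log(400), beta_trial = 0,
    setNames(rep(0, 14), paste0("target", 2:15)),
    beta_ntrials = 0, beta_lag10 = 0, shift_frac = 0.3, sigma = 0.3,
    beta_W = 0, alpha_W = 0.2, beta_A = 0, alpha_A = 0.2,
    gamma = 0.5, lambda = 0.5
  )
  vals[spec$params$name]
}
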