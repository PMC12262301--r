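---
title: "Modelling trial-by-trial successor-representation learning from reaction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial successor-representation learning from reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In graph sequence-learning tasks, people respond to a stream of stimuli
generated by a random walk on a hidden graph, and their reaction times (RTs)
speed up for transitions they have come to expect. Those expectancies are not
only one-step-ahead: RTs also reflect multi-step structure (for example,
slowing at transitions between graph clusters even though one-step
probabilities are matched), consistent with a successor representation (SR) —
a matrix `M` of temporally discounted expected future state occupancy. The
question this package is built around is *how such a long-run predictive
representation is learned trial by trial*: by chaining one-step bootstrap
backups (TD(0)), by eligibility traces that broadcast each observation to
recently visited states (TD(1), approximately Hebbian), or a mixture
(TD(lambda)).

`srtrace` provides the full workflow needed to study this with synthetic
data: the three 15-node, degree-4 graph environments (modular, ring lattice,
random regular), the family of trial-by-trial learners, a shifted log-normal
RT likelihood, hierarchical EM fitting with Laplace-approximated marginal
likelihoods, AIC-penalized model comparison, and two model-agnostic sequence
signature analyses.

## Learners

All learners run over the node sequence of a session, updating on *every*
trial (error and implausibly fast trials are excluded only from the
likelihood: the stimulus was still seen).

* **Recency** (`W`, learning rate `alpha_W`): an unconditional
  recency-weighted node-frequency vector,
  `W <- (1 - alpha) W + alpha onehot(s)`, initialized uniform. Its
  predictor for trial `t` is `W[s_t]`.
* **One-step** (`T`, `alpha_A`): a learned conditional transition matrix;
  only the predecessor row is decayed and incremented, so rows stay
  stochastic. Predictor: `T[s_prev, s_t]`.
* **SR-TD(lambda)** (`M`, `e`; `alpha_A`, `gamma`, `lambda`): temporal
  difference learning of the one-step-ahead SR
  `M = T + gamma T^2 + gamma^2 T^3 + ... = T (I - gamma T)^{-1}`. Each
  transition executes, in order: a *dutch* trace increment
  `e[s_prev] <- (1 - alpha) e[s_prev] + 1`; the TD error
  `delta = onehot(s) + gamma M[s, ] - M[s_prev, ]`; the sweep
  `M[k, ] <- M[k, ] + alpha e[k] delta` over all states; and the decay
  `e <- gamma lambda e`. With `lambda = 0` only the predecessor row is
  updated (pure bootstrapping); with `lambda = 1` successive bootstrap terms
  cancel (the trace decays by exactly `gamma`) and learning approximates a
  Monte-Carlo/Hebbian trace rule. The predictor is `M[s_prev, s_t]`
  normalized by its row sum, computed without mutating `M`.
* **Static SR** (`gamma` only): the closed-form SR of the empirical
  transition matrix of the entire sequence — multi-step structure with no
  trial-by-trial learning.

`M` is initialized at the closed form under a uniform transition matrix
(every entry `1 / (n (1 - gamma))`). Because `gamma` is a fitted parameter,
this initialization is recomputed inside every likelihood evaluation; the
trace starts at zero for each session.

## The RT model

RTs follow a shifted log-normal: `log(rt - shift) ~ Normal(mu_t, sigma^2)`,
with the shift fitted as a fraction (`shift_frac`, logit-scale) of the
session's minimum observed RT, and

```
mu_t = mu0 + beta_trial * trial_t + target_offset[code_t]
     + beta_W * W_t + beta_A * A_t
     + beta_ntrials * r_ntrials_t + beta_lag10 * r_lag10_t
```

where `trial_t` is the trial index rescaled to [0, 1], the 15 motor codes
(5 single-key plus 10 two-key responses) contribute 14 free offsets with
code 1 as the reference, `W_t` and `A_t` are the recency and higher-order
predictors (either may be switched off, giving the single-component and
baseline models), and the two nuisance regressors carry short-range recency:
the number of trials since the current node last occurred, and
`log(1 + k)` for its count `k` in the previous 10 trials.

Conventions the literature leaves open, fixed here once: the
trials-since-last-seen regressor is capped at 100 and takes the cap value at
a node's first occurrence (an unbounded lag creates leverage points); the
windowed count uses `log1p` so it is finite at zero; logs are natural
throughout. The first 500 trials of each session equilibrate the learners
but contribute no likelihood, decoupling learning dynamics from
initialization; trial 1 has no predecessor and is skipped (it is inside the
equilibration period anyway).

## Hierarchical estimation and model comparison

Session-level parameters live on an unconstrained scale (logit for rates,
fractions and discount/trace parameters; log for `sigma`) and get a Gaussian
prior with identity covariance centred on group means plus a stage
coefficient times the stage covariate (-1 first stage, +1 second).
Estimation alternates:

* **E-like step** — per-session MAP by L-BFGS-B with numerical gradients.
  The likelihood surface has plateaus in `(gamma, lambda)`, so the first
  sweep uses multiple jittered restarts (default 3); later sweeps warm-start
  from the previous MAP. The expensive part of each evaluation is the
  learner forward pass, which depends only on `(alpha_W, alpha_A, gamma,
  lambda)`; it is computed in compiled code and memoized, so the
  finite-difference perturbations of the other ~20 regression parameters
  reuse it.
* **M step** — closed-form least squares of the MAP vectors on the stage
  covariate: the group mean is the average of the two covariate-group means
  and the stage coefficient is half their difference.

Convergence is monitored on the total penalized MAP objective (the sum of
negative log posteriors); the Laplace approximation to each session's
negative log marginal likelihood — `h(theta_hat) - (k/2) log(2 pi) +
(1/2) log det H`, with `H` the numeric Hessian of the negative log
posterior — is computed once at the final iterate. Evaluating it at every
sweep would cost a full Hessian per session per sweep and does not change
the fixed point. Non-positive-definite Hessians are repaired by eigenvalue
clamping and flagged.

Model scores add an AIC penalty of one nat per group-level parameter
(means plus any stage coefficients), divided equally across sessions, to
each session's negative log marginal likelihood; models are compared by
one-sided paired t-tests on these scores. The per-subject AIC constant (one
nat versus two per parameter) only matters when comparing models with
different group-parameter counts; it is exposed via `model_score()`'s
`n_group_params` argument.

## The synthetic-data generator

`simulate_population()` draws session parameters on the unconstrained scale
around configurable group means and runs the generative model forward
(walk, learner updates, `mu_t`, shifted log-normal noise above a 150 ms
floor). Defaults emulate a serial RT experiment: baseline RT 500 ms,
`sigma = 0.2` on the log scale, a mild practice effect (`beta_trial =
-0.1`), two-key responses 12% slower than single-key, negative predictor
weights (`beta_W = -0.8`, `beta_A = -1`: expected nodes are responded to
faster) and SR-TD parameters `alpha_A = 0.15`, `gamma = 0.8`,
`lambda = 0.6`, with `alpha_W = 0.3` for the recency component. Magnitudes
were chosen so the effects are detectable in a group of about 40 subjects,
the scale of the recovery and model-selection studies.

Subject-level heterogeneity defaults to sd 0.5 on the unconstrained scale
for all parameters except the two lag-count slopes (`beta_ntrials`,
`beta_lag10`), whose regressors reach 100 and which therefore get
proportionally small spreads (0.002, 0.03). A unit-scale draw on those
slopes would produce astronomically long RTs; the fitted hierarchical prior
nonetheless remains the identity, as in the estimation model. With sd 0.5
the unbounded predictor weights still have a 40-subject sampling error
around 0.08, so recovery of `beta_W` / `beta_A` is judged against the
realized sample mean of the generating draws, while the bounded parameters
(`alpha_W`, `alpha_A`, `gamma`, `lambda`), compressed by the logistic
transform, are judged directly against the configured group values.

What the generator deliberately does *not* emulate: response errors as a
cognitive process (an optional contamination rate merely exercises the
exclusion filters), fatigue or practice nonlinearities beyond the linear
trial term, and any within-session drift in the learning parameters.
Passing tests therefore show that the estimation and signature machinery
behaves correctly under the model's own assumptions — not that those
assumptions hold in human data.

## Sequence signatures

The trace signature compares final-element RTs of `S X T S T` windows
(a trace learner strengthened S -> T through the intervening X) with
`X1 X2 T S T` controls in which the tested S appears for the first time in
the window; the bootstrap signature compares `B T S B S T` (the early
B -> T prediction can be chained back to S via the S -> B backup) with
`X T S B S T` controls. Controls additionally require the critical state to
be distinct from the window's other role-carrying states — without this, a
"control" window could itself trigger the update under test. All
overlapping windows are counted, and final elements pass the same exclusion
filters as the likelihood. Effects are estimated in ms by a linear mixed
model with motor-target fixed effects and correlated random
intercept/condition slopes per subject (and per graph instance when
several are present), with a per-subject paired-means fallback if the
random-effects fit fails.

Simulated pure-trace (`lambda = 1`) and pure-bootstrap (`lambda = 0`)
SR-TD agents (`alpha = 0.4`, `gamma = 0.7`, `beta_A = -2`,
`sigma = 0.15`, no recency or nuisance components) doubly dissociate, with
two caveats that the tests state precisely rather than idealize away. In
the trace contrast, bootstrap agents are not merely null but slightly
*slowed*: TD(0)'s own-row update moves `M[S, T]` toward
`gamma M[X, T]`, a first-order effect with the opposite sign to trace
facilitation. In the bootstrap contrast, trace agents retain a small
same-direction residual (the bootstrap term is algebraically present in
SR-TD(1); its cancellation happens across successive updates, and the
readout occurs mid-stream), so the dissociation there is asserted as a
strict magnitude ordering rather than an exact zero.

The novel-cluster analysis regresses nuisance-residualized log RTs (an OLS
fit per session of `log(rt - shift)` on trial and motor target only, with
the shift fixed at half the session minimum) on a 0/1 first/second
cluster-entry indicator, controlling recency with an effects-coded
categorical lag term (lags pooled at 100), with random intercept and slope
per subject. SR learners predict the second trial inside a freshly entered
cluster to be faster than the first; a recency learner does not.

## Numerical choices and problem sizes

* Transforms: logit/log with boundary values clamped at `1e-6` from the
  boundary (with a warning); `lambda` "fixed at 1" is held at `0.999999` so
  the internal transform stays finite.
* `sr_closed_form()` uses a dense solve; its correctness is checked against
  the truncated series `sum_k gamma^{k-1} T^k` with the geometric tail
  bound `gamma^K / (1 - gamma)`.
* SR-TD convergence is verified at `gamma = 0.5` (the package's generic
  mid-range default), `alpha = 0.02`, walks of 2e5 steps on each graph
  kind and `lambda` in {0, 0.5, 1}, against the closed form of the true
  walk transition matrix (sup-norm band 0.15, dominated by steady-state
  stochastic-update fluctuation rather than bias).
* Recovery, model-selection and lambda-identifiability studies use 40
  sessions of 1500 trials; EM runs up to 6 sweeps at tolerance 0.05 with 2
  restarts on the first sweep and warm starts afterwards. These sizes give
  stable t-statistics while keeping a full study re-runnable in minutes.
* Degenerate inputs: sessions with no valid trials raise an error; an
  all-equilibration session contributes zero likelihood with a warning;
  RTs at or below the shift are flagged, never silently dropped;
  zero-variance score differences short-circuit the paired t-test with a
  degeneracy flag.

## Known limitations

* The hierarchical prior covariance is fixed to the identity; no attempt is
  made to estimate group covariance or to model averaging.
* SR learning by iterating a one-step model (matrix-inversion /
  model-based routes to the SR) is out of scope, as are choice behaviour,
  drift-diffusion-style RT process models and lapse mixtures.
* The mixed-effects signature models use a particular estimator (lme4);
  the contract is the design matrix and random-effects structure, not a
  specific software's output to the last digit.
* Stage-difference coefficients on `mu0` trade off against the shift
  fraction and are weakly identified; stage effects are best placed on (or
  read from) parameters the likelihood pins down directly.
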