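#!/usr/bin/env Rscript

# Compare fitted models with one-sided paired t-tests on the AIC-penalized
# per-session negative log marginal likelihoods, mirroring the questions the
# workflow is built around: does combined recency + SR-TD beat recency alone
# and recency + one-step on combined-generator data, does it (correctly) fail
# to beat recency on recency-generator data, and does freeing lambda beat
# pinning it at 1?

suppressPackageStartupMessages({
  library(srtrace)
  library(readr)
  library(dplyr)
})

read_scores <- function(tag) {
  read_csv(file.path("results", paste0("scores_", tag, ".csv")),
           show_col_types = FALSE) %>% arrange(session)
}

pairs <- tribble(
  ~question, ~a, ~b,
  "combined beats recency (combined data)", "combined_srtd_free", "combined_recency",
  "combined beats one-step combo (combined data)", "combined_srtd_free", "combined_onestep",
  "lambda free beats lambda = 1 (combined data)", "combined_srtd_free", "combined_srtd_lam1",
  "combined beats recency (recency data)", "control_srtd_free", "control_recency"
)

out <- bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
  sa <- read_scores(pairs$a[i])
  sb <- read_scores(pairs$b[i])
  stopifnot(identical(sa$session, sb$session))
  cmp <- compare_models(sa, sb, alternative = "less")
  tibble(question = pairs$question[i], model_a = pairs$a[i],
         model_b = pairs$b[i], t = cmp$t, dof = cmp$dof, p = cmp$p,
         ci_lo = cmp$ci[1], ci_hi = cmp$ci[2], mean_diff = cmp$mean_diff)
}))
write_csv(out, "results/model_comparisons.csv")
print(as.data.frame(out[c("question", "t", "p", "mean_diff")]), digits = 3)
cat("\nNegative t favours model_a (lower penalized score is better).\n")
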