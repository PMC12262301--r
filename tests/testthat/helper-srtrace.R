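# shared fixtures built in code

modular_graph <- build_graph("modular")

# a tiny two-node path graph for degenerate-walk checks
path2_graph <- graph_from_edge_table(
  tibble::tibble(from = 1L, to = 2L), kind = "path2"
)

# random row-stochastic matrix
rand_stochastic <- function(n, seed) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    code
  }
  with_seed(seed, {
    m <- matrix(stats::rexp(n * n), n, n)
    m / rowSums(m)
  })
}

# independent brute-force pattern scans (plain loops, re-deriving the window
# definitions from scratch; used as the oracle for the vectorized finders)
brute_trace_scan <- function(nodes) {
  out <- list()
  for (t in seq_len(max(0, length(nodes) - 4L))) {
    w <- nodes[t:(t + 4L)]
    S <- w[1]; X <- w[2]; T1 <- w[3]; S2 <- w[4]; T2 <- w[5]
    if (S == S2 && T1 == T2 && S != X && X != T1 && S != T1) {
      out[[length(out) + 1L]] <- c(kind = 1L, start = t)
    } else if (T1 == T2 && !(S2 %in% c(S, X)) && S2 != T1) {
      out[[length(out) + 1L]] <- c(kind = 2L, start = t)
    }
  }
  do.call(rbind, out)
}

brute_bootstrap_scan <- function(nodes) {
  out <- list()
  for (t in seq_len(max(0, length(nodes) - 5L))) {
    w <- nodes[t:(t + 5L)]
    B1 <- w[1]; T1 <- w[2]; S1 <- w[3]; B2 <- w[4]; S2 <- w[5]; T2 <- w[6]
    distinct <- B2 != T1 && B2 != S1 && T1 != S1
    if (distinct && B1 == B2 && T1 == T2 && S1 == S2) {
      out[[length(out) + 1L]] <- c(kind = 1L, start = t)
    } else if (distinct && T1 == T2 && S1 == S2 &&
               !(B1 %in% c(B2, T1, S1))) {
      out[[length(out) + 1L]] <- c(kind = 2L, start = t)
    }
  }
  do.call(rbind, out)
}
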