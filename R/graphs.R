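#' Build one of the three 15-node walk graphs
#'
#' Constructs the degree-4-regular graphs used to generate stimulus
#' sequences: a modular graph (3 clusters of 5 nodes, complete within a
#' cluster except between its two connector nodes, with exactly one
#' connector edge between each pair of adjacent clusters arranged in a
#' ring), a ring lattice (each node joined to its two nearest neighbours on
#' each side), or a uniformly sampled connected 4-regular random graph.
#'
#' All three graphs are 4-regular, so a random walk on any of them has a
#' uniform stationary distribution and one-step transition probabilities are
#' matched across edge types — the property that makes cross-cluster RT
#' effects diagnostic of multi-step prediction.
#'
#' @param kind one of `"modular"`, `"lattice"`, `"random"`.
#' @param seed integer seed (used by the random graph sampler; ignored
#'   otherwise but recorded).
#' @return an object of class `walk_graph`: a list with `n_nodes`,
#'   `adjacency` (logical matrix), `neighbors` (list of integer vectors,
#'   1-based), `cluster_of` (integer vector, modular only, else `NULL`),
#'   `kind`, and `seed`.
#' @export
#' @examples
#' g <- build_graph("modular")
#' rowSums(g$adjacency) # all 4
build_graph <- function(kind = c("modular", "lattice", "random"), seed = 1L) {
  kind <- match.arg(kind)
  n <- 15L
  adj <- matrix(FALSE, n, n)
  cluster_of <- NULL
  if (kind == "modular") {
    cluster_of <- rep(1:3, each = 5L)
    for (c in 0:2) {
      ids <- 5L * c + 1:5
      adj[ids, ids] <- TRUE
      # connectors are the first and last node of each cluster; they are not
      # linked to each other within the cluster
      adj[ids[1], ids[5]] <- adj[ids[5], ids[1]] <- FALSE
    }
    diag(adj) <- FALSE
    # one connector edge between each pair of adjacent clusters (cluster ring)
    for (e in list(c(5L, 6L), c(10L, 11L), c(15L, 1L))) {
      adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
    }
  } else if (kind == "lattice") {
    for (i in 1:n) {
      for (d in c(1L, 2L)) {
        j <- ((i - 1L + d) %% n) + 1L
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  } else {
    adj <- with_seed(seed, sample_regular_adjacency(n, 4L))
  }
  new_walk_graph(adj, kind, cluster_of, seed)
}

new_walk_graph <- function(adj, kind, cluster_of = NULL, seed = NA_integer_) {
  stopifnot(isSymmetric(unname(adj * 1)), all(!diag(adj)))
  n <- nrow(adj)
  g <- structure(
    list(
      n_nodes = n,
      adjacency = adj,
      neighbors = lapply(1:n, function(i) which(adj[i, ])),
      cluster_of = cluster_of,
      kind = kind,
      seed = seed
    ),
    class = "walk_graph"
  )
  stopifnot(all(lengths(g$neighbors) >= 1L), graph_is_connected(adj))
  g
}

# rejection-sample a connected simple 4-regular graph uniformly via igraph
sample_regular_adjacency <- function(n, degree) {
  repeat {
    ig <- igraph::sample_degseq(rep(degree, n), method = "configuration")
    ig <- igraph::simplify(ig)
    if (igraph::is_connected(ig) &&
        all(igraph::degree(ig) == degree)) {
      adj <- as.matrix(igraph::as_adjacency_matrix(ig)) > 0
      dimnames(adj) <- NULL
      return(adj)
    }
  }
}

graph_is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Transition matrix of the unbiased random walk on a graph
#'
#' @param graph a `walk_graph`.
#' @return a row-stochastic matrix with uniform mass over neighbours.
#' @export
walk_transition_matrix <- function(graph) {
  adj <- graph$adjacency * 1
  sweep(adj, 1, rowSums(adj), "/")
}

#' Generate a random-walk state sequence
#'
#' The first node is uniform over all nodes; each subsequent node is uniform
#' over the neighbours of the previous one.
#'
#' @param graph a `walk_graph`.
#' @param n_trials number of trials (walk length), at least 1.
#' @param seed integer seed.
#' @return integer vector of 1-based node ids of length `n_trials`.
#' @export
random_walk <- function(graph, n_trials, seed = 1L) {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    nodes <- integer(n_trials)
    nodes[1] <- sample.int(graph$n_nodes, 1L)
    for (t in seq_len(n_trials - 1L)) {
      nb <- graph$neighbors[[nodes[t]]]
      nodes[t + 1L] <- nb[sample.int(length(nb), 1L)]
    }
    nodes
  })
}

#' Randomize the node-to-motor-code assignment
#'
#' Responses are one- or two-key combinations on a 5-key pad: codes 1-5 are
#' the single keys and codes 6-15 the `choose(5, 2)` key pairs. The
#' assignment of code to node is randomized per subject.
#'
#' @param n_nodes number of nodes (must be 15, matching the 15 codes).
#' @param seed integer seed.
#' @return integer vector `map` with `map[node] = code`, a permutation of
#'   1..15.
#' @export
assign_motor_targets <- function(n_nodes = 15L, seed = 1L) {
  stopifnot(n_nodes == 15L)
  with_seed(seed, sample.int(n_nodes))
}

#' Table of motor codes
#'
#' @return a tibble with columns `code` and `keys` (e.g. `"3"` or `"2+5"`),
#'   5 single-key plus 10 two-key combinations.
#' @export
motor_code_table <- function() {
  pairs <- utils::combn(N_KEYS, 2L)
  tibble::tibble(
    code = 1:15,
    keys = c(as.character(1:N_KEYS),
             paste(pairs[1, ], pairs[2, ], sep = "+"))
  )
}

#' Serialize a graph as an edge table
#'
#' @param graph a `walk_graph`.
#' @return tibble with 1-based `from`, `to` (each undirected edge once,
#'   `from < to`) and, for modular graphs, `cluster_from` / `cluster_to`.
#' @export
as_edge_table <- function(graph) {
  idx <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  out <- tibble::tibble(from = idx[, 1], to = idx[, 2])
  out <- out[order(out$from, out$to), ]
  if (!is.null(graph$cluster_of)) {
    out$cluster_from <- graph$cluster_of[out$from]
    out$cluster_to <- graph$cluster_of[out$to]
  }
  out
}

#' Rebuild a graph from an edge table
#'
#' @param edges a data frame as produced by [as_edge_table()].
#' @param kind graph kind label to attach.
#' @return a `walk_graph`.
#' @export
graph_from_edge_table <- function(edges, kind = "custom") {
  n <- max(edges$from, edges$to)
  adj <- matrix(FALSE, n, n)
  adj[cbind(edges$from, edges$to)] <- TRUE
  adj[cbind(edges$to, edges$from)] <- TRUE
  cluster_of <- NULL
  if ("cluster_from" %in% names(edges)) {
    cluster_of <- integer(n)
    cluster_of[edges$from] <- edges$cluster_from
    cluster_of[edges$to] <- edges$cluster_to
  }
  new_walk_graph(adj, kind, cluster_of)
}

#' @export
print.walk_graph <- function(x, ...) {
  cat(sprintf("<walk_graph: %s, %d nodes, %d edges>\n", x$kind, x$n_nodes,
              sum(x$adjacency) / 2))
  invisible(x)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
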