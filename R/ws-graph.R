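#' Generate a Watts-Strogatz small-world graph
#'
#' Constructs a ring lattice on `n_nodes` nodes in which every node is
#' connected to its `neighbor_k` nearest neighbours (`neighbor_k / 2` on
#' each side) and then rewires each lattice edge independently with
#' probability `rewiring_p`, avoiding self-loops and duplicate edges.
#' Rewiring moves the far endpoint of an edge to a uniformly chosen
#' eligible node, so the edge count `n_nodes * neighbor_k / 2` is conserved
#' for every `rewiring_p`. `rewiring_p = 0` returns the regular lattice and
#' `rewiring_p = 1` an (almost) random degree-heterogeneous graph; the
#' family interpolates between the two regimes.
#'
#' @param n_nodes number of nodes (default 35, one per measurement channel).
#' @param neighbor_k even lattice degree, `0 < neighbor_k < n_nodes`
#'   (default 10, giving lattice density close to the working sparsity 0.3
#'   on 35 nodes).
#' @param rewiring_p rewiring probability in `[0, 1]`.
#' @param seed optional integer seed for reproducible rewiring.
#' @return an object of class `ws_graph`: a list with `adjacency`
#'   (symmetric 0/1 integer matrix, zero diagonal), `n_nodes`,
#'   `neighbor_k`, `rewiring_p` and `seed`.
#' @examples
#' g <- make_ws_graph(35, 10, 0.1, seed = 1)
#' sum(g$adjacency) / 2  # 175 edges for any rewiring_p
#' @export
make_ws_graph <- function(n_nodes = 35, neighbor_k = 10, rewiring_p, seed = NULL) {
  if (length(n_nodes) != 1L || n_nodes < 3) stop("n_nodes must be a single count >= 3")
  if (neighbor_k %% 2 != 0) stop("neighbor_k must be even")
  if (neighbor_k <= 0 || neighbor_k >= n_nodes) stop("neighbor_k must satisfy 0 < neighbor_k < n_nodes")
  if (rewiring_p < 0 || rewiring_p > 1) stop("rewiring_p must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_nodes)
  half <- neighbor_k %/% 2
  adj <- matrix(0L, n, n)
  for (j in seq_len(half)) {
    tgt <- (seq_len(n) + j - 1L) %% n + 1L
    adj[cbind(seq_len(n), tgt)] <- 1L
    adj[cbind(tgt, seq_len(n))] <- 1L
  }

  if (rewiring_p > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(half)) {
        if (runif(1) >= rewiring_p) next
        old <- (i + j - 1L) %% n + 1L
        if (adj[i, old] == 0L) next # already rewired away by an earlier step
        candidates <- which(adj[i, ] == 0L)
        candidates <- candidates[candidates != i]
        if (length(candidates) == 0L) next
        new <- candidates[sample.int(length(candidates), 1L)]
        adj[i, old] <- adj[old, i] <- 0L
        adj[i, new] <- adj[new, i] <- 1L
      }
    }
  }

  structure(
    list(adjacency = adj, n_nodes = n, neighbor_k = as.integer(neighbor_k),
         rewiring_p = rewiring_p, seed = seed),
    class = "ws_graph"
  )
}

#' @export
print.ws_graph <- function(x, ...) {
  cat(sprintf("Watts-Strogatz graph: %d nodes, k = %d, p = %g, %d edges\n",
              x$n_nodes, x$neighbor_k, x$rewiring_p, sum(x$adjacency) / 2L))
  invisible(x)
}
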