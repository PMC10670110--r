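#' Mean clustering coefficient
#'
#' Node-averaged Watts-Strogatz clustering: each node contributes the
#' fraction of its neighbour pairs that are themselves connected; nodes
#' with fewer than two neighbours contribute 0.
#'
#' @param graph a `binary_graph`, `ws_graph` or adjacency matrix.
#' @return scalar clustering coefficient `C`.
#' @export
clustering_coefficient <- function(graph) {
  cpp_clustering(as_adjacency(graph))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs with finite
#' distance. Disconnected pairs are excluded from both numerator and
#' denominator (the finite-pairs rule), applied identically to observed
#' graphs and null graphs so that the normalized path length stays
#' comparable; an edgeless graph (no finite pair) is an error.
#'
#' @param graph a `binary_graph`, `ws_graph` or adjacency matrix.
#' @return scalar characteristic path length `L`.
#' @export
char_path_length <- function(graph) {
  l <- cpp_path_length(as_adjacency(graph))
  if (is.na(l)) stop("graph has no edges: no finite node pair")
  l
}

#' Degree-preserving random null ensemble
#'
#' Generates `count` randomized versions of the graph by Maslov-Sneppen
#' double-edge swaps (at least `swaps_per_edge` successful swaps per
#' edge), which preserve every node's degree exactly while destroying
#' higher-order structure. Connectivity is not enforced. Reproducible
#' under `seed`.
#'
#' @param graph a `binary_graph`, `ws_graph` or adjacency matrix.
#' @param count ensemble size (default 30).
#' @param seed optional integer seed.
#' @param swaps_per_edge target successful swaps per edge (default 10).
#' @return object of class `null_ensemble`: list of adjacency matrices.
#' @export
random_nulls <- function(graph, count = 30, seed = NULL, swaps_per_edge = 10) {
  adj <- as_adjacency(graph)
  edges <- adjacency_to_edges(adj)
  if (nrow(edges) < 2) stop("null randomization needs at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(adj)
  target <- swaps_per_edge * nrow(edges)
  shortfall <- 0L
  nulls <- vector("list", count)
  for (i in seq_len(count)) {
    rew <- cpp_degseq_rewire(edges, n, target, 20L * target)
    if (attr(rew, "swaps") < target) shortfall <- shortfall + 1L
    nulls[[i]] <- edges_to_adjacency(rew, n)
  }
  if (shortfall > 0) {
    warning(sprintf("swap saturation in %d of %d nulls (fewer than %d swaps achieved)",
                    shortfall, count, target))
  }
  structure(list(graphs = nulls, count = count, seed = seed), class = "null_ensemble")
}

#' Small-world metrics of a binary graph
#'
#' Computes clustering `C` and characteristic path length `L` of the
#' graph, normalizes them by the ensemble means of a degree-preserving
#' null ensemble (`gamma = C / mean(C_null)`, `lambda = L / mean(L_null)`)
#' and returns the small-worldness `sigma = gamma / lambda`. `sigma > 1`
#' indicates small-world organization: more clustered than random at
#' comparable path length.
#'
#' @param graph a `binary_graph`, `ws_graph` or adjacency matrix.
#' @param nulls a [random_nulls()] ensemble for this graph.
#' @return object of class `graph_metrics`: list with `C`, `L`, `gamma`,
#'   `lambda`, `sigma`, `null_count`.
#' @export
small_worldness <- function(graph, nulls) {
  adj <- as_adjacency(graph)
  C <- cpp_clustering(adj)
  L <- cpp_path_length(adj)
  if (is.na(L)) stop("graph has no edges: no finite node pair")
  cn <- vapply(nulls$graphs, cpp_clustering, numeric(1))
  ln <- vapply(nulls$graphs, cpp_path_length, numeric(1))
  mean_cn <- mean(cn)
  mean_ln <- mean(ln, na.rm = TRUE)
  if (!is.finite(mean_cn) || mean_cn == 0) stop("mean null clustering is zero")
  if (!is.finite(mean_ln) || mean_ln == 0) stop("mean null path length is zero")
  gamma <- C / mean_cn
  lambda <- L / mean_ln
  structure(list(C = C, L = L, gamma = gamma, lambda = lambda,
                 sigma = gamma / lambda, null_count = nulls$count),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("C = %.4f  L = %.4f  gamma = %.4f  lambda = %.4f  sigma = %.4f (%d nulls)\n",
              x$C, x$L, x$gamma, x$lambda, x$sigma, x$null_count))
  invisible(x)
}

#' Average degree distribution of a set of graphs
#'
#' Normalizes each graph's degree histogram over degree values
#' `0 .. n-1` to a probability mass function and averages across graphs.
#'
#' @param graphs a list of graphs/adjacency matrices sharing a node count
#'   (a single graph is also accepted).
#' @return named numeric vector summing to 1, one entry per degree value.
#' @export
degree_distribution <- function(graphs) {
  if (!is.list(graphs) || inherits(graphs, c("binary_graph", "ws_graph"))) graphs <- list(graphs)
  if (length(graphs) == 0) stop("empty graph list")
  adjs <- lapply(graphs, as_adjacency)
  n <- nrow(adjs[[1]])
  if (!all(vapply(adjs, nrow, integer(1)) == n)) stop("graphs must share the node count")
  pm <- rowMeans(vapply(adjs, function(a) {
    tabulate(colSums(a) + 1L, nbins = n) / n
  }, numeric(n)))
  names(pm) <- 0:(n - 1)
  pm
}

#' Aggregate a degree distribution over degree bins
#'
#' @param pmf a [degree_distribution()] result.
#' @param bins list of inclusive degree ranges, e.g.
#'   `list(c(0, 1), c(6, 15), c(16, 20))`.
#' @return named numeric vector of binned probability mass.
#' @export
bin_degree_distribution <- function(pmf,
                                    bins = list(c(0, 1), c(6, 15), c(16, 20))) {
  deg <- as.integer(names(pmf))
  out <- vapply(bins, function(b) sum(pmf[deg >= b[1] & deg <= b[2]]), numeric(1))
  names(out) <- vapply(bins, function(b) paste(b, collapse = "-"), character(1))
  out
}

# fast internal sigma evaluation used by the online engine: adjacency in,
# sigma out, nulls drawn from the current RNG stream
sigma_of_adjacency <- function(adj, null_count, swaps_per_edge = 10) {
  C <- cpp_clustering(adj)
  L <- cpp_path_length(adj)
  edges <- adjacency_to_edges(adj)
  target <- swaps_per_edge * nrow(edges)
  nm <- cpp_null_metrics(edges, nrow(adj), null_count, target, 20L * target)
  (C / mean(nm[, 1])) / (L / mean(nm[, 2], na.rm = TRUE))
}

#' Small-worldness of one data window
#'
#' The full online chain for a single window: Pearson correlation, Fisher
#' z, absolute-value sparsity thresholding, degree-preserving nulls, and
#' `sigma = gamma / lambda`.
#'
#' @param window time x channel matrix.
#' @param sparsity retained fraction of node pairs (default 0.3).
#' @param null_count null ensemble size (default 30).
#' @param seed optional seed for the null randomization.
#' @return scalar sigma.
#' @export
network_sigma <- function(window, sparsity = 0.3, null_count = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- fisher_z(correlation_matrix(window))
  g <- threshold_binarize(z, sparsity)
  sigma_of_adjacency(g$adjacency, null_count)
}
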