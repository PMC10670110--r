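#' Edge reallocation between two groups
#'
#' Contrasts per-subject mean edge strengths (Fisher z, upper-triangle
#' edge order) between two groups, selects edges whose independent t-test
#' is below `alpha` (0.01, the drawing threshold), and splits them into
#' increased (A > B) and decreased (A < B) sets. The mean endpoint degree
#' of each set — the "rich node / poor node" summary of the reallocation —
#' is computed on the pooled mean graph obtained by thresholding the
#' grand-mean connectivity at the working sparsity.
#'
#' @param group_a,group_b subject x edge matrices of mean Fisher-z values
#'   (group A minus group B is the reported contrast).
#' @param n_nodes node count (edges must equal `n_nodes (n_nodes - 1)/2`).
#' @param alpha edge-selection threshold (default 0.01).
#' @param sparsity sparsity of the pooled reference graph (default 0.3).
#' @param adjust BH-adjust edge p values before selection (default FALSE).
#' @return object of class `edge_change_map`: `edges` (the
#'   [edgewise_ttest()] table plus endpoint columns), `increased`,
#'   `decreased` (edge indices), `mean_degree_increased`,
#'   `mean_degree_decreased` (NA when a set is empty), `pooled_graph`,
#'   `degrees`.
#' @export
edge_reallocation <- function(group_a, group_b, n_nodes = 35, alpha = 0.01,
                              sparsity = 0.3, adjust = FALSE) {
  n_edges <- n_nodes * (n_nodes - 1) / 2
  if (ncol(as.matrix(group_a)) != n_edges) {
    stop("edge columns must match n_nodes (n_nodes - 1) / 2")
  }
  tests <- edgewise_ttest(group_a, group_b, alpha = alpha, adjust = adjust)
  pairs <- upper_tri_pairs(n_nodes)
  tests$node_i <- pairs[, "i"]
  tests$node_j <- pairs[, "j"]
  increased <- tests$edge[tests$selected & tests$mean_diff > 0]
  decreased <- tests$edge[tests$selected & tests$mean_diff < 0]

  pooled_z <- (colMeans(as.matrix(group_a)) * nrow(group_a) +
                 colMeans(as.matrix(group_b)) * nrow(group_b)) /
    (nrow(group_a) + nrow(group_b))
  pooled <- threshold_binarize(ut_matrix(pooled_z, n_nodes), sparsity)
  deg <- colSums(pooled$adjacency)

  endpoint_degree <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    mean((deg[pairs[idx, "i"]] + deg[pairs[idx, "j"]]) / 2)
  }
  structure(list(edges = tests, increased = increased, decreased = decreased,
                 mean_degree_increased = endpoint_degree(increased),
                 mean_degree_decreased = endpoint_degree(decreased),
                 pooled_graph = pooled, degrees = deg, n_nodes = n_nodes),
            class = "edge_change_map")
}

#' @export
print.edge_change_map <- function(x, ...) {
  cat(sprintf(paste0("edge change map: %d increased (mean endpoint degree %.3g), ",
                     "%d decreased (mean endpoint degree %.3g)\n"),
              length(x$increased), x$mean_degree_increased,
              length(x$decreased), x$mean_degree_decreased))
  invisible(x)
}

#' Correlation between node degree and its selected-edge change
#'
#' For every node, `delta_k` is the signed count of selected edge changes
#' incident to it (+1 per increased, -1 per decreased edge); the Pearson
#' correlation of `(k, delta_k)` over nodes quantifies whether high-degree
#' nodes lose and low-degree nodes gain connections. Node degree `k` comes
#' from the pooled mean graph of the change map. A uniform `delta_k`
#' (degenerate variance) is an error.
#'
#' @param change_map an [edge_reallocation()] result.
#' @return list with `delta_k` (per node), `k`, and `test` (a
#'   [pearson_corr()] outcome).
#' @export
degree_delta_correlation <- function(change_map) {
  n <- change_map$n_nodes
  pairs <- upper_tri_pairs(n)
  delta_k <- numeric(n)
  for (e in change_map$increased) {
    delta_k[pairs[e, ]] <- delta_k[pairs[e, ]] + 1
  }
  for (e in change_map$decreased) {
    delta_k[pairs[e, ]] <- delta_k[pairs[e, ]] - 1
  }
  list(delta_k = delta_k, k = change_map$degrees,
       test = pearson_corr(change_map$degrees, delta_k))
}

# simulate mean/SD reference curves of C(p) and L(p) for the WS family
ws_family_curves <- function(p_grid, n_nodes, neighbor_k, n_seeds, seed0) {
  res <- lapply(seq_along(p_grid), function(i) {
    cs <- numeric(n_seeds); ls <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      g <- make_ws_graph(n_nodes, neighbor_k, p_grid[i],
                         seed = derive_seed(seed0, i, s))
      cs[s] <- cpp_clustering(g$adjacency)
      ls[s] <- cpp_path_length(g$adjacency)
    }
    c(C = mean(cs), L = mean(ls), C_sd = stats::sd(cs), L_sd = stats::sd(ls))
  })
  data.frame(p = p_grid, do.call(rbind, res))
}

#' Locate observed metrics on the Watts-Strogatz rewiring continuum
#'
#' Places an observed (clustering, path length) pair in the family of
#' randomly rewired graphs with matched node count and degree: reference
#' curves `C(p)` and `L(p)` are simulated on a log-spaced grid of rewiring
#' probabilities (plus `p = 0`), the estimate minimizes the squared
#' distance to the curves with each metric normalized by its spread
#' across the family, and a second, finer grid pass refines the estimate
#' around the first minimum. Observations outside the simulated family
#' envelope are flagged and return the nearest-boundary estimate.
#'
#' @param C,L observed mean clustering coefficient and characteristic
#'   path length.
#' @param n_nodes,neighbor_k the reference family (defaults 35 and 10:
#'   channel count and the lattice degree matching the working sparsity).
#' @param n_seeds graphs simulated per grid point (default 100).
#' @param seed optional seed for the reference simulation.
#' @return object of class `ws_placement`: `p_hat`, `curves` (first-pass
#'   reference table), `refined` (second-pass table), `outside_envelope`.
#' @export
infer_rewiring_p <- function(C, L, n_nodes = 35, neighbor_k = 10,
                             n_seeds = 100, seed = NULL) {
  seed0 <- seed %||% 1L
  p_grid <- c(0, exp(seq(log(0.004), log(1), length.out = 12)))
  curves <- ws_family_curves(p_grid, n_nodes, neighbor_k, n_seeds, seed0)
  s_c <- stats::sd(curves$C); s_l <- stats::sd(curves$L)
  dist <- ((C - curves$C) / s_c)^2 + ((L - curves$L) / s_l)^2
  i <- which.min(dist)

  lo <- if (i > 1) max(curves$p[i - 1], 1e-4) else 1e-4
  hi <- if (i < nrow(curves)) curves$p[i + 1] else 1
  fine <- exp(seq(log(lo), log(hi), length.out = 9))
  if (i == 1) fine <- c(0, fine)
  refined <- ws_family_curves(fine, n_nodes, neighbor_k, n_seeds,
                              derive_seed(seed0, 2L))
  dist2 <- ((C - refined$C) / s_c)^2 + ((L - refined$L) / s_l)^2
  j <- which.min(dist2)

  outside <- C > max(curves$C + 2 * curves$C_sd) || C < min(curves$C - 2 * curves$C_sd) ||
    L > max(curves$L + 2 * curves$L_sd) || L < min(curves$L - 2 * curves$L_sd)
  structure(list(p_hat = refined$p[j], curves = curves, refined = refined,
                 outside_envelope = outside),
            class = "ws_placement")
}

#' @export
print.ws_placement <- function(x, ...) {
  cat(sprintf("estimated rewiring probability: %.4g%s\n", x$p_hat,
              if (x$outside_envelope) " (outside family envelope; boundary estimate)" else ""))
  invisible(x)
}
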