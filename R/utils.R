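# shared internal helpers

.datatable.aware <- TRUE

# upper-triangle (i < j) node pairs of an n-node graph, column-major order;
# this fixed enumeration is the package-wide edge indexing convention
upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

# symmetric matrix -> upper-triangle vector in the package edge order
ut_vector <- function(m) m[upper.tri(m)]

# upper-triangle vector -> symmetric matrix with zero diagonal
ut_matrix <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

# coerce the various graph representations to a 0/1 integer adjacency matrix
as_adjacency <- function(x) {
  if (inherits(x, "ws_graph") || inherits(x, "binary_graph")) x <- x$adjacency
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("expected a square adjacency matrix or a graph object")
  }
  storage.mode(x) <- "integer"
  x
}

adjacency_to_edges <- function(adj) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  idx
}

edges_to_adjacency <- function(edges, n) {
  adj <- matrix(0L, n, n)
  adj[edges] <- 1L
  adj[edges[, c(2, 1), drop = FALSE]] <- 1L
  adj
}

# derive a bounded child seed from a master seed and stream offsets so that
# every generator draws from its own reproducible stream
derive_seed <- function(seed, ...) {
  offs <- c(...)
  val <- (as.double(seed) + sum(offs * seq(10007, by = 2, length.out = length(offs)))) %% 2147483629
  as.integer(val)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
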