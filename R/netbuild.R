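#' Sliding-window specification
#'
#' Trailing windows of `length` samples advanced by `step` samples. The
#' online configuration uses 128-sample (5 s) windows stepped by 8 samples
#' (nominal 3 Hz refresh at 25.6 Hz sampling; 8 samples = 3.2 Hz is the
#' closest integer step). The offline configuration uses non-overlapping
#' 640-sample (25 s) windows.
#'
#' @param length window length in samples.
#' @param step step between window starts in samples, `0 < step <= length`
#'   for the online case; any positive step is allowed.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length = 128, step = 8) {
  if (step <= 0 || length <= 0) stop("window length and step must be positive")
  structure(list(length = as.integer(length), step = as.integer(step),
                 alignment = "trailing"), class = "window_spec")
}

#' Split a recording into trailing windows
#'
#' Window count is `floor((T - length) / step) + 1`; an error is raised if
#' the recording is shorter than one window.
#'
#' @param recording a [hemo_recording()] or time x channel matrix.
#' @param spec a [window_spec()].
#' @return list of time x channel matrices, one per window, with start
#'   indices as attribute `"starts"`.
#' @export
window_series <- function(recording, spec = window_spec()) {
  data <- if (inherits(recording, "hemo_recording")) recording$data else as.matrix(recording)
  n_t <- nrow(data)
  if (n_t < spec$length) stop("recording is shorter than one window")
  starts <- seq.int(1L, n_t - spec$length + 1L, by = spec$step)
  out <- lapply(starts, function(s) data[s:(s + spec$length - 1L), , drop = FALSE])
  attr(out, "starts") <- starts
  out
}

#' Pairwise Pearson correlation matrix of one window
#'
#' @param window time x channel matrix with at least 3 samples.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) < 3) stop("a window needs at least 3 samples")
  v <- apply(window, 2, stats::sd)
  if (any(v == 0)) {
    stop(sprintf("zero-variance channel: %s",
                 paste(colnames(window)[v == 0] %||% which(v == 0), collapse = ", ")))
  }
  stats::cor(window)
}

#' Fisher z transform of correlation values
#'
#' `Z = atanh(r) = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilizing
#' transform applied to every correlation before thresholding. `|r|` is
#' clamped to `1 - 1e-7` first so perfectly correlated pairs stay finite.
#' For matrix input the diagonal is set to zero (self-correlations are
#' excluded from all downstream use).
#'
#' @param r correlation value(s) in `[-1, 1]`; vector or matrix.
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  z <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  if (is.matrix(z) && nrow(z) == ncol(z)) diag(z) <- 0
  z
}

#' Threshold a connectivity matrix into a binary graph at fixed sparsity
#'
#' Ranks the off-diagonal pairs by absolute value (absolute sign
#' convention) and keeps the top `floor(sparsity * n(n-1)/2)` pairs as
#' edges of an undirected binary graph. Ties at the threshold boundary are
#' broken deterministically by ascending (row, column) index, so the
#' retained set is bit-reproducible. Because ranking only uses the order
#' of `|values|`, any strictly monotone transform of the magnitudes (e.g.
#' `|r|` vs `|z|`) yields the identical graph.
#'
#' @param matrix symmetric numeric matrix (e.g. Fisher-z connectivity).
#' @param sparsity fraction of possible node pairs to retain, in `(0, 1]`.
#' @return object of class `binary_graph`: list with `adjacency`,
#'   `sparsity` and `n_edges`.
#' @export
threshold_binarize <- function(matrix, sparsity) {
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]")
  n <- nrow(matrix)
  pairs <- upper_tri_pairs(n)
  vals <- abs(matrix[upper.tri(matrix)])
  m_keep <- floor(sparsity * n * (n - 1) / 2)
  ord <- order(-vals, pairs[, "i"], pairs[, "j"])
  keep <- ord[seq_len(m_keep)]
  adj <- matrix(0L, n, n)
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj[pairs[keep, c(2, 1), drop = FALSE]] <- 1L
  structure(list(adjacency = adj, sparsity = sparsity, n_edges = m_keep),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary graph: %d nodes, %d edges (sparsity %.3g)\n",
              nrow(x$adjacency), x$n_edges, x$sparsity))
  invisible(x)
}

#' Windowed Fisher-z connectivity matrices of a recording
#'
#' Convenience chain: window the recording, correlate every window, and
#' Fisher-transform.
#'
#' @param recording a [hemo_recording()] or time x channel matrix.
#' @param spec a [window_spec()].
#' @return list of symmetric z matrices, window starts as attribute.
#' @export
connectivity_series <- function(recording, spec = window_spec()) {
  wins <- window_series(recording, spec)
  out <- lapply(wins, function(w) fisher_z(correlation_matrix(w)))
  attr(out, "starts") <- attr(wins, "starts")
  out
}
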