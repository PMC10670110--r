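# independent brute-force oracles used to validate the package's graph and
# statistics code; deliberately naive implementations

# Watts-Strogatz clustering by explicit neighbour-pair enumeration
bf_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) links <- links + 1
      }
    }
    vals[i] <- 2 * links / (k * (k - 1))
  }
  mean(vals)
}

# characteristic path length via Floyd-Warshall, finite pairs only
bf_path_length <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (length(finite) == 0) return(NA_real_)
  mean(finite)
}

# random simple undirected graph on n nodes with at least one edge
random_small_graph <- function(n, p_edge = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- which(upper.tri(adj))
    on <- up[runif(length(up)) < p_edge]
    if (length(on) == 0) next
    adj[on] <- 1L
    adj <- adj + t(adj)
    return(adj)
  }
}

# pooled-variance two-sample t statistic from the textbook formula
bf_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# mixed-design (one between, one within factor) sums-of-squares by hand
bf_mixed_anova <- function(data) {
  g <- factor(data$group); d <- factor(data$day); s <- factor(data$subject)
  y <- data$value
  N <- length(y)
  gm <- mean(y)
  a <- nlevels(g); b <- nlevels(d)
  n_sub <- nlevels(s)
  ss_group <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_day <- sum(tapply(y, d, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(y, list(g, d), mean)
  gmean <- tapply(y, g, mean); dmean <- tapply(y, d, mean)
  ss_cells <- 0
  for (i in seq_len(a)) {
    for (j in seq_len(b)) {
      ss_cells <- ss_cells + sum(g == levels(g)[i] & d == levels(d)[j]) *
        (cell[i, j] - gm)^2
    }
  }
  ss_inter <- ss_cells - ss_group - ss_day
  sub_mean <- tapply(y, s, mean)
  sub_group <- tapply(as.character(data$group), s, `[`, 1)
  ss_subj <- b * sum((sub_mean - gmean[sub_group])^2)
  ss_tot <- sum((y - gm)^2)
  ss_resid <- ss_tot - ss_group - ss_day - ss_inter - ss_subj
  df_group <- a - 1; df_subj <- n_sub - a
  df_day <- b - 1; df_inter <- (a - 1) * (b - 1)
  df_resid <- df_subj * df_day
  data.frame(effect = c("group", "day", "group:day"),
             F = c((ss_group / df_group) / (ss_subj / df_subj),
                   (ss_day / df_day) / (ss_resid / df_resid),
                   (ss_inter / df_inter) / (ss_resid / df_resid)))
}
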