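# construct group edge-summary matrices in which the contrast moves edges
# from hub pairs to leaf pairs of the pooled reference graph
hub_to_leaf_groups <- function(n_nodes = 35, n_subj = 17, effect = 1.5) {
  n_edge <- n_nodes * (n_nodes - 1) / 2
  z0 <- rnorm(n_edge, 0, 0.5)
  pooled <- threshold_binarize(swnf:::ut_matrix(z0, n_nodes), 0.3)
  deg <- colSums(pooled$adjacency)
  pairs <- swnf:::upper_tri_pairs(n_nodes)
  pair_deg <- (deg[pairs[, "i"]] + deg[pairs[, "j"]]) / 2
  present <- swnf:::ut_vector(pooled$adjacency) == 1
  dec <- order(ifelse(present, pair_deg, -Inf), decreasing = TRUE)[1:8]
  inc <- order(ifelse(!present, pair_deg, Inf))[1:8]
  shift <- numeric(n_edge)
  shift[dec] <- -effect
  shift[inc] <- effect
  list(a = t(replicate(n_subj, z0 + shift + rnorm(n_edge, 0, 0.3))),
       b = t(replicate(n_subj, z0 + rnorm(n_edge, 0, 0.3))),
       dec = dec, inc = inc)
}

test_that("identical groups produce an empty change map", {
  set.seed(1)
  a <- matrix(rnorm(17 * 595), 17)
  map <- edge_reallocation(a, a)
  expect_length(map$increased, 0)
  expect_length(map$decreased, 0)
  expect_true(is.na(map$mean_degree_increased))
  expect_true(is.na(map$mean_degree_decreased))
})

test_that("the selection mask delegates exactly to the edge-wise tests", {
  set.seed(2)
  a <- matrix(rnorm(17 * 595, 0.05), 17)
  b <- matrix(rnorm(17 * 595), 17)
  map <- edge_reallocation(a, b)
  ref <- edgewise_ttest(a, b, alpha = 0.01)
  expect_identical(map$edges$selected, ref$selected)
  expect_identical(sort(c(map$increased, map$decreased)),
                   ref$edge[ref$selected])
})

test_that("hub-to-leaf reallocation shows in the endpoint degrees", {
  set.seed(3)
  wins <- vapply(1:20, function(i) {
    g <- hub_to_leaf_groups()
    map <- edge_reallocation(g$a, g$b)
    length(map$increased) > 0 && length(map$decreased) > 0 &&
      map$mean_degree_decreased > map$mean_degree_increased
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("node degree change balances the selected edge counts exactly", {
  set.seed(4)
  g <- hub_to_leaf_groups()
  map <- edge_reallocation(g$a, g$b)
  dk <- degree_delta_correlation(map)
  expect_equal(sum(dk$delta_k),
               2 * (length(map$increased) - length(map$decreased)))
})

test_that("degree-vs-change correlation is negative under hub-to-leaf flow", {
  set.seed(5)
  neg <- vapply(1:20, function(i) {
    g <- hub_to_leaf_groups()
    map <- edge_reallocation(g$a, g$b)
    degree_delta_correlation(map)$test$effect < 0
  }, logical(1))
  expect_gte(mean(neg), 0.9)
})

test_that("uniform degree change is a degenerate correlation input", {
  set.seed(6)
  a <- matrix(rnorm(17 * 595), 17)
  map <- edge_reallocation(a, a) # nothing selected: delta_k all zero
  expect_error(degree_delta_correlation(map), "zero-variance")
})

test_that("lattice metrics are placed at the regular end of the continuum", {
  g0 <- make_ws_graph(35, 10, 0)
  pl <- infer_rewiring_p(clustering_coefficient(g0), char_path_length(g0),
                         n_seeds = 30, seed = 1)
  expect_lte(pl$p_hat, 0.01)
})

test_that("the rewiring probability of a moderately random family is recovered", {
  runs <- vapply(1:5, function(run) {
    cs <- ls <- numeric(15)
    for (s in 1:15) {
      g <- make_ws_graph(35, 10, 0.1, seed = run * 100 + s)
      cs[s] <- clustering_coefficient(g)
      ls[s] <- char_path_length(g)
    }
    pl <- infer_rewiring_p(mean(cs), mean(ls), n_seeds = 40, seed = run)
    pl$p_hat >= 0.05 && pl$p_hat <= 0.2
  }, logical(1))
  expect_gte(mean(runs), 0.9)
})

test_that("the placement estimate is monotone in the true rewiring probability", {
  p_hat <- vapply(c(0.02, 0.1, 0.5), function(p) {
    cs <- ls <- numeric(10)
    for (s in 1:10) {
      g <- make_ws_graph(35, 10, p, seed = 500 + s)
      cs[s] <- clustering_coefficient(g)
      ls[s] <- char_path_length(g)
    }
    infer_rewiring_p(mean(cs), mean(ls), n_seeds = 30, seed = 3)$p_hat
  }, numeric(1))
  expect_true(all(diff(p_hat) > 0))
})
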