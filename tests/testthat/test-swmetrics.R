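complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

test_that("clustering and path length match hand-counted closed forms", {
  expect_equal(clustering_coefficient(complete_graph(4)), 1)

  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L; star <- star + t(star)
  expect_equal(clustering_coefficient(star), 0)

  # triangle {1,2,3} with pendant 4-3: (1 + 1 + 1/3 + 0) / 4 = 7/12
  tri <- matrix(0L, 4, 4)
  tri[1, 2] <- tri[2, 3] <- tri[1, 3] <- tri[3, 4] <- 1L
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(tri), 7 / 12, tolerance = 1e-12)

  path3 <- matrix(0L, 3, 3); path3[1, 2] <- path3[2, 3] <- 1L; path3 <- path3 + t(path3)
  expect_equal(char_path_length(path3), 4 / 3, tolerance = 1e-12)
  expect_equal(char_path_length(complete_graph(6)), 1)

  # two disjoint edges: only the connected pairs count
  disj <- matrix(0L, 4, 4); disj[1, 2] <- disj[3, 4] <- 1L; disj <- disj + t(disj)
  expect_equal(char_path_length(disj), 1)

  expect_error(char_path_length(matrix(0L, 3, 3)), "no edges")
})

test_that("metrics agree with brute-force oracles on all small graphs", {
  set.seed(10)
  for (i in 1:30) {
    adj <- random_small_graph(sample(3:8, 1))
    expect_equal(clustering_coefficient(adj), bf_clustering(adj), tolerance = 1e-12)
    expect_equal(char_path_length(adj), bf_path_length(adj), tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on random graphs", {
  set.seed(11)
  for (i in 1:10) {
    adj <- random_small_graph(12, 0.3)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(clustering_coefficient(adj),
                 igraph::transitivity(ig, type = "localaverage", isolates = "zero"),
                 tolerance = 1e-12)
    expect_equal(char_path_length(adj), igraph::mean_distance(ig),
                 tolerance = 1e-12)
  }
})

test_that("null ensembles preserve the degree sequence exactly", {
  g <- make_ws_graph(35, 10, 0.3, seed = 1)
  nulls <- random_nulls(g, count = 30, seed = 2)
  src_deg <- sort(colSums(g$adjacency))
  for (null in nulls$graphs) {
    expect_identical(sort(colSums(null)), src_deg)
    expect_equal(diag(null), rep(0L, 35))
    expect_true(isSymmetric(null))
  }
  # reproducible under seed
  nulls2 <- random_nulls(g, count = 30, seed = 2)
  expect_identical(nulls$graphs, nulls2$graphs)
})

test_that("rewiring destroys the lattice's triangles", {
  set.seed(3)
  below <- vapply(1:20, function(i) {
    g <- make_ws_graph(35, 10, 0.05)
    nulls <- random_nulls(g, count = 5)
    all(vapply(nulls$graphs, clustering_coefficient, numeric(1)) <
          clustering_coefficient(g))
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("small-worldness normalization behaves at its fixed points", {
  g <- make_ws_graph(35, 10, 0.1, seed = 4)
  self_ensemble <- structure(list(graphs = rep(list(g$adjacency), 5), count = 5,
                                  seed = NULL), class = "null_ensemble")
  m <- small_worldness(g, self_ensemble)
  expect_equal(m$gamma, 1)
  expect_equal(m$lambda, 1)
  expect_equal(m$sigma, 1)
  # sigma = gamma / lambda exactly, whatever the ensemble
  nulls <- random_nulls(g, 30, seed = 5)
  m2 <- small_worldness(g, nulls)
  expect_equal(m2$sigma * m2$lambda, m2$gamma, tolerance = 1e-12)
})

test_that("random graphs are their own null while lattice-like graphs are not", {
  set.seed(6)
  er_sigma <- mean(vapply(1:50, function(i) {
    z <- matrix(rnorm(35 * 35), 35); z <- z + t(z)
    g <- threshold_binarize(z, 0.3)
    small_worldness(g, random_nulls(g, 30))$sigma
  }, numeric(1)))
  expect_gt(er_sigma, 0.8)
  expect_lt(er_sigma, 1.2)

  ws_sigma <- mean(vapply(1:50, function(i) {
    g <- make_ws_graph(35, 10, 0.1)
    small_worldness(g, random_nulls(g, 30))$sigma
  }, numeric(1)))
  expect_gt(ws_sigma, 1.3)
})

test_that("a null ensemble member scores within the ensemble spread", {
  g <- make_ws_graph(35, 10, 0.2, seed = 7)
  nulls <- random_nulls(g, 30, seed = 8)
  member <- structure(list(adjacency = nulls$graphs[[1]], sparsity = NA,
                           n_edges = 175L), class = "binary_graph")
  m <- small_worldness(member, nulls)
  cn <- vapply(nulls$graphs, clustering_coefficient, numeric(1))
  ln <- vapply(nulls$graphs, char_path_length, numeric(1))
  expect_lt(abs(m$C - mean(cn)), 4 * stats::sd(cn))
  expect_lt(abs(m$L - mean(ln)), 4 * stats::sd(ln))
})

test_that("degree distributions are proper and centered correctly", {
  g <- make_ws_graph(35, 10, 0)
  pmf <- degree_distribution(g)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_equal(unname(pmf["10"]), 1)

  set.seed(9)
  ers <- lapply(1:400, function(i) {
    z <- matrix(rnorm(35 * 35), 35); z <- z + t(z)
    threshold_binarize(z, 0.3)
  })
  pmf <- degree_distribution(ers)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # modal degree at round(2 * 178 / 35) = 10
  expect_equal(as.integer(names(pmf)[which.max(pmf)]), 10)
  binned <- bin_degree_distribution(pmf)
  expect_named(binned, c("0-1", "6-15", "16-20"))
  expect_error(degree_distribution(list()), "empty")
})

test_that("lower sparsity yields higher small-worldness on clustered data", {
  set.seed(12)
  diffs <- vapply(1:15, function(i) {
    g <- make_ws_graph(35, 10, 0.1)
    rec <- gen_oxyhb(g, signal_gen_config(), 25)
    z <- fisher_z(correlation_matrix(rec$data))
    g01 <- threshold_binarize(z, 0.1)
    g03 <- threshold_binarize(z, 0.3)
    small_worldness(g01, random_nulls(g01, 10))$sigma -
      small_worldness(g03, random_nulls(g03, 10))$sigma
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("network recovery preserves the latent rewiring order of sigma", {
  set.seed(13)
  mean_sigma <- vapply(c(0.05, 0.5, 1.0), function(p) {
    mean(vapply(1:6, function(i) {
      g <- make_ws_graph(35, 10, p)
      rec <- gen_oxyhb(g, signal_gen_config(), 50)
      zs <- connectivity_series(rec, window_spec(640, 640))
      mean(vapply(zs, function(z) {
        g2 <- threshold_binarize(z, 0.3)
        small_worldness(g2, random_nulls(g2, 10))$sigma
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sigma) < 0))
})
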