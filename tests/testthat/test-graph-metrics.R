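test_that("metrics on canonical small graphs match hand enumeration", {
  p3 <- binary_graph(path_graph(3))
  k3 <- binary_graph(complete_graph(3))
  k5 <- binary_graph(complete_graph(5))
  star <- binary_graph(star_graph(4))

  d <- shortest_path_lengths(p3)
  expect_equal(d[1, 3], 2)
  expect_equal(clustering_coefficient(k3)$Cp, 1)
  expect_equal(clustering_coefficient(p3)$Cp, 0)
  expect_equal(characteristic_path_length(p3)$Lp, 4 / 3)
  expect_equal(characteristic_path_length(k5)$Lp, 1)
  expect_equal(characteristic_path_length(star)$Lp, 1.6)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(global_efficiency(p3), (1 + 1 + 0.5) / 3)
  expect_equal(global_efficiency(binary_graph(matrix(0L, 4, 4))), 0)
  expect_equal(local_efficiency(k3)$Eloc, 1)
  expect_equal(local_efficiency(star)$Eloc, 0)

  nm <- nodal_metrics(k5)
  expect_equal(unname(nm$Dnodal), rep(4, 5))
  expect_equal(unname(nm$Enodal), rep(1, 5))
  expect_equal(unname(nm$Bnodal), rep(0, 5))
  nms <- nodal_metrics(star)
  expect_equal(unname(nms$Bnodal[1]), choose(4, 2)) # hub routes all pairs
  expect_equal(unname(nms$Bnodal[-1]), rep(0, 4))   # leaves carry none

  # two disconnected dyads: cross distances are Inf
  dy <- matrix(0L, 4, 4)
  dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 1L
  dd <- shortest_path_lengths(binary_graph(dy))
  expect_true(is.infinite(dd[1, 3]))
  expect_error(characteristic_path_length(binary_graph(matrix(0L, 3, 3))),
               "Lp undefined")
})

test_that("all seven metrics agree with brute-force oracles on random graphs", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.2, 0.7))
    g <- binary_graph(adj)
    d <- shortest_path_lengths(g)
    expect_equal(unname(d), oracle_floyd_warshall(adj), tolerance = 1e-10)
    expect_equal(unname(clustering_coefficient(g)$values),
                 oracle_clustering(adj), tolerance = 1e-10)
    if (g$n_edges > 0) {
      expect_equal(characteristic_path_length(g)$Lp, oracle_lp(adj),
                   tolerance = 1e-10)
    }
    expect_equal(global_efficiency(g), oracle_global_eff(adj),
                 tolerance = 1e-10)
    expect_equal(unname(local_efficiency(g)$values), oracle_local_eff(adj),
                 tolerance = 1e-10)
    nm <- nodal_metrics(g)
    expect_equal(unname(nm$Dnodal), rowSums(adj), ignore_attr = TRUE)
    expect_equal(sum(nm$Dnodal), 2 * g$n_edges)
    expect_equal(unname(nm$Enodal), oracle_nodal_eff(adj), tolerance = 1e-10)
    expect_equal(unname(nm$Bnodal), oracle_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("degree-preserving rewiring keeps degrees and edge count exactly", {
  set.seed(11)
  adj <- random_adjacency(50, 0.15)
  g <- binary_graph(adj)
  r1 <- rewire_preserving_degree(g, rng_seed = 5)
  r2 <- rewire_preserving_degree(g, rng_seed = 5)
  r3 <- rewire_preserving_degree(g, rng_seed = 6)
  expect_identical(r1$adjacency, r2$adjacency)       # same seed, same graph
  expect_false(identical(r1$adjacency, r3$adjacency)) # different seed
  for (r in list(r1, r3)) {
    expect_equal(rowSums(r$adjacency), rowSums(adj), ignore_attr = TRUE)
    expect_equal(r$n_edges, g$n_edges)
    expect_equal(diag(r$adjacency), rep(0L, 50), ignore_attr = TRUE)
  }
  # complete graph admits no swap
  k5 <- binary_graph(complete_graph(5))
  expect_identical(rewire_preserving_degree(k5, rng_seed = 1)$adjacency,
                   k5$adjacency)
})

test_that("small-world normalization is exact on K5 and sane on ring lattices", {
  k5 <- binary_graph(complete_graph(5))
  m <- small_world_metrics(k5, n_random = 20, rng_seed = 1)
  expect_equal(m$Gamma, 1)
  expect_equal(m$Lambda, 1)
  expect_equal(m$Sigma, 1)
  expect_equal(m$Sigma, m$Gamma / m$Lambda, tolerance = 1e-10)

  set.seed(33)
  ws <- igraph::sample_smallworld(1, 60, 3, 0.1)
  adj <- (igraph::as_adjacency_matrix(igraph::simplify(ws),
                                      sparse = FALSE) > 0) * 1L
  mws <- small_world_metrics(binary_graph(adj), n_random = 30, rng_seed = 2)
  expect_gt(mws$Gamma, 1)
  expect_gt(mws$Sigma, 1)
  expect_equal(mws$Sigma, mws$Gamma / mws$Lambda, tolerance = 1e-10)
})

test_that("metric AUC follows the trapezoid rule", {
  s <- seq(0.10, 0.34, 0.01)
  expect_equal(metric_auc(rep(2, 25), s), 2 * 0.24, tolerance = 1e-12)
  expect_equal(metric_auc(s, s), (0.34^2 - 0.10^2) / 2, tolerance = 1e-12)
  expect_error(metric_auc(1:3, s), "equal length")
  expect_error(metric_auc(1, 0.1), "at least two")
})

test_that("network profiles integrate global and nodal curves across a sweep", {
  # all 25 graphs identical => AUC = 0.24 * single-graph value
  adj <- complete_graph(5)
  g <- binary_graph(adj)
  sw_const <- structure(list(sparsities = seq(0.10, 0.34, 0.01),
                             graphs = rep(list(g), 25)),
                        class = "sparsity_sweep")
  prof <- network_profile(sw_const, "functional_auc", n_random = 5,
                          rng_seed = 3)
  expect_equal(ncol(prof$curves$global), 7)
  expect_equal(nrow(prof$curves$global), 25)
  single <- small_world_metrics(g, n_random = 5, rng_seed = 3)
  for (mname in c("Cp", "Lp", "Eglob", "Eloc", "Gamma", "Lambda", "Sigma")) {
    expect_equal(unname(prof$global[mname]), 0.24 * single[[mname]],
                 tolerance = 1e-10)
  }
  expect_equal(dim(prof$nodal), c(5, 3))
  expect_equal(unname(prof$nodal[, "Dnodal"]), rep(0.24 * 4, 5),
               tolerance = 1e-10)

  # global efficiency is monotone non-decreasing along a nested sweep
  set.seed(9)
  n <- 30
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  m[ut] <- stats::runif(length(ut))
  m <- m + t(m)
  m <- m / max(m)
  diag(m) <- 0
  sw2 <- sparsity_sweep(connectivity_matrix(m, "correlation"))
  eg <- vapply(sw2$graphs, global_efficiency, numeric(1))
  expect_true(all(diff(eg) >= -1e-12))

  # structural mode returns the single-threshold profile
  pst <- network_profile(g, "structural_single_threshold", n_random = 5,
                         rng_seed = 1)
  expect_equal(pst$global$Gamma, 1)
  expect_s3_class(pst$nodal, "nodal_metrics")
})
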