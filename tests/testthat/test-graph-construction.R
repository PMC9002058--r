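test_that("connectivity_matrix enforces symmetry, zero diagonal and kind", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 5
  cm <- connectivity_matrix(m, "fiber_number")
  expect_s3_class(cm, "connectivity_matrix")

  bad <- m
  bad[1, 2] <- 4 # asymmetric
  expect_error(connectivity_matrix(bad, "fiber_number"), "not symmetric")

  negd <- m
  negd[1, 3] <- negd[3, 1] <- -2
  expect_error(connectivity_matrix(negd, "fiber_number"),
               "nonnegative integers")

  diag_bad <- m
  diag(diag_bad) <- 1
  expect_error(connectivity_matrix(diag_bad, "fiber_number"), "diagonal")

  toohot <- matrix(0, 2, 2)
  toohot[1, 2] <- toohot[2, 1] <- 1.5
  expect_error(connectivity_matrix(toohot, "correlation"), "\\[-1, 1\\]")
})

test_that("fiber-count thresholding applies the >= rule exactly", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 5
  m[1, 3] <- m[3, 1] <- 2
  m[2, 3] <- m[3, 2] <- 3
  g <- threshold_structural(connectivity_matrix(m, "fiber_number"))
  expect_equal(g$n_edges, 2)
  expect_equal(g$adjacency[1, 2], 1L)
  expect_equal(g$adjacency[2, 3], 1L)
  expect_equal(g$adjacency[1, 3], 0L)

  empty <- threshold_structural(
    connectivity_matrix(matrix(0, 4, 4), "fiber_number"))
  expect_equal(empty$n_edges, 0)
  expect_false(empty$connected)

  all3 <- matrix(3, 5, 5) - diag(3, 5)
  k5 <- threshold_structural(connectivity_matrix(all3, "fiber_number"))
  expect_equal(k5$n_edges, 10)
  expect_true(k5$connected)

  # min_fibers = 1 on strictly positive off-diagonal gives complete graph
  pos <- matrix(1, 6, 6) - diag(6)
  kall <- threshold_structural(connectivity_matrix(pos, "fiber_number"),
                               min_fibers = 1)
  expect_equal(kall$n_edges, choose(6, 2))
})

test_that("compute_fc matches Pearson correlation and flags bad input", {
  ts <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 1, 2))
  fc <- compute_fc(ts)
  expect_equal(fc$values[1, 2], 1)
  neg <- cbind(a = c(1, 2, 3), b = -c(1, 2, 3) + 5)
  expect_equal(compute_fc(neg)$values[1, 2], -1)
  # frozen from the covariance formula: cor((1,2,3),(1,3,2)) = 0.5
  pair <- cbind(x = c(1, 2, 3), y = c(1, 3, 2))
  expect_equal(compute_fc(pair)$values[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(diag(fc$values), rep(0, 3), ignore_attr = TRUE)

  expect_error(compute_fc(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant time series in region a")
  expect_error(compute_fc(cbind(a = c(1, 2), b = c(2, 1))), "3 time points")
})

test_that("fisher_z is arctanh with clipping at the boundary", {
  r <- matrix(0, 3, 3)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 1
  z <- fisher_z(connectivity_matrix(r, "correlation"))
  expect_equal(z$values[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(z$values[2, 3], 0)
  expect_true(is.finite(z$values[1, 3]))
  expect_equal(z$values[1, 3], atanh(1 - 1e-7))
  expect_equal(diag(z$values), rep(0, 3), ignore_attr = TRUE)
})

test_that("sparsity binarization keeps the K strongest positive edges", {
  set.seed(42)
  n <- 90
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  m[ut] <- stats::runif(length(ut), -1, 1)
  m <- (m + t(m))
  m <- m / max(abs(m))
  diag(m) <- 0
  cm <- connectivity_matrix(m, "correlation")
  g <- sparsity_binarize(cm, 0.10)
  expect_equal(g$n_edges, floor(0.10 * n * (n - 1) / 2)) # 400
  # no negative edge survives
  expect_true(all(m[g$adjacency == 1L] > 0))

  # 4-node example: the 3 largest of six distinct positive weights
  m4 <- matrix(0, 4, 4)
  w <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  m4[upper.tri(m4)] <- w
  m4 <- m4 + t(m4)
  g4 <- sparsity_binarize(connectivity_matrix(m4, "correlation"), 0.5)
  expect_equal(g4$n_edges, 3)
  kept <- m4[which(upper.tri(m4) & g4$adjacency == 1L)]
  expect_setequal(kept, c(0.9, 0.8, 0.7))

  # shortage: only 2 positive entries at sparsity 0.10 on N = 90
  sparse <- matrix(0, n, n)
  sparse[1, 2] <- sparse[2, 1] <- 0.5
  sparse[3, 4] <- sparse[4, 3] <- 0.4
  gs <- sparsity_binarize(connectivity_matrix(sparse, "correlation"), 0.10)
  expect_equal(gs$n_edges, 2)
  expect_equal(gs$sparsity, 2 / 4005)

  expect_error(sparsity_binarize(cm, 0), "\\(0, 1\\]")
  expect_error(sparsity_binarize(cm, 1.2), "\\(0, 1\\]")
})

test_that("binarization is idempotent and deterministic under ties", {
  m <- matrix(0, 6, 6)
  m[upper.tri(m)] <- c(0.5, 0.5, 0.5, 0.5, 0.2, 0.2, 0.2, 0.9, 0.9,
                       0.1, 0.1, 0.1, 0.3, 0.3, 0.3)
  m <- m + t(m)
  cm <- connectivity_matrix(m, "correlation")
  g1 <- sparsity_binarize(cm, 0.4)
  g2 <- sparsity_binarize(cm, 0.4)
  expect_identical(g1$adjacency, g2$adjacency)
  # re-threshold the binary graph at the same sparsity: identical graph
  cm_bin <- connectivity_matrix(g1$adjacency + 0, "correlation")
  g3 <- sparsity_binarize(cm_bin, 0.4)
  expect_identical(g3$adjacency, g1$adjacency)
})

test_that("sparsity sweep yields 25 nested graphs with monotone sparsity", {
  set.seed(7)
  n <- 40
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  m[ut] <- stats::runif(length(ut), -1, 1)
  m <- m + t(m)
  m <- m / max(abs(m))
  diag(m) <- 0
  cm <- connectivity_matrix(m, "correlation")
  sw <- sparsity_sweep(cm)
  expect_length(sw$sparsities, 25)
  expect_equal(sw$sparsities[1], 0.10)
  expect_equal(sw$sparsities[25], 0.34)
  realized <- vapply(sw$graphs, function(g) g$sparsity, numeric(1))
  expect_true(all(diff(realized) >= 0))
  expect_true(all(realized <= sw$sparsities + 1e-12))
  for (i in 2:25) {
    expect_true(all(sw$graphs[[i]]$adjacency >= sw$graphs[[i - 1]]$adjacency))
  }
  expect_error(sparsity_sweep(cm, s_min = 0.2, s_max = 0.2), "below")
})
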