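# Brute-force oracles, independent of the package's igraph-backed code
# paths: Floyd-Warshall distances, triangle enumeration, explicit
# shortest-path counting. Only used to check the real implementations.

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) links <- links + adj[nb[a], nb[b]]
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_lp <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  ut <- d[upper.tri(d)]
  mean(ut[is.finite(ut)])
}

oracle_global_eff <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_nodal_eff <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

# number of shortest i-j paths, by recursion on distance layers
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      pred <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  sigma <- oracle_path_counts(adj, d)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

# partial correlation oracle via inversion of the full correlation matrix
oracle_partial_cor <- function(x, y, z) {
  cm <- stats::cor(cbind(x, y, z))
  p <- solve(cm)
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

random_adjacency <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- stats::rbinom(length(ut), 1, p)
  a + t(a)
}

# label-permutation-matched agreement between two partitions
match_accuracy <- function(found, truth) {
  k <- max(truth)
  perms <- gtools_permutations(k)
  best <- 0
  for (r in seq_len(nrow(perms))) {
    acc <- mean(perms[r, found] == truth)
    if (acc > best) best <- acc
  }
  best
}

gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

complete_graph <- function(n) matrix(1L, n, n) - diag(n)

star_graph <- function(leaves) {
  a <- matrix(0L, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  a
}
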