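#' Taxon count table
#'
#' Samples-by-taxa matrix of nonnegative integer counts (OTU or genus
#' level). Every sample must have a positive total.
#'
#' @param counts S x G integer matrix; rows samples, columns taxa.
#' @param level `"otu"` or `"genus"`.
#' @param sample_ids,taxon_ids Optional identifiers (default from dimnames).
#' @return Object of class `count_table`.
#' @export
count_table <- function(counts, level = c("genus", "otu"),
                        sample_ids = NULL, taxon_ids = NULL) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- colnames(counts)
  if (is.null(taxon_ids)) taxon_ids <- sprintf("T%03d", seq_len(ncol(counts)))
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop(sprintf("sample %s has zero total count", sample_ids[tot == 0][1]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 taxon_ids = taxon_ids, level = level),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa (%s level)\n",
              nrow(x$counts), ncol(x$counts), x$level))
  invisible(x)
}

#' Relative abundances
#'
#' Row-normalizes counts to probabilities summing to one per sample.
#'
#' @param x A [count_table()], count matrix, or single count vector.
#' @return Matrix (or vector) of relative abundances.
#' @export
relative_abundance <- function(x) {
  if (inherits(x, "count_table")) x <- x$counts
  if (is.null(dim(x))) {
    if (sum(x) == 0) stop("zero-total sample", call. = FALSE)
    return(x / sum(x))
  }
  tot <- rowSums(x)
  if (any(tot == 0)) {
    bad <- rownames(x)[tot == 0][1]
    if (is.null(bad)) bad <- as.character(which(tot == 0)[1])
    stop(sprintf("sample %s has zero total count", bad), call. = FALSE)
  }
  sweep(x, 1, tot, "/")
}

#' Shannon diversity index (nats)
#'
#' H = -sum p_i ln p_i: the average uncertainty in predicting the taxon of
#' a randomly drawn individual; increases with richness and evenness.
#' Counts are accepted and normalized internally.
#'
#' @param p Probability (or count) vector, or a [count_table()] /
#'   matrix for per-sample values.
#' @return Scalar, or per-sample named vector.
#' @export
shannon <- function(p) {
  if (inherits(p, "count_table")) p <- p$counts
  vegan::diversity(p, index = "shannon")
}

#' Simpson dominance index
#'
#' D = sum p_i^2: the probability that two randomly drawn individuals
#' belong to the same taxon; lies in (0, 1] and decreases as diversity
#' increases.
#'
#' @inheritParams shannon
#' @return Scalar, or per-sample named vector.
#' @export
simpson <- function(p) {
  if (inherits(p, "count_table")) p <- p$counts
  1 - vegan::diversity(p, index = "simpson")
}

#' Jensen-Shannon divergence (nats)
#'
#' JSD(p, q) = KL(p||m)/2 + KL(q||m)/2 with m = (p+q)/2; symmetric,
#' bounded by ln 2. The clustering distance used for enterotyping is
#' sqrt(JSD), a metric.
#'
#' @param p,q Probability vectors of equal length.
#' @return Divergence in nats.
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' sqrt-JSD distance matrix between samples
#'
#' @param ra Samples x taxa relative-abundance matrix.
#' @return Symmetric S x S matrix of sqrt(JSD) distances.
#' @export
jsd_dist <- function(ra) {
  s <- nrow(ra)
  d <- matrix(0, s, s, dimnames = list(rownames(ra), rownames(ra)))
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      d[i, j] <- d[j, i] <- sqrt(max(jsd(ra[i, ], ra[j, ]), 0))
    }
  }
  d
}

#' Partitioning around medoids on a distance matrix
#'
#' Thin, seeded wrapper around the classical PAM build + swap algorithm.
#'
#' @param dist S x S symmetric distance matrix (zero diagonal).
#' @param k Number of clusters, 2 <= k < S (k = S allowed: each sample its
#'   own medoid).
#' @param rng_seed Optional seed (PAM itself is deterministic; the seed
#'   pins any RNG state for reproducible pipelines).
#' @return List with `labels` (1..k per sample) and `medoids` (sample ids).
#' @export
pam_cluster <- function(dist, k, rng_seed = NULL) {
  dist <- as.matrix(dist)
  if (any(dist < 0) || any(abs(dist - t(dist)) > 1e-10) ||
      any(diag(dist) != 0)) {
    stop("`dist` must be symmetric, nonnegative, zero-diagonal",
         call. = FALSE)
  }
  s <- nrow(dist)
  if (k < 2 || k > s) stop("`k` must satisfy 2 <= k <= S", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (k == s) {
    ids <- rownames(dist)
    if (is.null(ids)) ids <- as.character(seq_len(s))
    return(list(labels = seq_len(s), medoids = ids))
  }
  fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(s))
  list(labels = unname(fit$clustering), medoids = ids[fit$id.med])
}

# Calinski-Harabasz index of a partition, computed on a classical MDS
# embedding of the distance matrix (positive-eigenvalue axes only).
ch_index <- function(embedding, labels) {
  n <- nrow(embedding)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  centroid <- colMeans(embedding)
  ssb <- 0
  ssw <- 0
  for (cl in unique(labels)) {
    pts <- embedding[labels == cl, , drop = FALSE]
    cc <- colMeans(pts)
    ssb <- ssb + nrow(pts) * sum((cc - centroid)^2)
    ssw <- ssw + sum(sweep(pts, 2, cc)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Enterotype samples
#'
#' Clusters gut community profiles by partitioning around medoids on
#' sqrt Jensen-Shannon distances, selecting the cluster number by the
#' Calinski-Harabasz index over candidate k (the classical enterotyping
#' recipe). Each cluster's driver taxon is the taxon with the largest
#' between-cluster mean-abundance contrast.
#'
#' @param table [count_table()] at genus level, >= 10 samples.
#' @param k_candidates Candidate cluster counts (default 2:6).
#' @param fixed_k Optional fixed cluster count, bypassing selection.
#' @param rng_seed Optional seed.
#' @return Object of class `enterotype_assignment`: `labels`, `k`,
#'   `medoids`, `driver_taxa`, `ch_scores`, and `weak_clustering` (largest
#'   CH margin over the runner-up below 10%).
#' @export
enterotype <- function(table, k_candidates = 2:6, fixed_k = NULL,
                       rng_seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  s <- nrow(table$counts)
  if (s < 10) stop("need at least 10 samples to enterotype", call. = FALSE)
  ra <- relative_abundance(table)
  d <- jsd_dist(ra)
  emb <- stats::cmdscale(stats::as.dist(d), k = min(s - 1, 10))
  fits <- lapply(k_candidates, function(k) pam_cluster(d, k, rng_seed))
  ch <- vapply(seq_along(k_candidates), function(i)
    ch_index(emb, fits[[i]]$labels), numeric(1))
  names(ch) <- paste0("k", k_candidates)
  if (!is.null(fixed_k)) {
    if (!fixed_k %in% k_candidates) {
      fits <- c(fits, list(pam_cluster(d, fixed_k, rng_seed)))
      k_candidates <- c(k_candidates, fixed_k)
    }
    best <- which(k_candidates == fixed_k)
  } else {
    best <- which.max(ch)
  }
  fit <- fits[[best]]
  k <- k_candidates[best]
  # weak clustering: no candidate clearly dominates the others
  sorted <- sort(ch, decreasing = TRUE)
  weak <- length(sorted) > 1 && (sorted[1] - sorted[2]) / sorted[1] < 0.10
  drivers <- vapply(seq_len(k), function(cl) {
    inside <- colMeans(ra[fit$labels == cl, , drop = FALSE])
    outside <- colMeans(ra[fit$labels != cl, , drop = FALSE])
    table$taxon_ids[which.max(inside - outside)]
  }, character(1))
  structure(list(labels = fit$labels, k = k, medoids = fit$medoids,
                 driver_taxa = drivers, ch_scores = ch,
                 weak_clustering = weak),
            class = "enterotype_assignment")
}

#' @export
print.enterotype_assignment <- function(x, ...) {
  cat(sprintf("<enterotype_assignment> k = %d (%s)\n", x$k,
              if (x$weak_clustering) "weak clustering" else "clear"))
  cat("driver taxa:", paste(x$driver_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Label-permutation-matched partition agreement
#'
#' Fraction of samples on which two cluster labelings agree, maximized
#' over relabelings of the first partition; used to score enterotype
#' recovery against planted components.
#'
#' @param found,truth Integer label vectors of equal length.
#' @return Agreement fraction in \[0, 1\].
#' @export
partition_agreement <- function(found, truth) {
  stopifnot(length(found) == length(truth))
  ks <- sort(unique(found))
  perms <- all_permutations(length(ks))
  best <- 0
  for (r in seq_len(nrow(perms))) {
    relab <- ks[perms[r, match(found, ks)]]
    acc <- mean(relab == truth)
    if (acc > best) best <- acc
  }
  best
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(sub[, seq_len(i - 1), drop = FALSE], k,
          sub[, seq_len(k - i) + i - 1, drop = FALSE])
  }))
}

#' Species accumulation curve
#'
#' Mean cumulative richness as samples are accumulated in random order,
#' averaged over permutations; used to judge sampling sufficiency.
#'
#' @param table [count_table()], >= 2 samples.
#' @param n_perm Number of sample-order permutations (default 100).
#' @param rng_seed Optional seed.
#' @return Numeric vector: mean distinct-taxon count after 1..S samples.
#' @export
species_accumulation <- function(table, n_perm = 100, rng_seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (nrow(table$counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sac <- vegan::specaccum(table$counts, method = "random",
                          permutations = n_perm)
  as.numeric(sac$richness)
}
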