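#' Binary graph
#'
#' Undirected, unweighted graph on N nodes, the object every topological
#' metric consumes. Stored as a 0/1 adjacency matrix.
#'
#' @param adjacency 0/1 symmetric matrix with zero diagonal.
#' @param region_labels Optional node names.
#' @return Object of class `binary_graph`: list with `adjacency`, `n_nodes`,
#'   `n_edges`, `connected` (single component reaching every node) and
#'   `sparsity` (edges / possible pairs).
#' @export
binary_graph <- function(adjacency, region_labels = NULL) {
  if (!is.matrix(adjacency)) stop("`adjacency` must be a matrix", call. = FALSE)
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  }
  if (any(adjacency != t(adjacency))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("adjacency diagonal must be zero", call. = FALSE)
  }
  n <- nrow(adjacency)
  if (is.null(region_labels)) {
    region_labels <- rownames(adjacency)
    if (is.null(region_labels)) region_labels <- default_region_labels(n)
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(region_labels, region_labels)
  n_edges <- sum(adjacency) / 2
  g <- structure(list(adjacency = adjacency, n_nodes = n, n_edges = n_edges,
                      connected = NA, sparsity = NA_real_,
                      region_labels = region_labels),
                 class = "binary_graph")
  g$connected <- if (n_edges == 0) n == 1L else
    igraph::is_connected(bg_igraph(g))
  g$sparsity <- if (n > 1) n_edges / (n * (n - 1) / 2) else 0
  g
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %.4f), %s\n",
              x$n_nodes, x$n_edges, x$sparsity,
              if (isTRUE(x$connected)) "connected" else "disconnected"))
  invisible(x)
}

bg_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Threshold a fiber-number matrix into a binary structural graph
#'
#' Two regions are structurally connected when the streamline (fiber) count
#' between them reaches `min_fibers`; the default of 3 suppresses spurious
#' single-streamline connections.
#'
#' @param fn `connectivity_matrix` of kind `fiber_number`.
#' @param min_fibers Minimum fiber count for an edge (default 3).
#' @return A [binary_graph()]; its `connected` field flags whether the
#'   thresholded network forms a single component.
#' @export
threshold_structural <- function(fn, min_fibers = 3) {
  stopifnot(inherits(fn, "connectivity_matrix"))
  if (fn$kind != "fiber_number") {
    stop("`fn` must be a fiber_number connectivity matrix", call. = FALSE)
  }
  if (min_fibers <= 0) stop("`min_fibers` must be positive", call. = FALSE)
  adj <- (fn$values >= min_fibers) * 1L
  diag(adj) <- 0L
  binary_graph(adj, fn$region_labels)
}

#' Functional connectivity from regional time series
#'
#' Pearson correlation of every pair of regional BOLD time series; the
#' diagonal is set to zero.
#'
#' @param timeseries T x N numeric matrix (time points by regions), T >= 3.
#' @param region_labels Optional region names (defaults to column names).
#' @return `connectivity_matrix` of kind `correlation`.
#' @export
compute_fc <- function(timeseries, region_labels = NULL) {
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    lab <- colnames(ts)[which(sds == 0)[1]]
    if (is.null(lab)) lab <- as.character(which(sds == 0)[1])
    stop(sprintf("constant time series in region %s", lab), call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- colnames(ts)
  r <- stats::cor(ts)
  # clamp round-off so entries stay within [-1, 1]
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 0
  connectivity_matrix(unname(r), kind = "correlation",
                      region_labels = region_labels)
}

#' Fisher z-transformation of a correlation matrix
#'
#' Elementwise arctanh, variance-stabilizing FC values. Magnitudes are
#' clipped just below 1 so that perfect correlations map to a large finite z.
#'
#' @param fc `connectivity_matrix` of kind `correlation`.
#' @param clip Magnitude bound applied before arctanh (default `1 - 1e-7`).
#' @return `connectivity_matrix` of kind `fisher_z`.
#' @export
fisher_z <- function(fc, clip = 1 - 1e-7) {
  stopifnot(inherits(fc, "connectivity_matrix"))
  if (fc$kind != "correlation") {
    stop("`fc` must be a correlation connectivity matrix", call. = FALSE)
  }
  z <- atanh(pmin(pmax(fc$values, -clip), clip))
  diag(z) <- 0
  connectivity_matrix(unname(z), kind = "fisher_z",
                      region_labels = fc$region_labels)
}

# Deterministic ranking of the upper-triangle edge weights: descending
# weight, ties broken by smaller row then smaller column index.
edge_ranking <- function(values, include_negative = FALSE) {
  n <- nrow(values)
  ut <- which(upper.tri(values))
  rows <- row(values)[ut]
  cols <- col(values)[ut]
  w <- values[ut]
  if (include_negative) w <- abs(w)
  keep <- w > 0
  ord <- order(-w[keep], rows[keep], cols[keep])
  list(rows = rows[keep][ord], cols = cols[keep][ord], n = n)
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Retains the K = floor(sparsity * N(N-1)/2) strongest positive edges
#' (negative correlations never become edges unless `include_negative`
#' ranks by magnitude). Ties at the cutoff are broken by node index, so the
#' graph is fully deterministic. When fewer than K positive weights exist,
#' all of them are retained and the realized sparsity is recorded.
#'
#' @param cm `connectivity_matrix` (any kind).
#' @param sparsity Target fraction of retained edges, in (0, 1].
#' @param include_negative Rank edges by absolute weight instead of
#'   excluding negative ones (off by default).
#' @return [binary_graph()] whose `sparsity` field holds the realized value.
#' @export
sparsity_binarize <- function(cm, sparsity, include_negative = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity > 1) {
    stop("`sparsity` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(cm$values)
  k_budget <- floor(sparsity * n * (n - 1) / 2)
  rk <- edge_ranking(cm$values, include_negative)
  k <- min(k_budget, length(rk$rows))
  adj <- matrix(0L, n, n)
  if (k > 0) {
    sel <- cbind(rk$rows[seq_len(k)], rk$cols[seq_len(k)])
    adj[sel] <- 1L
    adj[sel[, 2:1, drop = FALSE]] <- 1L
  }
  binary_graph(adj, cm$region_labels)
}

#' Sparsity sweep
#'
#' Binarizes a connectivity matrix over a grid of sparsity thresholds
#' (default 0.10 to 0.34 in steps of 0.01, 25 graphs). Because the edge
#' ranking is fixed, the graphs are nested: every edge present at a lower
#' sparsity is present at all higher ones.
#'
#' @inheritParams sparsity_binarize
#' @param s_min,s_max,step Sweep range and increment.
#' @return Object of class `sparsity_sweep`: list with `sparsities` and
#'   `graphs` (one [binary_graph()] per threshold).
#' @export
sparsity_sweep <- function(cm, s_min = 0.10, s_max = 0.34, step = 0.01,
                           include_negative = FALSE) {
  if (s_min >= s_max) stop("`s_min` must be below `s_max`", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  sparsities <- round(seq(s_min, s_max, by = step), 10)
  graphs <- lapply(sparsities, sparsity_binarize, cm = cm,
                   include_negative = include_negative)
  structure(list(sparsities = sparsities, graphs = graphs),
            class = "sparsity_sweep")
}

#' @export
print.sparsity_sweep <- function(x, ...) {
  cat(sprintf("<sparsity_sweep> %d thresholds in [%.2f, %.2f]\n",
              length(x$sparsities), min(x$sparsities), max(x$sparsities)))
  invisible(x)
}
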