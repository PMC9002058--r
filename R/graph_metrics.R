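#' Hop distances between all node pairs
#'
#' Breadth-first shortest-path lengths of a binary graph. Unreachable pairs
#' carry `Inf`.
#'
#' @param g [binary_graph()].
#' @return N x N numeric matrix, zero diagonal, symmetric.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- igraph::distances(bg_igraph(g))
  dimnames(d) <- list(g$region_labels, g$region_labels)
  d
}

#' Clustering coefficient
#'
#' Per-node interconnectedness of a node's direct neighbors:
#' 2 * triangles(i) / (k_i (k_i - 1)), defined as 0 for degree < 2. `Cp` is
#' the mean over all nodes.
#'
#' @param g [binary_graph()].
#' @return List with `values` (per node) and `Cp`.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  v <- igraph::transitivity(bg_igraph(g), type = "localundirected",
                            isolates = "zero")
  names(v) <- g$region_labels
  list(values = v, Cp = mean(v))
}

#' Characteristic path length
#'
#' Mean hop distance over all reachable unordered node pairs. Disconnected
#' pairs are excluded; the returned `connected` flag records whether any
#' pair was excluded. An edgeless graph has no reachable pair and errors.
#'
#' @param g [binary_graph()].
#' @return List with `Lp` and `connected`.
#' @export
characteristic_path_length <- function(g) {
  d <- shortest_path_lengths(g)
  ut <- d[upper.tri(d)]
  reach <- is.finite(ut)
  if (!any(reach)) stop("Lp undefined: graph has no reachable pair",
                        call. = FALSE)
  list(Lp = mean(ut[reach]), connected = all(reach))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with
#' unreachable pairs contributing zero; the efficiency of information
#' transfer through the entire graph.
#'
#' @param g [binary_graph()].
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  if (n < 2 || g$n_edges == 0) return(0)
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# all-pairs hop distances of a small dense adjacency via boolean matrix
# powers; cheap for the neighbor subgraphs local efficiency needs
dist_small <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  cur <- adj > 0
  step <- 1
  while (step < n) {
    cur <- (cur %*% adj) > 0
    step <- step + 1
    newly <- cur & !is.finite(d)
    if (!any(newly)) break
    d[newly] <- step
  }
  d
}

efficiency_of_adj <- function(adj) {
  n <- nrow(adj)
  if (n < 2 || sum(adj) == 0) return(0)
  inv <- 1 / dist_small(adj)
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its direct
#' neighbors (0 when degree < 2); `Eloc` is the mean over nodes.
#'
#' @param g [binary_graph()].
#' @return List with `values` (per node) and `Eloc`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  vals <- vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2) return(0)
    efficiency_of_adj(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  names(vals) <- g$region_labels
  list(values = vals, Eloc = mean(vals))
}

#' Nodal metrics: degree, efficiency, betweenness
#'
#' Degree centrality (edge count), nodal efficiency (mean inverse distance
#' to every other node) and unnormalized betweenness centrality (fraction
#' of shortest paths through the node, summed over unordered source-target
#' pairs).
#'
#' @param g [binary_graph()].
#' @return Object of class `nodal_metrics`: list of per-node vectors
#'   `Dnodal`, `Enodal`, `Bnodal`.
#' @export
nodal_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  deg <- rowSums(g$adjacency)
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  en <- rowSums(inv) / (n - 1)
  bn <- igraph::betweenness(bg_igraph(g), directed = FALSE, normalized = FALSE)
  names(deg) <- names(en) <- names(bn) <- g$region_labels
  structure(list(Dnodal = deg, Enodal = en, Bnodal = bn),
            class = "nodal_metrics")
}

#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Double-edge swaps that preserve each node's degree exactly, producing
#' the null networks used to normalize Cp and Lp. Seeded and reproducible.
#'
#' @param g [binary_graph()].
#' @param n_swaps Number of swap attempts (default 10 x edges).
#' @param rng_seed Optional integer seed.
#' @return Rewired [binary_graph()] with the same degree sequence.
#' @export
rewire_preserving_degree <- function(g, n_swaps = NULL, rng_seed = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  if (is.null(n_swaps)) n_swaps <- 10 * g$n_edges
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ig <- bg_igraph(g)
  if (g$n_edges < 2) {
    warning("graph too small to swap; returning a copy")
    return(g)
  }
  rw <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                  niter = n_swaps))
  adj <- igraph::as_adjacency_matrix(rw, sparse = FALSE)
  binary_graph((adj > 0) * 1L, g$region_labels)
}

#' Small-world metrics with random-network normalization
#'
#' Cp and Lp of the graph are divided by their means over `n_random`
#' degree-preserving rewired null networks, giving the normalized
#' clustering coefficient (Gamma), normalized characteristic path length
#' (Lambda) and small-worldness Sigma = Gamma/Lambda; Sigma > 1 indicates
#' small-world topology. Global and local efficiency are returned
#' alongside.
#'
#' @param g [binary_graph()].
#' @param n_random Number of null networks (default 100).
#' @param rng_seed Integer seed for the null ensemble.
#' @return Object of class `global_metrics`: list with `Cp`, `Lp`, `Eglob`,
#'   `Eloc`, `Gamma`, `Lambda`, `Sigma`, plus `connected` and
#'   `n_null_excluded`.
#' @export
small_world_metrics <- function(g, n_random = 100, rng_seed = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  cp <- clustering_coefficient(g)$Cp
  lp_res <- characteristic_path_length(g)
  eglob <- global_efficiency(g)
  eloc <- local_efficiency(g)$Eloc
  if (!is.null(rng_seed)) set.seed(rng_seed)
  null_cp <- numeric(n_random)
  null_lp <- numeric(n_random)
  excluded <- 0L
  ig <- bg_igraph(g)
  can_swap <- g$n_edges >= 2
  n_swaps <- 10 * g$n_edges
  for (i in seq_len(n_random)) {
    nullg <- if (can_swap) {
      igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                niter = n_swaps))
    } else ig
    null_cp[i] <- mean(igraph::transitivity(nullg, type = "localundirected",
                                            isolates = "zero"))
    # mean shortest path over reachable pairs; NaN when no pair reachable
    lp_i <- suppressWarnings(igraph::mean_distance(nullg,
                                                   unconnected = TRUE))
    if (!is.finite(lp_i)) {
      lp_i <- NA_real_
      excluded <- excluded + 1L
    }
    null_lp[i] <- lp_i
  }
  if (excluded > 0.10 * n_random) {
    stop(sprintf("%d of %d null networks had undefined Lp", excluded,
                 n_random), call. = FALSE)
  }
  gamma <- cp / mean(null_cp, na.rm = TRUE)
  lambda <- lp_res$Lp / mean(null_lp, na.rm = TRUE)
  structure(list(Cp = cp, Lp = lp_res$Lp, Eglob = eglob, Eloc = eloc,
                 Gamma = gamma, Lambda = lambda, Sigma = gamma / lambda,
                 connected = lp_res$connected, n_null_excluded = excluded),
            class = "global_metrics")
}

#' Area under a metric curve across the sparsity sweep
#'
#' Trapezoidal integral of a topological metric over the sparsity interval,
#' the threshold-independent scalar summary used for functional networks.
#'
#' @param curve_values Metric value at each sparsity.
#' @param sparsities Increasing sparsity fractions (same length, >= 2).
#' @return Scalar AUC.
#' @export
metric_auc <- function(curve_values, sparsities) {
  if (length(curve_values) != length(sparsities)) {
    stop("`curve_values` and `sparsities` must have equal length",
         call. = FALSE)
  }
  if (length(sparsities) < 2) {
    stop("need at least two thresholds for an AUC", call. = FALSE)
  }
  if (any(diff(sparsities) <= 0)) {
    stop("`sparsities` must be strictly increasing", call. = FALSE)
  }
  pracma::trapz(sparsities, curve_values)
}

global_metric_names <- c("Cp", "Lp", "Eglob", "Eloc", "Gamma", "Lambda",
                         "Sigma")
nodal_metric_names <- c("Dnodal", "Enodal", "Bnodal")

#' Full topological profile of a subject's network(s)
#'
#' Structural networks are profiled at the single fiber-count threshold;
#' functional networks are profiled at every sparsity of a sweep and each
#' metric is summarized by its AUC.
#'
#' @param x A [binary_graph()] (structural mode) or [sparsity_sweep()]
#'   (functional mode).
#' @param mode `"structural_single_threshold"` or `"functional_auc"`.
#' @param n_random Null networks per small-world normalization.
#' @param rng_seed Integer seed.
#' @return Structural mode: list with `global` ([small_world_metrics()])
#'   and `nodal` ([nodal_metrics()]). Functional mode: list with `global`
#'   (named AUC vector), `nodal` (region x metric AUC matrix) and `curves`
#'   (per-sparsity values).
#' @export
network_profile <- function(x,
                            mode = c("structural_single_threshold",
                                     "functional_auc"),
                            n_random = 100, rng_seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "structural_single_threshold") {
    stopifnot(inherits(x, "binary_graph"))
    return(list(global = small_world_metrics(x, n_random, rng_seed),
                nodal = nodal_metrics(x)))
  }
  stopifnot(inherits(x, "sparsity_sweep"))
  ns <- length(x$sparsities)
  n <- x$graphs[[1]]$n_nodes
  glob <- matrix(NA_real_, ns, length(global_metric_names),
                 dimnames = list(NULL, global_metric_names))
  nod <- lapply(nodal_metric_names, function(m)
    matrix(NA_real_, n, ns,
           dimnames = list(x$graphs[[1]]$region_labels, NULL)))
  names(nod) <- nodal_metric_names
  if (!is.null(rng_seed)) set.seed(rng_seed)
  for (i in seq_len(ns)) {
    g <- x$graphs[[i]]
    gm <- small_world_metrics(g, n_random, rng_seed = NULL)
    glob[i, ] <- unlist(gm[global_metric_names])
    nm <- nodal_metrics(g)
    for (m in nodal_metric_names) nod[[m]][, i] <- nm[[m]]
  }
  global_auc <- apply(glob, 2, metric_auc, sparsities = x$sparsities)
  nodal_auc <- vapply(nod, function(mat)
    apply(mat, 1, metric_auc, sparsities = x$sparsities),
    numeric(n))
  list(global = global_auc, nodal = nodal_auc,
       curves = list(sparsities = x$sparsities, global = glob, nodal = nod))
}
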