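#' Per-region structure-function coupling
#'
#' For each region, the non-zero structural edges incident to it are
#' log-transformed and correlated (Pearson) with the functional values of
#' the same edges, yielding one coupling coefficient r per region. Regions
#' with fewer than `min_edges` usable edges, or with zero variance on
#' either side, carry `NA`.
#'
#' @param sc `connectivity_matrix` of kind `fiber_number`.
#' @param fc `connectivity_matrix` of kind `fisher_z` (default) or
#'   `correlation`; same dimension and region order as `sc`.
#' @param min_edges Minimum incident edges for a defined correlation
#'   (default 5).
#' @param subject_id Optional identifier carried in the result.
#' @return Object of class `coupling_profile`: list with `r_values` (length
#'   N, `NA` where undefined), `n_edges_used` and `subject_id`.
#' @export
regional_coupling <- function(sc, fc, min_edges = 5, subject_id = NA_character_) {
  stopifnot(inherits(sc, "connectivity_matrix"),
            inherits(fc, "connectivity_matrix"))
  if (sc$kind != "fiber_number") {
    stop("`sc` must be a fiber_number matrix", call. = FALSE)
  }
  if (!identical(dim(sc$values), dim(fc$values)) ||
      !identical(sc$region_labels, fc$region_labels)) {
    stop("`sc` and `fc` must share dimension and region order", call. = FALSE)
  }
  n <- nrow(sc$values)
  r <- rep(NA_real_, n)
  used <- integer(n)
  for (i in seq_len(n)) {
    j <- which(sc$values[i, ] > 0)
    j <- j[j != i]
    used[i] <- length(j)
    if (length(j) < min_edges) next
    x <- log(sc$values[i, j])
    y <- fc$values[i, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i] <- NA_real_
      next
    }
    r[i] <- stats::cor(x, y)
  }
  names(r) <- names(used) <- sc$region_labels
  structure(list(r_values = r, n_edges_used = used, subject_id = subject_id),
            class = "coupling_profile")
}

#' Cohort coupling table
#'
#' Computes [regional_coupling()] for a cohort of (SC, FC) matrix pairs and
#' returns one tidy row per subject x region; missing couplings stay `NA`.
#'
#' @param pairs Named list; each element a list with components `sc` and
#'   `fc`.
#' @param min_edges Passed to [regional_coupling()].
#' @return `data.frame` with columns `subject`, `region`, `r`,
#'   `n_edges_used`.
#' @export
coupling_table <- function(pairs, min_edges = 5) {
  stopifnot(length(pairs) > 0)
  labels <- pairs[[1]]$sc$region_labels
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(pairs))
  out <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    if (!identical(p$sc$region_labels, labels)) {
      stop(sprintf("subject %s has inconsistent region labels", ids[k]),
           call. = FALSE)
    }
    cp <- regional_coupling(p$sc, p$fc, min_edges, subject_id = ids[k])
    data.frame(subject = ids[k], region = labels, r = unname(cp$r_values),
               n_edges_used = unname(cp$n_edges_used),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
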