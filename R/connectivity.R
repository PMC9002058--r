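#' AAL-90 region labels
#'
#' Short names of the 90 cerebral regions of the Automated Anatomical
#' Labeling atlas (45 bilateral pairs, left/right interleaved), the default
#' node set of all connectivity matrices in this package.
#'
#' @return Character vector of length 90.
#' @export
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

default_region_labels <- function(n) {
  if (n == 90L) aal90_labels() else sprintf("R%03d", seq_len(n))
}

#' Connectivity matrix
#'
#' Container for a symmetric region-by-region connectivity matrix with a
#' zero diagonal. Three kinds are distinguished: `fiber_number` (integer
#' streamline counts from tractography, the structural edge weight),
#' `correlation` (Pearson functional connectivity in \[-1, 1\]) and
#' `fisher_z` (arctanh-transformed correlations).
#'
#' @param values Square numeric matrix, symmetric with zero diagonal.
#' @param kind One of `"fiber_number"`, `"correlation"`, `"fisher_z"`.
#' @param region_labels Character vector of region names; defaults to the
#'   AAL-90 labels when the matrix is 90 x 90.
#'
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `values`, `kind`, `region_labels`.
#' @export
connectivity_matrix <- function(values,
                                kind = c("fiber_number", "correlation",
                                         "fisher_z"),
                                region_labels = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (ncol(values) != n) stop("`values` must be square", call. = FALSE)
  asym <- abs(values - t(values))
  if (any(asym > 1e-10)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix not symmetric: cell (%d, %d) differs from (%d, %d)",
                 idx[1], idx[2], idx[2], idx[1]), call. = FALSE)
  }
  if (any(diag(values) != 0)) {
    stop(sprintf("diagonal must be exactly zero (region %d is not)",
                 which(diag(values) != 0)[1]), call. = FALSE)
  }
  if (kind == "fiber_number") {
    bad <- which(values < 0 | abs(values - round(values)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "fiber_number entries must be nonnegative integers: cell (%d, %d)",
        bad[1, 1], bad[1, 2]), call. = FALSE)
    }
  }
  if (kind == "correlation" && any(values < -1 | values > 1)) {
    bad <- which(values < -1 | values > 1, arr.ind = TRUE)
    stop(sprintf("correlation entries must lie in [-1, 1]: cell (%d, %d)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  if (length(region_labels) != n) {
    stop("`region_labels` length must match matrix dimension", call. = FALSE)
  }
  # enforce exact symmetry so downstream thresholding cannot drift
  values <- (values + t(values)) / 2
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, kind = kind,
                 region_labels = region_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Read / write a connectivity matrix as TSV
#'
#' Plain TSV dialect: one header row of region labels, N data rows. Values
#' are written at full double precision so a write/read round trip is exact.
#'
#' @param path File path.
#' @param kind Matrix kind, as in [connectivity_matrix()].
#' @return `read_connectivity_matrix` returns a `connectivity_matrix`;
#'   `write_connectivity_matrix` returns `path` invisibly.
#' @export
read_connectivity_matrix <- function(path, kind = "fiber_number") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab)
  connectivity_matrix(unname(m), kind = kind,
                      region_labels = colnames(tab))
}

#' @rdname read_connectivity_matrix
#' @param cm A `connectivity_matrix`.
#' @export
write_connectivity_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  txt <- apply(cm$values, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(c(paste(cm$region_labels, collapse = "\t"), txt), path)
  invisible(path)
}
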