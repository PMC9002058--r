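#' Read / write taxon count tables
#'
#' TSV in either orientation: taxa as rows (QIIME-classic; header sentinel
#' `taxon_id` in the first column) or samples as rows (sentinel
#' `sample_id`). Both parse to the same samples-by-taxa [count_table()].
#'
#' @param path File path.
#' @param level Passed to [count_table()].
#' @return A [count_table()].
#' @export
read_count_table <- function(path, level = "genus") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]][1]
  m <- as.matrix(tab)
  if (identical(first, "taxon_id")) {
    m <- t(m)
  } else if (!identical(first, "sample_id")) {
    stop(sprintf(
      "unrecognized orientation sentinel '%s' (expected taxon_id or sample_id)",
      first), call. = FALSE)
  }
  count_table(m, level = level)
}

#' @rdname read_count_table
#' @param table A [count_table()].
#' @param orientation `"taxa"` (rows are taxa) or `"samples"`.
#' @export
write_count_table <- function(table, path, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(table, "count_table"))
  if (orientation == "taxa") {
    m <- t(table$counts)
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  } else {
    m <- table$counts
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write subject metadata
#'
#' TSV with a `subject_id` column plus covariate and score columns; any
#' missing cell is an error naming the subject and column.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("metadata must contain a subject_id column", call. = FALSE)
  }
  na_cells <- which(is.na(df), arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    stop(sprintf("missing value for subject %s in column %s",
                 df$subject_id[na_cells[1, 1]],
                 names(df)[na_cells[1, 2]]), call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param df Metadata `data.frame`.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `counts.tsv`, `sc/<subject>.tsv`, `fc/<subject>.tsv`,
#' `metadata.tsv` and `truth.json` in the package's standard formats.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "sc"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fc"), showWarnings = FALSE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_metadata(cohort$cohort, file.path(dir, "metadata.tsv"))
  for (id in names(cohort$networks)) {
    write_connectivity_matrix(cohort$networks[[id]]$sc,
                              file.path(dir, "sc", paste0(id, ".tsv")))
    write_connectivity_matrix(cohort$networks[[id]]$fc,
                              file.path(dir, "fc", paste0(id, ".tsv")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
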