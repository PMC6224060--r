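#' Read and write square connectivity matrices as delimited text
#'
#' Matrices are stored as plain tab-delimited text with no row or column
#' names, one matrix per file, which keeps subject-level artifacts
#' diff-able and language-agnostic.
#'
#' @param path file path.
#' @param n_nodes optional expected dimension; an error is raised when the
#'   parsed matrix does not match.
#' @return `read_connectivity_matrix()` returns a numeric square matrix.
#' @export
read_connectivity_matrix <- function(path, n_nodes = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    rlang::abort(sprintf("matrix in '%s' is %d x %d, expected square",
                         path, nrow(m), ncol(m)))
  }
  if (!is.null(n_nodes) && nrow(m) != n_nodes) {
    rlang::abort(sprintf("matrix in '%s' is %d x %d, expected %d x %d",
                         path, nrow(m), ncol(m), n_nodes, n_nodes))
  }
  m
}

#' @rdname read_connectivity_matrix
#' @param m numeric square matrix.
#' @export
write_connectivity_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a delimited table with columns `subject_id`, `sex`
#' (`"M"`/`"F"`), `age` (years) and `path` (location of the subject's
#' correlation matrix, relative to the manifest unless absolute).
#'
#' @param path manifest file path.
#' @return tibble with one row per subject.
#' @export
read_cohort_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject_id", "sex", "age", "path")
  if (!all(need %in% names(man))) {
    rlang::abort(paste0("manifest must have columns ",
                        paste(need, collapse = ", ")))
  }
  man$path <- ifelse(startsWith(man$path, "/"), man$path,
                     file.path(dirname(path), man$path))
  tibble::as_tibble(man)
}

#' Read region centroids
#'
#' @param path delimited text with header `node_id,x,y,z` (tab or comma
#'   separated); coordinates in millimetres.
#' @return tibble with columns `node_id`, `x`, `y`, `z`.
#' @export
read_centroids <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  cen <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("node_id", "x", "y", "z")
  if (!all(need %in% names(cen))) {
    rlang::abort("centroid file must have header columns node_id, x, y, z")
  }
  tibble::as_tibble(cen[need])
}
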