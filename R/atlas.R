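#' The 94-node Harvard-Oxford cortical parcellation table
#'
#' Returns the packaged node table: 94 cortical regions, nodes 1-47 in the
#' left hemisphere and 48-94 their right-hemisphere homologues.
#'
#' @return tibble with columns `node` (integer 1..94), `hemisphere`
#'   (`"left"`/`"right"`) and `region` (area name).
#' @examples
#' atlas <- hoa_atlas()
#' atlas[atlas$node == 31, ]
#' @export
hoa_atlas <- function() {
  path <- system.file("extdata", "atlas.tsv", package = "fdconnect",
                      mustWork = TRUE)
  atlas <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             node = readr::col_integer(),
                             hemisphere = readr::col_character(),
                             region = readr::col_character()))
  if (nrow(atlas) != 94L || !identical(atlas$node, 1:94)) {
    rlang::abort("packaged atlas table is corrupted: expected nodes 1..94")
  }
  atlas
}

#' Look up atlas region names by node id
#'
#' @param node integer vector of node ids in 1..94.
#' @return character vector of region names.
#' @examples
#' hoa_region(31) # "Left Precuneus Cortex"
#' @export
hoa_region <- function(node) {
  atlas <- hoa_atlas()
  node <- as.integer(node)
  bad <- node[is.na(node) | node < 1L | node > 94L]
  if (length(bad) > 0) {
    rlang::abort(sprintf("node id(s) out of range 1..94: %s",
                         paste(bad, collapse = ", ")))
  }
  atlas$region[node]
}

#' Pairwise Euclidean distance matrix between region centroids
#'
#' Distances enter the weighting model through the exponent
#' `exp(-(eta * D_ij - F_ij))`; with `normalize = TRUE` (the default) the
#' matrix is divided by its largest off-diagonal entry so that all
#' distances lie in `[0, 1]` and the distance weight `eta` can be held at 1.
#'
#' @param centroids data frame with columns `node_id`, `x`, `y`, `z`
#'   (millimetres), one row per node.
#' @param normalize divide by the maximum off-diagonal distance so entries
#'   span `[0, 1]`.
#' @param nodes optional integer vector of node ids that must all be
#'   present; an error names any node without a centroid.
#' @return symmetric numeric matrix with zero diagonal, rows/columns
#'   ordered and named by `node_id`.
#' @examples
#' cen <- tibble::tibble(node_id = 1:2, x = c(0, 3), y = c(0, 4), z = 0)
#' distance_matrix(cen, normalize = FALSE)[1, 2] # 5
#' @export
distance_matrix <- function(centroids, normalize = TRUE, nodes = NULL) {
  need <- c("node_id", "x", "y", "z")
  if (!all(need %in% names(centroids))) {
    rlang::abort("centroids must have columns node_id, x, y, z")
  }
  if (anyDuplicated(centroids$node_id)) {
    rlang::abort("duplicated node_id in centroid set")
  }
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, centroids$node_id)
    if (length(missing) > 0) {
      rlang::abort(sprintf("missing centroid for node(s): %s",
                           paste(missing, collapse = ", ")))
    }
    centroids <- centroids[centroids$node_id %in% nodes, ]
  }
  centroids <- centroids[order(centroids$node_id), ]
  d <- as.matrix(stats::dist(as.matrix(centroids[, c("x", "y", "z")])))
  dimnames(d) <- list(centroids$node_id, centroids$node_id)
  if (normalize) {
    dmax <- max(d)
    if (dmax <= 0) {
      rlang::abort("cannot normalize: all centroids coincide")
    }
    d <- d / dmax
  }
  d
}
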