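#' Centrality index over the thresholded group networks
#'
#' For each node `v`, the centrality index `CI(v)` is the sum of the
#' degrees of `v` over the double-thresholded group networks, divided by
#' the largest such sum. It is defined only for nodes with at least one
#' surviving incident link; the maximal node has `CI = 1`.
#'
#' @param thresholded list of [second_threshold()] results or matrices
#'   (one per group, same node indexing).
#' @return tibble with columns `node` and `ci`, sorted by descending `ci`.
#' @export
centrality_index <- function(thresholded) {
  if (length(thresholded) == 0) rlang::abort("no group matrices supplied")
  mats <- lapply(thresholded, as_wstar_matrix)
  degs <- vapply(mats, node_degrees, integer(nrow(mats[[1]])))
  if (is.null(dim(degs))) degs <- matrix(degs, nrow = 1)
  total <- rowSums(degs)
  keep <- which(total > 0)
  if (length(keep) == 0) {
    return(tibble::tibble(node = integer(0), ci = numeric(0)))
  }
  ci <- total[keep] / max(total[keep])
  out <- tibble::tibble(node = keep, ci = ci)
  dplyr::arrange(out, dplyr::desc(.data$ci), .data$node)
}

#' Centrality cutoff from the CI histogram
#'
#' Builds an `n_bins`-bin histogram over the observed CI range
#' `[min, max]` and returns the midpoint of bin 5, i.e.
#' `min + 4.5 * (max - min) / n_bins` for the default 10 bins. Spanning
#' the observed range (rather than `[0, 1]`) is what reproduces the
#' published cutoff of 0.46 on the reference centrality tables.
#'
#' @param ci_table tibble from [centrality_index()] (or any data frame
#'   with a `ci` column).
#' @param n_bins number of histogram bins.
#' @return the exact cutoff value (not rounded).
#' @examples
#' ci_cutoff(tibble::tibble(ci = c(0.02, 1.00))) # 0.461
#' @export
ci_cutoff <- function(ci_table, n_bins = 10) {
  ci <- ci_table$ci
  if (length(unique(ci)) < 2) {
    rlang::abort("ci_cutoff needs at least two distinct CI values")
  }
  min(ci) + 4.5 * (max(ci) - min(ci)) / n_bins
}

#' Principal vertices: nodes with centrality index at or above the cutoff
#'
#' @inheritParams ci_cutoff
#' @param cutoff CI cutoff in `(0, 1]`; compare with the published
#'   precision by rounding the [ci_cutoff()] value to 2 decimals first.
#' @return sorted integer vector of node ids (the set V').
#' @export
principal_vertices <- function(ci_table, cutoff) {
  sort(ci_table$node[ci_table$ci >= cutoff])
}

#' Principal edges: emerging links with both endpoints principal
#'
#' @param links an [extract_links()] table (columns `node_i`, `node_j`,
#'   `frequency`).
#' @param vp principal vertex set.
#' @return tibble of edges (subset of `links`) with any nonzero frequency.
#' @export
principal_edges <- function(links, vp) {
  dplyr::filter(tibble::as_tibble(links),
                .data$node_i %in% vp, .data$node_j %in% vp,
                .data$frequency >= 1)[, c("node_i", "node_j", "frequency")]
}

#' Secondary vertices: non-principal nodes strongly tied to V'
#'
#' A node outside V' joins V'' when it shares a link of frequency at least
#' `min_freq` (it appears in at least that many of the 14 group networks)
#' with some principal vertex.
#'
#' @inheritParams principal_edges
#' @param min_freq minimum link frequency (default 7, half the group
#'   count).
#' @return sorted integer vector of node ids (the set V'').
#' @export
secondary_vertices <- function(links, vp, min_freq = 7) {
  stopifnot(min_freq >= 1)
  lt <- dplyr::filter(tibble::as_tibble(links), .data$frequency >= min_freq)
  cand <- c(lt$node_i[lt$node_j %in% vp], lt$node_j[lt$node_i %in% vp])
  sort(setdiff(unique(cand), vp))
}

#' Secondary edges
#'
#' Two kinds: (i) the strong links that brought each secondary vertex in
#' (one endpoint in V'', the other in V', frequency at least `min_freq`),
#' and (ii) any emerging link with both endpoints in V'', regardless of
#' frequency, since extra connections between secondary vertices add
#' robustness to the network.
#'
#' @inheritParams secondary_vertices
#' @param vs secondary vertex set.
#' @return tibble of edges with columns `node_i`, `node_j`, `frequency`.
#' @export
secondary_edges <- function(links, vp, vs, min_freq = 7) {
  lt <- tibble::as_tibble(links)
  strong <- dplyr::filter(
    lt, .data$frequency >= min_freq,
    (.data$node_i %in% vs & .data$node_j %in% vp) |
      (.data$node_j %in% vs & .data$node_i %in% vp))
  within <- dplyr::filter(
    lt, .data$node_i %in% vs, .data$node_j %in% vs, .data$frequency >= 1)
  dplyr::distinct(
    dplyr::bind_rows(strong, within)[, c("node_i", "node_j", "frequency")])
}

#' Assemble the representative graph G(V, E)
#'
#' `V = V' U V''` and `E = E' U E''`; isolated vertices are retained and
#' an edge occurring in both sets is stored once with class `"principal"`.
#'
#' @param vp,vs principal and secondary vertex sets (disjoint).
#' @param ep,es principal and secondary edge tables (`node_i`, `node_j`,
#'   `frequency`).
#' @return object of class `fd_graph`: list with `graph` (igraph),
#'   `vertices` (tibble `node`, `class`) and `edges` (tibble `node_i`,
#'   `node_j`, `class`, `frequency`).
#' @export
build_graph <- function(vp, vs, ep, es) {
  if (length(intersect(vp, vs)) > 0) {
    rlang::abort("principal and secondary vertex sets must be disjoint")
  }
  v <- sort(unique(c(vp, vs)))
  edges <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(ep), class = "principal"),
    dplyr::mutate(tibble::as_tibble(es), class = "secondary"))
  if (nrow(edges) > 0) {
    edges <- dplyr::arrange(edges, .data$class) # principal first
    edges <- dplyr::distinct(edges, .data$node_i, .data$node_j,
                             .keep_all = TRUE)
    dangling <- setdiff(unique(c(edges$node_i, edges$node_j)), v)
    if (length(dangling) > 0) {
      rlang::abort(sprintf("edge endpoint(s) not in V' U V'': %s",
                           paste(dangling, collapse = ", ")))
    }
    edges <- dplyr::arrange(edges, dplyr::desc(.data$frequency),
                            .data$node_i, .data$node_j)
  } else {
    edges <- tibble::tibble(node_i = integer(0), node_j = integer(0),
                            frequency = integer(0), class = character(0))
  }
  vertices <- tibble::tibble(
    node = v,
    class = ifelse(v %in% vp, "principal", "secondary"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$node_i),
                   to = as.character(edges$node_j),
                   frequency = edges$frequency,
                   class = edges$class),
    directed = FALSE,
    vertices = data.frame(name = as.character(v), class = vertices$class))
  structure(list(graph = g, vertices = vertices,
                 edges = edges[, c("node_i", "node_j", "class", "frequency")]),
            class = "fd_graph")
}

#' @export
print.fd_graph <- function(x, ...) {
  cat(sprintf("<fd_graph> %d vertices (%d principal), %d edges\n",
              nrow(x$vertices), sum(x$vertices$class == "principal"),
              nrow(x$edges)))
  invisible(x)
}

#' Full vertex/edge selection from a link table and centrality table
#'
#' Runs the five selection steps: CI cutoff (rounded to the published
#' 2-decimal precision before comparison), principal vertices and edges,
#' secondary vertices and edges, and graph assembly.
#'
#' @inheritParams principal_edges
#' @inheritParams ci_cutoff
#' @inheritParams secondary_vertices
#' @param cutoff optional fixed CI cutoff; when `NULL` it is computed with
#'   [ci_cutoff()] and rounded to `round_digits` decimals.
#' @param round_digits decimals kept on the computed cutoff.
#' @return `fd_graph` with attribute `cutoff`.
#' @export
representative_graph <- function(links, ci_table, cutoff = NULL,
                                 n_bins = 10, min_freq = 7,
                                 round_digits = 2) {
  if (is.null(cutoff)) {
    cutoff <- round(ci_cutoff(ci_table, n_bins = n_bins), round_digits)
  }
  vp <- principal_vertices(ci_table, cutoff)
  vs <- secondary_vertices(links, vp, min_freq = min_freq)
  ep <- principal_edges(links, vp)
  es <- secondary_edges(links, vp, vs, min_freq = min_freq)
  g <- build_graph(vp, vs, ep, es)
  attr(g, "cutoff") <- cutoff
  g
}

#' Structural properties of a representative graph
#'
#' @param g an `fd_graph` (or igraph object).
#' @return list with `n_components`, `component_sizes`, `planar` (logical)
#'   and `degree_sequence` (named by node).
#' @export
graph_properties <- function(g) {
  ig <- if (inherits(g, "fd_graph")) g$graph else g
  comp <- igraph::components(ig)
  deg <- igraph::degree(ig)
  structure(list(
    n_components = comp$no,
    component_sizes = unname(sort(comp$csize, decreasing = TRUE)),
    planar = is_planar_graph(ig),
    degree_sequence = deg),
    class = "fd_graph_properties")
}

#' @export
print.fd_graph_properties <- function(x, ...) {
  cat(sprintf("components: %d (sizes %s); planar: %s\n",
              x$n_components, paste(x$component_sizes, collapse = ", "),
              x$planar))
  invisible(x)
}
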