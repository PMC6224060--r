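#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a representative graph
#'
#' Force-directed layout with principal vertices emphasised and edge
#' width proportional to link frequency.
#'
#' @param object an `fd_graph`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_graph <- function(object, seed = 42, ...) {
  lay <- withr::with_seed(seed,
                          igraph::layout_with_fr(object$graph))
  nodes <- object$vertices
  nodes$x <- lay[, 1]
  nodes$y <- lay[, 2]
  edges <- object$edges
  idx <- match(edges$node_i, nodes$node)
  jdx <- match(edges$node_j, nodes$node)
  edges$x <- nodes$x[idx]
  edges$y <- nodes$y[idx]
  edges$xend <- nodes$x[jdx]
  edges$yend <- nodes$y[jdx]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$frequency,
                   colour = .data$class), alpha = 0.7) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$class),
      size = 6, fill = "white") +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::scale_shape_manual(values = c(principal = 21,
                                           secondary = 22)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge class", shape = "vertex class",
                  linewidth = "frequency")
}

#' Plot the difference-matrix histogram of a model comparison
#'
#' Histogram of the positive entries of `M = Wrep - Frep` with the
#' selection threshold marked; the gap the threshold sits in is what
#' separates the concordant bulk from the discrepant links.
#'
#' @param object an `fd_model_comparison`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_model_comparison <- function(object, bins = 30, ...) {
  ut <- upper.tri(object$m)
  pos <- object$m[ut][object$m[ut] > 0]
  df <- tibble::tibble(difference = pos)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Wrep - Frep (positive entries)", y = "count") +
    ggplot2::theme_minimal()
}

#' Bar chart of emerging-link frequencies
#'
#' @param links an [extract_links()] table.
#' @param top show only the `top` most frequent links.
#' @return a ggplot object.
#' @export
plot_link_frequencies <- function(links, top = 30) {
  lt <- utils::head(tibble::as_tibble(links), top)
  lt$link <- factor(paste0(lt$node_i, "-", lt$node_j),
                    levels = rev(paste0(lt$node_i, "-", lt$node_j)))
  ggplot2::ggplot(lt, ggplot2::aes(x = .data$frequency, y = .data$link)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "groups in which the link survives", y = NULL) +
    ggplot2::theme_minimal()
}
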