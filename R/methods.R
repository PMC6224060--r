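#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.fd_perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$raw_p,
                 n_permutations = x$n_permutations,
                 exhaustive = x$exhaustive)
}

#' @exportS3Method generics::glance
glance.fd_perm_test <- function(x, ...) tidy(x)

#' @exportS3Method generics::tidy
tidy.fd_global_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fd_global_result")
  out
}

#' @exportS3Method generics::glance
glance.fd_global_result <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x),
                 n_significant = sum(x$significant),
                 min_adj_p = min(x$adj_p),
                 n_perm = attr(x, "n_perm"),
                 level = attr(x, "level"))
}

#' @exportS3Method generics::tidy
tidy.fd_local_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fd_local_result")
  out
}

#' @exportS3Method generics::glance
glance.fd_local_result <- function(x, ...) {
  tibble::tibble(group = attr(x, "group"), n_links = nrow(x),
                 n_significant = sum(x$significant),
                 n_weak = sum(x$weak_evidence),
                 n_perm = attr(x, "n_perm"),
                 exhaustive = attr(x, "exhaustive"))
}

#' @exportS3Method generics::tidy
tidy.fd_graph <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.fd_graph <- function(x, ...) {
  p <- graph_properties(x)
  tibble::tibble(n_vertices = nrow(x$vertices),
                 n_principal = sum(x$vertices$class == "principal"),
                 n_edges = nrow(x$edges),
                 n_components = p$n_components,
                 planar = p$planar)
}

#' @exportS3Method generics::tidy
tidy.fd_model_comparison <- function(x, ...) x$selected

#' @exportS3Method generics::glance
glance.fd_model_comparison <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 threshold_mode = x$threshold_mode,
                 n_selected = nrow(x$selected),
                 n_positive = x$n_positive,
                 n_negative = x$n_negative)
}
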