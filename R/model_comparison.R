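#' Cohort-representative matrices for the FD and pure-correlation models
#'
#' Elementwise means over all subjects (sexes pooled): `Wrep` from the FD
#' weight matrices, `Frep` from the raw (clipped) correlation matrices.
#'
#' @param w_list list of FD weight matrices or [fd_weights()] objects.
#' @param f_list list of correlation matrices, same length and dimension.
#' @return list with `wrep` and `frep`.
#' @export
representative_matrices <- function(w_list, f_list) {
  if (length(w_list) != length(f_list)) {
    rlang::abort("w_list and f_list must have the same number of subjects")
  }
  wrep <- average_group(w_list)
  frep <- average_group(f_list)
  if (!all(dim(wrep) == dim(frep))) {
    rlang::abort("weight and correlation matrices have mismatched shapes")
  }
  list(wrep = wrep, frep = frep)
}

#' Links where the FD model departs from pure correlation
#'
#' Forms `M = Wrep - Frep` and selects entries strictly above a threshold.
#' The default `"histogram_gap"` mode derives the threshold from the data:
#' a 10-bin histogram of the positive entries of `M` is scanned for its
#' widest run of empty bins (the "clear separation between two sets") and
#' the threshold is the lower edge of the first occupied bin above that
#' run. The `"fixed"` mode takes a supplied threshold instead. Negative
#' entries never enter the selection but are counted in the report.
#'
#' @param wrep,frep representative matrices (see
#'   [representative_matrices()]).
#' @param threshold_mode `"histogram_gap"` or `"fixed"`.
#' @param threshold required in `"fixed"` mode.
#' @param n_bins histogram bins for gap detection.
#' @return object of class `fd_model_comparison`: list with `m` (the
#'   difference matrix), `threshold`, `threshold_mode`, `selected` (tibble
#'   `node_i`, `node_j`, `difference`, plus atlas region names for 94-node
#'   matrices) and `n_negative`.
#' @export
select_discrepant_links <- function(wrep, frep,
                                    threshold_mode = c("histogram_gap",
                                                       "fixed"),
                                    threshold = NULL, n_bins = 10) {
  threshold_mode <- match.arg(threshold_mode)
  if (!all(dim(wrep) == dim(frep))) {
    rlang::abort("wrep and frep must be aligned")
  }
  m <- wrep - frep
  diag(m) <- 0
  ut <- upper.tri(m)
  pos <- m[ut][m[ut] > 0]
  if (threshold_mode == "fixed") {
    if (is.null(threshold)) {
      rlang::abort("fixed mode needs a threshold value")
    }
  } else {
    if (length(pos) == 0) {
      threshold <- NA_real_
    } else {
      threshold <- histogram_gap_threshold(pos, n_bins)
    }
  }
  if (length(pos) == 0) {
    rlang::warn("difference matrix has no positive entries; empty selection")
    selected <- tibble::tibble(node_i = integer(0), node_j = integer(0),
                               difference = numeric(0))
  } else {
    idx <- which(ut & m > threshold, arr.ind = TRUE)
    selected <- tibble::tibble(node_i = unname(idx[, 1]),
                               node_j = unname(idx[, 2]),
                               difference = unname(m[idx]))
    selected <- dplyr::arrange(selected, dplyr::desc(.data$difference))
  }
  if (nrow(m) == 94 && nrow(selected) > 0) {
    selected$region_i <- hoa_region(selected$node_i)
    selected$region_j <- hoa_region(selected$node_j)
  }
  structure(list(m = m, threshold = threshold,
                 threshold_mode = threshold_mode, selected = selected,
                 n_positive = length(pos),
                 n_negative = sum(m[ut] < 0)),
            class = "fd_model_comparison")
}

# Lower edge of the first occupied bin above the widest run of empty bins
# (ties broken towards the top). Falls back to the maximum (empty
# selection) with a warning when no empty bin separates the distribution.
histogram_gap_threshold <- function(pos, n_bins) {
  lo <- min(pos)
  hi <- max(pos)
  if (hi == lo) return(lo - .Machine$double.eps) # all equal: select all
  w <- (hi - lo) / n_bins
  bin <- pmin(n_bins, floor((pos - lo) / w) + 1)
  counts <- tabulate(bin, nbins = n_bins)
  empty <- counts == 0
  if (!any(empty)) {
    rlang::warn("no empty histogram bin: no separation found, empty selection")
    return(hi)
  }
  r <- rle(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs] + starts[runs] / (2 * n_bins))]
  first_above <- ends[best] + 1
  if (first_above > n_bins) {
    rlang::warn("empty bins only at the top of the histogram; empty selection")
    return(hi)
  }
  lo + (first_above - 1) * w
}

#' @export
print.fd_model_comparison <- function(x, ...) {
  cat(sprintf(
    "<fd_model_comparison> threshold %.4g (%s): %d link(s) selected\n",
    x$threshold, x$threshold_mode, nrow(x$selected)))
  invisible(x)
}

#' Average-based FD vs pure-correlation comparison for a cohort
#'
#' Convenience wrapper: builds the representative matrices and selects the
#' discrepant links.
#'
#' @inheritParams representative_matrices
#' @inheritParams select_discrepant_links
#' @export
compare_models <- function(w_list, f_list,
                           threshold_mode = c("histogram_gap", "fixed"),
                           threshold = NULL, n_bins = 10) {
  rep <- representative_matrices(w_list, f_list)
  select_discrepant_links(rep$wrep, rep$frep,
                          threshold_mode = threshold_mode,
                          threshold = threshold, n_bins = n_bins)
}
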