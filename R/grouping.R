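#' Age-group schemes
#'
#' Two packaged schemes: `"fourteen"` (the original 14 age groups used for
#' group averaging and graph construction) and `"seven"` (the merged
#' 7-group scheme used by the statistical analysis, where adjacent groups
#' are pooled to raise sample sizes). Labels follow the study's printed
#' labels; `age_lo`/`age_hi` give the actual coverage, which tiles 6..79.
#'
#' @param scheme `"fourteen"` or `"seven"`.
#' @return tibble with columns `group_id`, `label`, `age_lo`, `age_hi`.
#' @export
age_group_scheme <- function(scheme = c("fourteen", "seven")) {
  scheme <- match.arg(scheme)
  if (scheme == "fourteen") {
    lo <- c(6, 11, 16, 21, 26, 31, 36, 41, 46, 51, 58, 66, 71, 76)
    hi <- c(10, 15, 20, 25, 30, 35, 40, 45, 50, 57, 65, 70, 75, 79)
    lab <- paste0(lo, "-", hi)
  } else {
    lo <- c(6, 16, 26, 36, 46, 58, 71)
    hi <- c(15, 25, 35, 45, 57, 70, 79)
    lab <- c("6-15", "16-21", "26-35", "36-40", "46-50", "58-70", "71-79")
  }
  tibble::tibble(group_id = seq_along(lo), label = lab,
                 age_lo = lo, age_hi = hi)
}

#' Assign subjects to age/sex groups
#'
#' Each subject falls in exactly one (sex, age-range) group. Ages must lie
#' within 6..79, the span covered by both schemes.
#'
#' @param cohort data frame with at least `subject_id`, `sex` (`"M"`/`"F"`)
#'   and `age` columns.
#' @param scheme `"fourteen"`, `"seven"`, or a scheme tibble as returned by
#'   [age_group_scheme()].
#' @return the input tibble with `group_id` and `group_label` columns
#'   added; groups are the combination of `sex` and `group_label`.
#' @export
assign_groups <- function(cohort, scheme = "fourteen") {
  if (is.character(scheme)) scheme <- age_group_scheme(scheme)
  cohort <- tibble::as_tibble(cohort)
  if (!all(c("subject_id", "sex", "age") %in% names(cohort))) {
    rlang::abort("cohort must have columns subject_id, sex, age")
  }
  if (!all(cohort$sex %in% c("M", "F"))) {
    rlang::abort('sex must be "M" or "F"')
  }
  idx <- findInterval(cohort$age, scheme$age_lo)
  ok <- idx >= 1 & cohort$age <= scheme$age_hi[pmax(idx, 1)]
  if (!all(ok)) {
    rlang::abort(sprintf(
      "age outside scheme range (%d..%d) for subject(s): %s",
      min(scheme$age_lo), max(scheme$age_hi),
      paste(cohort$subject_id[!ok], collapse = ", ")))
  }
  cohort$group_id <- scheme$group_id[idx]
  cohort$group_label <- scheme$label[idx]
  cohort
}

#' Merge the fourteen age groups into the seven statistical groups
#'
#' @inheritParams assign_groups
#' @return tibble with `group_id`/`group_label` referring to the merged
#'   scheme.
#' @export
merge_groups <- function(cohort) {
  assign_groups(cohort[setdiff(names(cohort), c("group_id", "group_label"))],
                scheme = "seven")
}

#' Elementwise mean of a group's weight matrices
#'
#' Encodes a whole group in a single matrix: the members' FD weight
#' matrices are summed and divided by the group cardinality.
#'
#' @param members list of matrices (or `fd_weights` objects) of identical
#'   dimension.
#' @return numeric matrix.
#' @export
average_group <- function(members) {
  if (length(members) == 0) rlang::abort("cannot average an empty group")
  mats <- lapply(members, as_w_matrix)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) {
    rlang::abort("group members have mismatched dimensions")
  }
  Reduce(`+`, mats) / length(mats)
}

#' Second thresholding step on a group-average matrix
#'
#' Retains, among the links surviving the first step, only those with high
#' intensity. A reference level `m` is taken from the upper end of the
#' distribution of nonzero entries and the threshold is `lam = m / 2`;
#' entries below `lam` are set to zero.
#'
#' Two readings of "the bin formed by the highest 10% of entries" are
#' provided. The default, `"top_decile_midpoint"`, treats the top decile of
#' nonzero entries as one bin and takes its midpoint,
#' `m = (q90 + max) / 2` with a nearest-rank 90% quantile. The alternative,
#' `"top_bin_of_10"`, takes the center of the 10th bin of a 10-bin
#' histogram spanning `[min, max]` of the nonzero entries.
#'
#' @param wbar group-average weight matrix with at least one nonzero
#'   off-diagonal entry.
#' @param mode threshold construction, see Details.
#' @return object of class `fd_second_threshold`: list with `wstar` (the
#'   thresholded matrix), `m`, `lam = m/2` and `mode`.
#' @examples
#' # with m = 0.3848 the threshold is lam = 0.1924
#' @export
second_threshold <- function(wbar,
                             mode = c("top_decile_midpoint",
                                      "top_bin_of_10")) {
  mode <- match.arg(mode)
  wbar <- as_w_matrix(wbar)
  stopifnot(is.matrix(wbar), nrow(wbar) == ncol(wbar))
  off <- !diag(nrow(wbar))
  vals <- wbar[off]
  vals <- vals[vals > 0]
  if (length(vals) == 0) {
    rlang::abort("second_threshold: group matrix has no nonzero entries")
  }
  if (mode == "top_decile_midpoint") {
    v <- sort(vals)
    q90 <- v[ceiling(0.9 * length(v))]
    m <- (q90 + max(v)) / 2
  } else {
    m <- min(vals) + 9.5 * (max(vals) - min(vals)) / 10
  }
  lam <- m / 2
  wstar <- wbar
  wstar[wbar < lam] <- 0
  diag(wstar) <- 0
  structure(list(wstar = wstar, m = m, lam = lam, mode = mode),
            class = "fd_second_threshold")
}

#' @export
print.fd_second_threshold <- function(x, ...) {
  cat(sprintf("<fd_second_threshold> m = %.4g, lam = %.4g (%s), %d links\n",
              x$m, x$lam, x$mode, sum(x$wstar[upper.tri(x$wstar)] > 0)))
  invisible(x)
}

as_wstar_matrix <- function(x) {
  if (inherits(x, "fd_second_threshold")) x$wstar else as_w_matrix(x)
}

#' Extract the emerging-link table from thresholded group matrices
#'
#' The emerging links are the node pairs with a nonzero entry in at least
#' one of the double-thresholded group matrices. For each link the table
#' records its per-group intensity and its frequency (number of groups in
#' which it survives).
#'
#' @param thresholded named list of [second_threshold()] results (or plain
#'   matrices), one per group; all matrices must share node indexing.
#'   Groups that are absent from the list simply contribute no column.
#' @return tibble of class `fd_link_table` with columns `node_i`,
#'   `node_j` (`node_i < node_j`), `frequency`, and one `intensity_<group>`
#'   column per group, sorted by descending frequency then by node pair.
#' @export
extract_links <- function(thresholded) {
  if (length(thresholded) == 0) rlang::abort("no group matrices supplied")
  mats <- lapply(thresholded, as_wstar_matrix)
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1) rlang::abort("group matrices differ in dimension")
  labels <- names(mats)
  if (is.null(labels)) labels <- paste0("g", seq_along(mats))
  ut <- upper.tri(matrix(0, n, n))
  pairs <- which(ut, arr.ind = TRUE)
  intens <- vapply(mats, function(m) m[ut], numeric(sum(ut)))
  if (is.null(dim(intens))) intens <- matrix(intens, nrow = 1)
  keep <- rowSums(intens != 0) > 0
  lt <- tibble::tibble(node_i = pairs[keep, 1],
                       node_j = pairs[keep, 2],
                       frequency = as.integer(rowSums(intens[keep, ,
                                                             drop = FALSE] != 0)))
  icols <- tibble::as_tibble(as.data.frame(intens[keep, , drop = FALSE]))
  names(icols) <- paste0("intensity_", labels)
  lt <- dplyr::bind_cols(lt, icols)
  lt <- dplyr::arrange(lt, dplyr::desc(.data$frequency),
                       .data$node_i, .data$node_j)
  class(lt) <- c("fd_link_table", class(lt))
  lt
}
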