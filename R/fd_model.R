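#' Set negative correlations to zero
#'
#' Resting-state correlation matrices contain negative entries whose
#' interpretation is debated; the pipeline analyses the non-negative part
#' only, so negatives are clipped to zero before thresholding.
#'
#' @param f symmetric correlation matrix with entries in `[-1, 1]`.
#' @param tol symmetry tolerance.
#' @return matrix of the same dimension with all entries `>= 0`.
#' @export
clip_negatives <- function(f, tol = 1e-8) {
  stopifnot(is.matrix(f), nrow(f) == ncol(f))
  if (max(abs(f - t(f))) > tol) {
    rlang::abort("correlation matrix is not symmetric (beyond tolerance)")
  }
  pmax(f, 0)
}

#' First thresholding step: select the neighborhood of interest (NOI)
#'
#' The distribution of non-negative correlations is viewed as a 10-bin
#' histogram on the unit interval; at rest the mass accumulates in the
#' first two bins, so only entries strictly above the upper edge of bin 2
#' (0.2 by default) are retained. The retained upper portion is the
#' subject's neighborhood of interest.
#'
#' @param f non-negative matrix with off-diagonal entries in `[0, 1]`
#'   (typically the output of [clip_negatives()]).
#' @param cut threshold; entries must be strictly above it to survive.
#'   The default 0.2 is the upper edge of the second histogram bin.
#' @return an object of class `fd_noi`: list with elements `fs` (the
#'   thresholded matrix, zero diagonal), `noi_threshold` (the cut used) and
#'   `retained_fraction` (proportion of off-diagonal entries retained).
#' @export
first_threshold <- function(f, cut = 0.2) {
  stopifnot(is.matrix(f), nrow(f) == ncol(f))
  off <- !diag(nrow(f))
  vals <- f[off]
  if (any(vals < 0) || any(vals > 1)) {
    rlang::abort("first_threshold expects off-diagonal entries in [0, 1]")
  }
  fs <- f
  fs[off & f <= cut] <- 0
  diag(fs) <- 0
  structure(
    list(fs = fs,
         noi_threshold = cut,
         retained_fraction = mean(vals > cut)),
    class = "fd_noi")
}

#' @export
print.fd_noi <- function(x, ...) {
  cat(sprintf("<fd_noi> %d x %d, cut = %.3g, retained %.1f%% of entries\n",
              nrow(x$fs), ncol(x$fs), x$noi_threshold,
              100 * x$retained_fraction))
  invisible(x)
}

as_fs_matrix <- function(x) {
  if (inherits(x, "fd_noi")) x$fs else x
}

#' Node degrees of a thresholded correlation matrix
#'
#' The degree of a node is the number of nonzero off-diagonal entries in
#' its row, i.e. the number of retained links at that node.
#'
#' @param fs thresholded matrix or [first_threshold()] result.
#' @return integer vector of length `nrow(fs)`.
#' @export
node_degrees <- function(fs) {
  fs <- as_fs_matrix(fs)
  stopifnot(is.matrix(fs), nrow(fs) == ncol(fs))
  m <- fs != 0
  diag(m) <- FALSE
  as.integer(rowSums(m))
}

#' FD-model edge weights
#'
#' Computes, for every off-diagonal pair, the unnormalized weight
#' `w_ij = deg(i) * deg(j) * exp(-(eta * D_ij - Fs_ij))` and normalizes by
#' the maximum weight so the strongest edge has weight 1. Degrees come from
#' the thresholded correlation matrix itself. If every node is isolated
#' (all degrees zero) the result is the all-zero matrix with `wmax = 0`.
#'
#' The formula imposes no support restriction: pairs with `Fs_ij = 0` still
#' receive a (distance- and degree-driven) weight. Set
#' `mask_zero_correlation = TRUE` to restrict weights to the retained
#' correlation support.
#'
#' @param fs thresholded correlation matrix or [first_threshold()] result.
#' @param d normalized distance matrix (entries in `[0, 1]`, see
#'   [distance_matrix()]).
#' @param eta distance weight; after distance normalization it is held at 1.
#' @param mask_zero_correlation zero out pairs whose thresholded
#'   correlation is zero.
#' @return object of class `fd_weights`: list with `w` (normalized weight
#'   matrix, max entry 1 unless degenerate), `wmax` (the normalization
#'   value), `degrees`, `eta`.
#' @examples
#' fs <- matrix(c(0, .6, .6, 0), 2)
#' d <- matrix(c(0, 1, 1, 0), 2)
#' fd_weights(fs, d)$wmax # exp(-0.4)
#' @export
fd_weights <- function(fs, d, eta = 1, mask_zero_correlation = FALSE) {
  fs <- as_fs_matrix(fs)
  stopifnot(is.matrix(fs), is.matrix(d))
  if (!all(dim(fs) == dim(d))) {
    rlang::abort(sprintf(
      "shape mismatch: correlations are %d x %d but distances are %d x %d",
      nrow(fs), ncol(fs), nrow(d), ncol(d)))
  }
  if (eta <= 0) rlang::abort("eta must be > 0")
  deg <- node_degrees(fs)
  w <- outer(deg, deg) * exp(-(eta * d - fs))
  diag(w) <- 0
  if (mask_zero_correlation) {
    w[fs == 0] <- 0
  }
  wmax <- max(w)
  if (wmax > 0) w <- w / wmax
  structure(
    list(w = w, wmax = wmax, degrees = deg, eta = eta),
    class = "fd_weights")
}

#' @export
print.fd_weights <- function(x, ...) {
  cat(sprintf("<fd_weights> %d nodes, wmax = %.4g, %d non-isolated nodes\n",
              nrow(x$w), x$wmax, sum(x$degrees > 0)))
  invisible(x)
}

as_w_matrix <- function(x) {
  if (inherits(x, "fd_weights")) x$w else x
}

#' Per-subject processing: clip, threshold, weight
#'
#' Convenience wrapper running [clip_negatives()], [first_threshold()] and
#' [fd_weights()] on one subject's correlation matrix.
#'
#' @param f raw symmetric correlation matrix (entries in `[-1, 1]`).
#' @param d normalized distance matrix.
#' @inheritParams fd_weights
#' @inheritParams first_threshold
#' @return `fd_weights` object with the NOI report attached as attribute
#'   `noi`.
#' @export
subject_weights <- function(f, d, cut = 0.2, eta = 1,
                            mask_zero_correlation = FALSE) {
  noi <- first_threshold(clip_negatives(f), cut = cut)
  fw <- fd_weights(noi, d, eta = eta,
                   mask_zero_correlation = mask_zero_correlation)
  attr(fw, "noi") <- noi
  fw
}
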