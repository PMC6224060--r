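#' Two-group ANOVA statistic for one link
#'
#' The classical one-way ANOVA F statistic with two groups: between-group
#' sum of squares over pooled within-group variance,
#' `T = [n1 (ybar - m)^2 + n2 (xbar - m)^2] / [SSW / (n1 + n2 - 2)]`,
#' where `m` is the grand mean. Equivalent to the squared pooled two-sample
#' t statistic. When the pooled within-group variance is zero the
#' statistic is 0 for equal means and `Inf` otherwise (the `Inf` sentinel
#' ranks above every finite permuted statistic, keeping permutation
#' p-values well defined on degenerate links).
#'
#' @param y,x numeric vectors (e.g. male and female link values); both
#'   non-empty with `length(y) + length(x) >= 3`.
#' @return scalar statistic.
#' @examples
#' anova_statistic(c(1, 2, 3), c(4, 5, 6)) # 13.5
#' @export
anova_statistic <- function(y, x) {
  n1 <- length(y)
  n2 <- length(x)
  if (n1 < 1 || n2 < 1) rlang::abort("both samples must be non-empty")
  if (n1 + n2 < 3) rlang::abort("need at least 3 observations in total")
  ybar <- mean(y)
  xbar <- mean(x)
  m <- (n1 * ybar + n2 * xbar) / (n1 + n2)
  ssb <- n1 * (ybar - m)^2 + n2 * (xbar - m)^2
  ssw <- sum((y - ybar)^2) + sum((x - xbar)^2)
  if (ssw <= 0) {
    if (ssb <= .Machine$double.eps) return(0)
    return(Inf)
  }
  ssb / (ssw / (n1 + n2 - 2))
}

#' Sum-of-F multivariate statistic
#'
#' The global male/female distance over all emerging links: the per-link
#' ANOVA statistics are summed, giving a multivariate test statistic that
#' remains usable when the number of links exceeds the sample size. An
#' `Inf` on any link propagates.
#'
#' @param y,x numeric matrices with one row per subject and one column per
#'   link; equal column counts.
#' @return scalar statistic.
#' @export
global_statistic <- function(y, x) {
  y <- as_subject_matrix(y)
  x <- as_subject_matrix(x)
  if (ncol(y) != ncol(x)) {
    rlang::abort("male and female matrices must share the same links")
  }
  sum(vapply(seq_len(ncol(y)),
             function(e) anova_statistic(y[, e], x[, e]), numeric(1)))
}

# Vectors are one-link samples (one column); matrices are rows = subjects.
as_subject_matrix <- function(v) {
  if (is.matrix(v)) v else matrix(v, ncol = 1)
}

# Permutation index matrix: rows are the subject indices assigned to the
# first ("male") sample. Exhaustive when choose(n, n1) <= limit, otherwise
# Monte-Carlo draws (the observed labelling is accounted for in the
# p-value formula, not duplicated here).
perm_indices <- function(n, n1, n_perm, exhaustive_limit) {
  n_total <- choose(n, n1)
  if (n_total <= exhaustive_limit) {
    list(idx = t(utils::combn(n, n1)), exhaustive = TRUE)
  } else {
    idx <- t(vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                    integer(n1)))
    list(idx = idx, exhaustive = FALSE)
  }
}

# Per-permutation, per-link two-group F statistics, vectorized.
# z: (n x Q) combined data, rows 1..n; idx: (P x n1) matrix of "male"
# index sets. Returns a (P x Q) matrix of F values (Inf sentinel where the
# within variance vanishes but the means differ).
perm_f_stats <- function(z, n1, idx) {
  z <- rbind(z)
  n <- nrow(z)
  n2 <- n - n1
  p <- nrow(idx)
  a <- matrix(0, p, n)
  a[cbind(rep(seq_len(p), ncol(idx)), as.vector(idx))] <- 1
  s1 <- a %*% z                        # (P x Q) sums of the male subset
  tot <- colSums(z)
  tot2 <- colSums(z^2)
  gm <- tot / n
  sst <- tot2 - n * gm^2               # total SS, permutation-invariant
  ybar <- s1 / n1
  xbar <- sweep(-s1, 2, tot, `+`) / n2
  ssb <- n1 * sweep(ybar, 2, gm)^2 + n2 * sweep(xbar, 2, gm)^2
  ssw <- sweep(-ssb, 2, sst, `+`)
  ssw[ssw < 0] <- 0                    # numerical guard
  f <- ssb / (ssw / (n - 2))
  tol <- 1e-12 * pmax(1, sst)
  degen <- sweep(ssw, 2, tol, `<`)
  if (any(degen)) {
    big <- ssb > rep(tol, each = p)
    f[degen & big] <- Inf
    f[degen & !big] <- 0
  }
  f
}

#' Permutation test for a male/female difference
#'
#' Compares two samples (vectors, or subject-by-link matrices for the
#' multivariate sum statistic) by permuting group labels. All label
#' reassignments are enumerated when `choose(n, n_y) <= exhaustive_limit`;
#' otherwise `n_perm` Monte-Carlo permutations are drawn and the p-value
#' `(1 + #extreme) / (1 + n_perm)` includes the identity permutation, so
#' it is never zero. A permuted statistic counts as extreme when it is
#' greater than or equal to the observed one.
#'
#' @param y,x numeric vectors or matrices (rows = subjects).
#' @param statistic `"sum_f"` (default; per-link two-group F summed over
#'   columns, reducing to the single F for vectors) or a function
#'   `function(y, x)` returning a scalar.
#' @param n_perm number of Monte-Carlo permutations (ignored when the test
#'   is exhaustive).
#' @param seed optional integer; when supplied the Monte-Carlo draw is
#'   reproducible and the global RNG state is left untouched.
#' @param exhaustive_limit enumerate all `choose(n, n_y)` reassignments
#'   when at most this many.
#' @return object of class `fd_perm_test`: list with `statistic`,
#'   `raw_p`, `n_permutations`, `exhaustive`, `seed`.
#' @export
permutation_test <- function(y, x, statistic = "sum_f", n_perm = 9999,
                             seed = NULL, exhaustive_limit = 20000) {
  if (n_perm < 1) rlang::abort("n_perm must be >= 1")
  y <- as_subject_matrix(y)
  x <- as_subject_matrix(x)
  if (ncol(y) != ncol(x)) rlang::abort("y and x must share columns")
  n1 <- nrow(y)
  n <- n1 + nrow(x)
  if (n < 3) rlang::abort("need at least 3 subjects in total")
  z <- rbind(y, x)
  run <- function() {
    pi <- perm_indices(n, n1, n_perm, exhaustive_limit)
    if (is.function(statistic)) {
      t_obs <- statistic(y, x)
      t_perm <- apply(pi$idx, 1, function(ii) {
        statistic(z[ii, , drop = FALSE], z[-ii, , drop = FALSE])
      })
    } else {
      f_obs <- perm_f_stats(z, n1, matrix(seq_len(n1), nrow = 1))
      t_obs <- sum(f_obs)
      t_perm <- rowSums(perm_f_stats(z, n1, pi$idx))
    }
    eps <- 1e-10 * max(1, abs(if (is.finite(t_obs)) t_obs else 1))
    hits <- sum(t_perm >= t_obs - eps)
    raw_p <- if (pi$exhaustive) hits / nrow(pi$idx)
             else (1 + hits) / (1 + n_perm)
    structure(list(statistic = t_obs, raw_p = raw_p,
                   n_permutations = nrow(pi$idx),
                   exhaustive = pi$exhaustive, seed = seed),
              class = "fd_perm_test")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.fd_perm_test <- function(x, ...) {
  cat(sprintf("<fd_perm_test> T = %.4g, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$raw_p,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down familywise-error control: p-values are sorted ascending, the
#' k-th smallest is multiplied by `m - k + 1`, the sequence is made
#' monotone non-decreasing, capped at 1, and returned in input order.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.04 0.04
#' @export
holm_adjust <- function(p) {
  if (any(p <= 0) || any(p > 1) || anyNA(p)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Assemble the per-group statistical dataset
#'
#' Restricts each subject's FD weight matrix to the emerging-link set L
#' and splits subjects into the merged age groups by sex, producing the
#' male matrix `Y` (`|M| x Q`) and female matrix `X` (`|B| x Q`) per
#' group.
#'
#' @param cohort data frame with `subject_id`, `sex`, `age`.
#' @param weights named list (by `subject_id`) of FD weight matrices or
#'   [fd_weights()] objects.
#' @param links data frame with columns `node_i`, `node_j` defining the
#'   ordered link set L.
#' @param scheme grouping scheme (default the merged seven-group scheme).
#' @return object of class `fd_stat_dataset`: list with `groups` (named
#'   list of `list(y, x)` per group label) and `links`.
#' @export
build_stat_dataset <- function(cohort, weights, links, scheme = "seven") {
  cohort <- assign_groups(cohort, scheme = scheme)
  if (!all(cohort$subject_id %in% names(weights))) {
    rlang::abort("every cohort subject needs a weight matrix")
  }
  links <- tibble::as_tibble(links)[, c("node_i", "node_j")]
  q <- nrow(links)
  link_values <- function(ids) {
    vals <- vapply(ids, function(id) {
      w <- as_w_matrix(weights[[id]])
      w[cbind(links$node_i, links$node_j)]
    }, numeric(q))
    # one row per subject regardless of Q or the number of subjects
    matrix(as.numeric(vals), nrow = length(ids), ncol = q, byrow = TRUE)
  }
  labels <- if (is.character(scheme)) age_group_scheme(scheme)$label
            else scheme$label
  groups <- lapply(labels, function(lab) {
    males <- cohort$subject_id[cohort$group_label == lab & cohort$sex == "M"]
    females <- cohort$subject_id[cohort$group_label == lab & cohort$sex == "F"]
    list(y = link_values(males), x = link_values(females))
  })
  names(groups) <- labels
  structure(list(groups = groups, links = links),
            class = "fd_stat_dataset")
}

#' Global analysis: one multivariate permutation test per merged age group
#'
#' Each merged group gets a permutation test of the null "male and female
#' link-value distributions are equal" using the sum-of-F statistic over
#' all links; the seven raw p-values are then Holm-adjusted jointly and
#' groups with adjusted p below `level` are flagged.
#'
#' @param dataset an [build_stat_dataset()] object.
#' @inheritParams permutation_test
#' @param level familywise significance level.
#' @return tibble of class `fd_global_result`: one row per group with
#'   `group`, `n_male`, `n_female`, `statistic`, `raw_p`, `adj_p`,
#'   `significant`, `exhaustive`. Groups with fewer than 2 subjects are
#'   skipped with a warning.
#' @export
run_global_analysis <- function(dataset, n_perm = 9999, seed = NULL,
                                level = 0.05, exhaustive_limit = 20000) {
  run <- function() {
    rows <- purrr::imap(dataset$groups, function(g, lab) {
      n1 <- nrow(g$y)
      n2 <- nrow(g$x)
      if (n1 < 1 || n2 < 1 || n1 + n2 < 3) {
        rlang::warn(sprintf(
          "group %s skipped: needs both sexes and >= 3 subjects", lab))
        return(NULL)
      }
      pt <- permutation_test(g$y, g$x, n_perm = n_perm,
                             exhaustive_limit = exhaustive_limit)
      tibble::tibble(group = lab, n_male = n1, n_female = n2,
                     statistic = pt$statistic, raw_p = pt$raw_p,
                     exhaustive = pt$exhaustive)
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) rlang::abort("no testable group")
    out$adj_p <- holm_adjust(out$raw_p)
    out$significant <- out$adj_p < level
    out <- out[, c("group", "n_male", "n_female", "statistic",
                   "raw_p", "adj_p", "significant", "exhaustive")]
    class(out) <- c("fd_global_result", class(out))
    attr(out, "n_perm") <- n_perm
    attr(out, "level") <- level
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Local analysis: per-link permutation tests within one merged group
#'
#' For a group flagged by the global analysis, each link of L is tested
#' separately with the univariate two-group F statistic; one shared set of
#' permutations is used across links and the Q raw p-values are
#' Holm-adjusted jointly. Links are reported at the strict (5%) and weak
#' (10%) adjusted levels.
#'
#' @inheritParams run_global_analysis
#' @param group merged-group label (e.g. `"71-79"`).
#' @param levels strict and weak adjusted significance levels.
#' @return tibble of class `fd_local_result`: one row per link with
#'   `node_i`, `node_j`, `statistic`, `raw_p`, `adj_p`, `significant`,
#'   `weak_evidence`.
#' @export
run_local_analysis <- function(dataset, group, n_perm = 9999, seed = NULL,
                               levels = c(0.05, 0.10),
                               exhaustive_limit = 20000) {
  if (!group %in% names(dataset$groups)) {
    rlang::abort(sprintf("unknown group '%s'", group))
  }
  g <- dataset$groups[[group]]
  n1 <- nrow(g$y)
  n <- n1 + nrow(g$x)
  if (n1 < 1 || nrow(g$x) < 1 || n < 3) {
    rlang::abort(sprintf("group %s has too few subjects for testing", group))
  }
  z <- rbind(g$y, g$x)
  run <- function() {
    pi <- perm_indices(n, n1, n_perm, exhaustive_limit)
    f_obs <- perm_f_stats(z, n1, matrix(seq_len(n1), nrow = 1))[1, ]
    f_perm <- perm_f_stats(z, n1, pi$idx)
    eps <- 1e-10 * pmax(1, abs(ifelse(is.finite(f_obs), f_obs, 1)))
    hits <- colSums(f_perm >= rep(f_obs - eps, each = nrow(f_perm)))
    raw_p <- if (pi$exhaustive) hits / nrow(pi$idx)
             else (1 + hits) / (1 + n_perm)
    out <- tibble::tibble(
      node_i = dataset$links$node_i, node_j = dataset$links$node_j,
      statistic = f_obs, raw_p = raw_p, adj_p = holm_adjust(raw_p))
    out$significant <- out$adj_p < levels[1]
    out$weak_evidence <- out$adj_p < levels[2]
    out <- dplyr::arrange(out, .data$adj_p, .data$raw_p,
                          .data$node_i, .data$node_j)
    class(out) <- c("fd_local_result", class(out))
    attr(out, "group") <- group
    attr(out, "n_perm") <- nrow(pi$idx)
    attr(out, "exhaustive") <- pi$exhaustive
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
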