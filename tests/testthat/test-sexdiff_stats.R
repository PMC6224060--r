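test_that("the two-group statistic equals the classical ANOVA F", {
  expect_equal(anova_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(anova_statistic(c(1, 2, 3), c(4, 5, 6)), 13.5)
  # squared pooled t
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$statistic
  expect_equal(anova_statistic(c(1, 2, 3), c(4, 5, 6)), unname(tt^2))
  withr::with_seed(31, {
    for (rep in 1:50) {
      n1 <- sample(2:10, 1)
      n2 <- sample(2:10, 1)
      y <- rnorm(n1)
      x <- rnorm(n2, mean = runif(1, -1, 1))
      f_ref <- stats::oneway.test(c(y, x) ~ rep(1:2, c(n1, n2)),
                                  var.equal = TRUE)$statistic
      expect_equal(anova_statistic(y, x), unname(f_ref), tolerance = 1e-12)
    }
  })
  expect_error(anova_statistic(numeric(0), 1:3), "non-empty")
  expect_error(anova_statistic(1, 2), "at least 3")
})

test_that("zero within-group variance yields the 0 / Inf sentinel", {
  expect_equal(anova_statistic(c(2, 2), c(2, 2)), 0)
  expect_identical(anova_statistic(c(1, 1), c(2, 2)), Inf)
})

test_that("the global statistic is the per-link sum", {
  y <- matrix(c(1, 2, 3), ncol = 1)
  x <- matrix(c(4, 5, 6), ncol = 1)
  expect_equal(global_statistic(y, x), anova_statistic(y[, 1], x[, 1]))
  y2 <- cbind(y, c(1, 2, 3))
  x2 <- cbind(x, c(1, 2, 3))
  expect_equal(global_statistic(y2, x2), 13.5) # 13.5 + 0
  withr::with_seed(37, {
    ym <- matrix(rnorm(15), 5, 3)
    xm <- matrix(rnorm(12), 4, 3)
    ref <- sum(vapply(1:3, function(e) anova_statistic(ym[, e], xm[, e]),
                      1.0))
    expect_equal(global_statistic(ym, xm), ref)
  })
  expect_error(global_statistic(matrix(0, 2, 2), matrix(0, 2, 3)),
               "share")
})

test_that("vectorized permutation statistics match the scalar path", {
  withr::with_seed(41, {
    z <- matrix(rnorm(8 * 4), 8, 4)
    idx <- t(utils::combn(8, 3))
    fast <- fdconnect:::perm_f_stats(z, 3, idx)
    for (r in sample(nrow(idx), 10)) {
      for (e in 1:4) {
        slow <- anova_statistic(z[idx[r, ], e], z[-idx[r, ], e])
        expect_equal(fast[r, e], slow, tolerance = 1e-10)
      }
    }
  })
})

test_that("exhaustive permutation p-values match brute-force enumeration", {
  # independent oracle: iterate over all bitmasks, classical F via
  # oneway.test, count >= observed
  brute_p <- function(y, x) {
    n1 <- length(y)
    n <- n1 + length(x)
    z <- c(y, x)
    f_of <- function(sel) {
      g <- factor(ifelse(seq_len(n) %in% sel, "a", "b"))
      unname(stats::oneway.test(z ~ g, var.equal = TRUE)$statistic)
    }
    obs <- f_of(seq_len(n1))
    stats <- c()
    for (mask in 0:(2^n - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(sel) == n1) stats <- c(stats, f_of(sel))
    }
    mean(stats >= obs - 1e-12)
  }
  cases <- list(
    list(y = c(0, 0.1), x = c(1, 1.1)),
    list(y = c(0.3, 0.7, 0.2), x = c(0.5, 0.9)),
    list(y = c(1, 2, 3, 4), x = c(2, 3, 4, 5)))
  for (cs in cases) {
    pt <- permutation_test(cs$y, cs$x)
    expect_true(pt$exhaustive)
    expect_equal(pt$raw_p, brute_p(cs$y, cs$x))
  }
  # the two-versus-two example: only the identity and full swap are extreme
  pt <- permutation_test(c(0, 0.1), c(1, 1.1))
  expect_equal(pt$raw_p, 2 / 6)
})

test_that("exhaustive p-values are invariant to which sample is labelled male", {
  withr::with_seed(43, {
    y <- rnorm(4)
    x <- rnorm(5, 1)
  })
  expect_equal(permutation_test(y, x)$raw_p, permutation_test(x, y)$raw_p)
})

test_that("Monte-Carlo p-values are reproducible, positive and seed-scoped", {
  withr::with_seed(47, {
    y <- rnorm(12)
    x <- rnorm(12, 3)
  })
  p1 <- permutation_test(y, x, n_perm = 200, seed = 99,
                         exhaustive_limit = 10)
  p2 <- permutation_test(y, x, n_perm = 200, seed = 99,
                         exhaustive_limit = 10)
  expect_false(p1$exhaustive)
  expect_identical(p1$raw_p, p2$raw_p)
  expect_gt(p1$raw_p, 0) # (1 + hits) / (1 + n_perm) can never be 0
  expect_equal(p1$raw_p, 1 / 201)
  expect_error(permutation_test(y, x, n_perm = 0), "n_perm")
})

test_that("degenerate links keep permutation p-values well defined", {
  # Inf sentinel: pure splits are the only ones as extreme
  pt <- permutation_test(c(1, 1), c(2, 2))
  expect_identical(pt$statistic, Inf)
  expect_equal(pt$raw_p, 2 / 6)
  # all-identical data: every permutation ties the observed 0
  pt2 <- permutation_test(rep(1, 3), rep(1, 3))
  expect_equal(pt2$statistic, 0)
  expect_equal(pt2$raw_p, 1)
})

test_that("Holm adjustment reproduces the hand-derived step-down values", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(rep(0.02, 5)), rep(0.1, 5))
  withr::with_seed(53, {
    p <- runif(20, 0.001, 1)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-15))
    expect_true(all(adj <= 1))
  })
  expect_error(holm_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(holm_adjust(1.2), "\\(0, 1\\]")
})

test_that("the stat dataset restricts weights to the link set by group", {
  withr::with_seed(59, {
    cohort <- tibble::tibble(
      subject_id = paste0("s", 1:6),
      sex = rep(c("M", "F"), 3),
      age = c(12, 14, 47, 50, 72, 78))
    weights <- lapply(1:6, function(i) rand_fs(6, p_zero = 0.2))
    names(weights) <- cohort$subject_id
  })
  links <- tibble::tibble(node_i = c(1, 2), node_j = c(4, 5))
  ds <- build_stat_dataset(cohort, weights, links)
  expect_named(ds$groups, age_group_scheme("seven")$label)
  g1 <- ds$groups[["6-15"]]
  expect_equal(dim(g1$y), c(1, 2))
  expect_equal(g1$y[1, 1], weights$s1[1, 4])
  expect_equal(g1$x[1, 2], weights$s2[2, 5])
  expect_equal(dim(ds$groups[["26-35"]]$y), c(0, 2))
})

test_that("global analysis flags nothing on identical data and skips thin groups", {
  links <- tibble::tibble(node_i = 1, node_j = 2)
  same <- matrix(0.5, 3, 3)
  cohort <- tibble::tibble(subject_id = paste0("s", 1:8),
                           sex = rep(c("M", "F"), 4),
                           age = c(12, 14, 13, 12, 72, 78, 75, 74))
  weights <- setNames(replicate(8, same, simplify = FALSE),
                      cohort$subject_id)
  ds <- build_stat_dataset(cohort, weights, links)
  res <- suppressWarnings(run_global_analysis(ds, n_perm = 50, seed = 1))
  expect_s3_class(res, "fd_global_result")
  expect_true(all(res$raw_p == 1))
  expect_false(any(res$significant))
  expect_equal(nrow(res), 2) # only the populated groups survive
  w <- testthat::capture_warnings(run_global_analysis(ds, n_perm = 50,
                                                      seed = 1))
  expect_true(any(grepl("skipped", w)))
})

test_that("local analysis with a single link leaves Holm untouched", {
  withr::with_seed(61, {
    cohort <- tibble::tibble(subject_id = paste0("s", 1:8),
                             sex = rep(c("M", "F"), each = 4),
                             age = 72:79)
    weights <- lapply(1:8, function(i) {
      m <- matrix(0, 3, 3)
      m[1, 2] <- m[2, 1] <- rnorm(1, ifelse(i <= 4, 0, 3))
      m
    })
    names(weights) <- cohort$subject_id
  })
  links <- tibble::tibble(node_i = 1, node_j = 2)
  ds <- build_stat_dataset(cohort, weights, links)
  loc <- run_local_analysis(ds, "71-79", n_perm = 200, seed = 5)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$adj_p, loc$raw_p)
  expect_error(run_local_analysis(ds, "nope"), "unknown group")
})

test_that("local p-values under the null are roughly uniform", {
  withr::with_seed(67, {
    cohort <- tibble::tibble(subject_id = paste0("s", 1:16),
                             sex = rep(c("M", "F"), each = 8),
                             age = rep(72:79, 2))
    weights <- lapply(1:16, function(i) rand_fs(10, p_zero = 0))
    names(weights) <- cohort$subject_id
    pairs <- which(upper.tri(diag(10)), arr.ind = TRUE)[1:30, ]
    links <- tibble::tibble(node_i = pairs[, 1], node_j = pairs[, 2])
    ds <- build_stat_dataset(cohort, weights, links)
    loc <- run_local_analysis(ds, "71-79", n_perm = 400)
    # expected ~5% of raw p below 0.05; allow generous binomial slack
    expect_lt(mean(loc$raw_p < 0.05), 0.25)
    # Holm keeps the family error small: a couple of hits at most
    expect_lte(sum(loc$significant), 2)
  })
})
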