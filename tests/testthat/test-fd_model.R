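test_that("negative correlations are zeroed and positives untouched", {
  f <- matrix(c(1, -0.3, -0.3, 1), 2)
  expect_equal(clip_negatives(f), matrix(c(1, 0, 0, 1), 2))
  f2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(clip_negatives(f2), f2)
  withr::with_seed(3, {
    f3 <- rand_sym(10)
    clipped <- clip_negatives(f3)
    expect_equal(sum(clipped == 0), sum(f3 < 0)) # oracle: elementwise scan
    expect_equal(clipped[f3 >= 0], f3[f3 >= 0])
  })
  bad <- matrix(runif(16), 4)
  bad[1, 2] <- bad[2, 1] + 1
  expect_error(clip_negatives(bad), "symmetric")
})

test_that("first threshold keeps entries strictly above the bin-2 edge", {
  # off-diagonal pairs 0.05, 0.15, 0.25, 0.90 (plus two zero pairs)
  f <- matrix(0, 4, 4)
  f[1, 2] <- 0.05; f[1, 3] <- 0.15; f[1, 4] <- 0.25; f[2, 3] <- 0.90
  f[lower.tri(f)] <- t(f)[lower.tri(f)]
  noi <- first_threshold(f)
  kept <- sort(unique(noi$fs[noi$fs > 0]))
  expect_equal(kept, c(0.25, 0.90))
  expect_equal(noi$noi_threshold, 0.2)
  expect_equal(noi$retained_fraction, 4 / 12) # 2 of 6 pairs, both triangles

  # ties at the cut are dropped; everything at or below 0.2 -> empty
  f2 <- matrix(0.2, 3, 3); diag(f2) <- 0
  noi2 <- first_threshold(f2)
  expect_true(all(noi2$fs == 0))
  expect_equal(noi2$retained_fraction, 0)

  expect_error(first_threshold(matrix(c(0, 1.2, 1.2, 0), 2)), "\\[0, 1\\]")
})

test_that("first threshold agrees with a naive elementwise scan", {
  withr::with_seed(11, {
    f <- abs(rand_sym(12, 0, 1))
    diag(f) <- 1
    noi <- first_threshold(f)
    ref <- f
    ref[f <= 0.2] <- 0
    diag(ref) <- 0
    expect_equal(noi$fs, ref)
  })
})

test_that("node degrees count nonzero off-diagonal row entries", {
  fs <- matrix(0, 4, 4)
  fs[1, 3] <- fs[3, 1] <- 0.5
  expect_equal(node_degrees(fs), c(1L, 0L, 1L, 0L))
  full <- matrix(0.4, 5, 5)
  expect_equal(node_degrees(full), rep(4L, 5)) # diagonal ignored
  withr::with_seed(8, {
    m <- rand_fs(15)
    expect_equal(node_degrees(m),
                 vapply(1:15, function(v) sum(m[v, -v] != 0), 1L))
  })
})

test_that("FD weights match the hand-evaluated two-node case", {
  fs <- matrix(c(0, 0.6, 0.6, 0), 2)
  d <- matrix(c(0, 1, 1, 0), 2)
  fw <- fd_weights(fs, d, eta = 1)
  # deg = 1 each: unnormalized w = 1 * 1 * exp(-(1 - 0.6))
  expect_equal(fw$wmax, exp(-0.4))
  expect_equal(fw$w[1, 2], 1)
  expect_equal(diag(fw$w), c(0, 0))
})

test_that("equal degrees, zero distance and equal correlations level out", {
  fs <- matrix(0.5, 4, 4); diag(fs) <- 0
  d <- matrix(0, 4, 4)
  fw <- fd_weights(fs, d)
  off <- fw$w[!diag(4)]
  expect_true(all(off == 1))
})

test_that("weights increase in correlation and decrease in distance", {
  withr::with_seed(21, {
    fs <- rand_fs(8, p_zero = 0.3)
    d <- matrix(runif(64, 0.1, 0.9), 8, 8)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    base <- fd_weights(fs, d)
    unnorm <- function(x) x$w * x$wmax
    nz <- which(fs > 0 & upper.tri(fs), arr.ind = TRUE)
    for (r in seq_len(min(5, nrow(nz)))) {
      i <- nz[r, 1]; j <- nz[r, 2]
      fs2 <- fs
      fs2[i, j] <- fs2[j, i] <- min(1, fs[i, j] + 0.05) # degrees unchanged
      up <- fd_weights(fs2, d)
      expect_gt(unnorm(up)[i, j], unnorm(base)[i, j])
      d2 <- d
      d2[i, j] <- d2[j, i] <- min(1, d[i, j] + 0.05)
      down <- fd_weights(fs, d2)
      expect_lt(unnorm(down)[i, j], unnorm(base)[i, j])
    }
  })
})

test_that("all-isolated input yields the all-zero weight matrix", {
  fs <- matrix(0, 5, 5)
  d <- matrix(0.5, 5, 5); diag(d) <- 0
  fw <- fd_weights(fs, d)
  expect_true(all(fw$w == 0))
  expect_equal(fw$wmax, 0)
})

test_that("normalization contract: max weight is 1 and shape mismatch errors", {
  withr::with_seed(5, {
    fs <- rand_fs(10)
    d <- distance_matrix(rand_centroids(10))
    dimnames(d) <- NULL
    fw <- fd_weights(fs, d)
    expect_equal(max(fw$w), 1)
    # explicit reconstruction of the formula
    deg <- node_degrees(fs)
    w_ref <- outer(deg, deg) * exp(-(d - fs))
    diag(w_ref) <- 0
    expect_equal(fw$w, w_ref / max(w_ref))
  })
  expect_error(fd_weights(matrix(0, 3, 3), matrix(0, 4, 4)),
               "shape mismatch")
  expect_error(fd_weights(matrix(0, 3, 3), matrix(0, 3, 3), eta = 0),
               "eta")
})

test_that("masking restricts weights to the retained correlation support", {
  withr::with_seed(6, {
    fs <- rand_fs(8)
    d <- distance_matrix(rand_centroids(8))
    dimnames(d) <- NULL
    fw <- fd_weights(fs, d, mask_zero_correlation = TRUE)
    expect_true(all(fw$w[fs == 0 & !diag(8)] == 0))
    fw2 <- fd_weights(fs, d)
    deg <- node_degrees(fs)
    pos <- deg > 0
    expect_true(all(fw2$w[pos, pos][!diag(sum(pos))] > 0))
  })
})

test_that("the per-subject pipeline is deterministic", {
  withr::with_seed(9, {
    f <- rand_sym(12)
    d <- distance_matrix(rand_centroids(12))
    dimnames(d) <- NULL
  })
  a <- subject_weights(f, d)
  b <- subject_weights(f, d)
  expect_identical(a$w, b$w)
  expect_identical(a$wmax, b$wmax)
})
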