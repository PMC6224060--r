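# Shared generators for randomized tests. All symmetric with zero or unit
# diagonal as the operation under test expects.

rand_sym <- function(n, lo = -1, hi = 1) {
  m <- matrix(stats::runif(n * n, lo, hi), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# sparse non-negative thresholded-style matrix, zero diagonal
rand_fs <- function(n, p_zero = 0.6, cut = 0.2) {
  m <- matrix(stats::runif(n * n, cut + 1e-6, 1), n, n)
  m[stats::runif(n * n) < p_zero] <- 0
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

rand_centroids <- function(n) {
  tibble::tibble(node_id = seq_len(n),
                 x = stats::runif(n, -70, 70),
                 y = stats::runif(n, -100, 70),
                 z = stats::runif(n, -50, 80))
}

# tiny cohort configuration: two populated age groups, a 4-node community
# out of 20 nodes, short series -- fast enough for pipeline-level tests
tiny_config <- function(seed = 1, n_per_cell = 3, effects = NULL) {
  sizes <- tibble::tibble(
    label = c("46-50", "71-75"),
    age_lo = c(46, 71), age_hi = c(50, 75),
    n_male = n_per_cell, n_female = n_per_cell)
  cohort_config(group_sizes = sizes, community = c(1L, 2L, 11L, 12L),
                n_nodes = 20, t_points = 80, seed = seed,
                effects = effects)
}
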