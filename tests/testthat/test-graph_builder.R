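make_star <- function(n, center = 1, weight = 0.5) {
  m <- matrix(0, n, n)
  for (v in setdiff(seq_len(n), center)) {
    m[center, v] <- m[v, center] <- weight
  }
  m
}

test_that("centrality index normalizes degree sums across groups", {
  star <- make_star(5)
  ct <- centrality_index(list(star))
  expect_equal(ct$ci[ct$node == 1], 1)
  expect_equal(ct$ci[ct$node != 1], rep(1 / 4, 4))
  # brute-force oracle on random matrices
  withr::with_seed(19, {
    mats <- replicate(3, rand_fs(8), simplify = FALSE)
    ct2 <- centrality_index(mats)
    sums <- rowSums(vapply(mats, node_degrees, integer(8)))
    keep <- which(sums > 0)
    ref <- tibble::tibble(node = keep, ci = sums[keep] / max(sums[keep]))
    expect_equal(dplyr::arrange(ct2, node)$ci,
                 dplyr::arrange(ref, node)$ci)
    expect_equal(max(ct2$ci), 1)
  })
})

test_that("the CI cutoff is the 5th-bin midpoint of the observed range", {
  expect_equal(ci_cutoff(tibble::tibble(ci = c(0, 1))), 0.45)
  expect_equal(ci_cutoff(tibble::tibble(ci = c(0.02, 1.00))),
               0.02 + 4.5 * 0.098)
  expect_error(ci_cutoff(tibble::tibble(ci = rep(0.5, 4))), "distinct")
})

test_that("vertex selection on the reference tables yields the published sets", {
  cm <- load_fixture("centrality_male")
  cf <- load_fixture("centrality_female")
  lm <- load_fixture("link_frequencies_male")
  lf <- load_fixture("link_frequencies_female")
  expect_equal(round(ci_cutoff(cm), 2), 0.46)
  expect_equal(round(ci_cutoff(cf), 2), 0.46)
  vp_m <- principal_vertices(cm, 0.46)
  vp_f <- principal_vertices(cf, 0.46)
  expect_equal(vp_m, c(22, 28, 29, 30, 31, 48, 69, 75, 76, 77, 78))
  expect_equal(vp_f, c(22, 30, 31, 48, 69, 75, 76, 78))
  expect_equal(secondary_vertices(lm, vp_m), 1)
  expect_equal(secondary_vertices(lf, vp_f), c(1, 28, 29, 77))
  expect_equal(principal_vertices(cm, 1.01), numeric(0))
})

test_that("edge selection follows the principal/secondary rules", {
  lm <- load_fixture("link_frequencies_male")
  lf <- load_fixture("link_frequencies_female")
  vp_m <- principal_vertices(load_fixture("centrality_male"), 0.46)
  vp_f <- principal_vertices(load_fixture("centrality_female"), 0.46)
  ep <- principal_edges(lm, vp_m)
  expect_true(any(ep$node_i == 31 & ep$node_j == 78))
  expect_false(any(ep$node_i == 54 & ep$node_j == 64)) # endpoints not in V'
  expect_equal(nrow(principal_edges(lm, integer(0))), 0)

  vs_m <- secondary_vertices(lm, vp_m)
  es_m <- secondary_edges(lm, vp_m, vs_m)
  expect_true(any(es_m$node_i == 1 & es_m$node_j == 48)) # freq 10 >= 7
  vs_f <- secondary_vertices(lf, vp_f)
  es_f <- secondary_edges(lf, vp_f, vs_f)
  # both endpoints secondary: any nonzero frequency qualifies
  expect_true(any(es_f$node_i == 28 & es_f$node_j == 29))
  expect_equal(nrow(secondary_edges(lm, vp_m, integer(0))), 0)
  # principal and secondary edge sets are disjoint
  key <- function(e) paste(e$node_i, e$node_j)
  expect_length(intersect(key(ep), key(es_m)), 0)

  capped <- dplyr::mutate(lm, frequency = pmin(frequency, 6L))
  expect_length(secondary_vertices(capped, vp_m), 0)
})

test_that("lowering thresholds never shrinks the selected sets", {
  cm <- load_fixture("centrality_male")
  lm <- load_fixture("link_frequencies_male")
  prev_v <- integer(0)
  for (cut in c(0.8, 0.6, 0.46, 0.2)) {
    vp <- principal_vertices(cm, cut)
    expect_true(all(prev_v %in% vp))
    prev_v <- vp
  }
  vp <- principal_vertices(cm, 0.46)
  prev_s <- integer(0)
  for (mf in c(12, 9, 7, 3, 1)) {
    vs <- secondary_vertices(lm, vp, min_freq = mf)
    expect_true(all(prev_s %in% vs))
    prev_s <- vs
  }
})

test_that("graph assembly keeps one copy of duplicated edges and checks endpoints", {
  ep <- tibble::tibble(node_i = 1, node_j = 2, frequency = 9L)
  es <- tibble::tibble(node_i = c(1, 2), node_j = c(2, 3),
                       frequency = c(9L, 3L))
  g <- build_graph(vp = c(1, 2), vs = 3, ep = ep, es = es)
  expect_equal(nrow(g$edges), 2)
  e12 <- g$edges[g$edges$node_i == 1 & g$edges$node_j == 2, ]
  expect_equal(e12$class, "principal")
  expect_error(build_graph(vp = 1, vs = 1, ep = ep[0, ], es = es[0, ]),
               "disjoint")
  expect_error(build_graph(vp = c(1, 2), vs = integer(0), ep = ep,
                           es = tibble::tibble(node_i = 7, node_j = 1,
                                               frequency = 8L)),
               "endpoint")
  empty <- build_graph(integer(0), integer(0), ep[0, ], es[0, ])
  expect_equal(nrow(empty$vertices), 0)
})

test_that("the representative graphs for the two sexes share their vertex union", {
  g_m <- representative_graph(load_fixture("link_frequencies_male"),
                              load_fixture("centrality_male"))
  g_f <- representative_graph(load_fixture("link_frequencies_female"),
                              load_fixture("centrality_female"))
  expect_equal(attr(g_m, "cutoff"), 0.46)
  union <- c(1, 22, 28, 29, 30, 31, 48, 69, 75, 76, 77, 78)
  expect_equal(g_m$vertices$node, union)
  expect_equal(g_f$vertices$node, union)
  # both published graphs: two connected components, each planar
  for (g in list(g_m, g_f)) {
    p <- graph_properties(g)
    expect_equal(p$n_components, 2)
    expect_true(p$planar)
  }
})

test_that("graph properties report components and planarity", {
  single <- igraph::make_graph(~ a - b)
  p <- graph_properties(single)
  expect_equal(p$n_components, 1)
  expect_true(p$planar)
  expect_false(graph_properties(igraph::make_full_graph(5))$planar)
})
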