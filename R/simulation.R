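#' Familywise error rate of the global analysis under a null cohort
#'
#' Repeatedly simulates cohorts with no male/female difference
#' (`delta = 0`), runs the full pipeline up to the 7-group global
#' permutation analysis — per-subject FD weights, 14-group averaging and
#' second thresholding, per-cohort emerging-link extraction, merged-group
#' sum-of-F permutation tests with Holm adjustment — and reports the
#' fraction of cohorts in which any adjusted p-value falls below `level`.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_perm Monte-Carlo permutations per group test.
#' @param seed master seed; per-cohort seeds are derived from it.
#' @param cfg cohort configuration (effects are ignored/forced to NULL).
#' @param level familywise level.
#' @param cut,eta first-threshold cut and distance weight.
#' @return list with `fwer` (proportion in `[0, 1]`), `n_flagged`,
#'   `n_cohorts`, `flags` (logical vector).
#' @export
simulate_global_null_fwer <- function(n_cohorts = 500, n_perm = 200,
                                      seed = 1, cfg = cohort_config(),
                                      level = 0.05, cut = 0.2, eta = 1) {
  cfg$effects <- NULL
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, n_cohorts + 1))
  d <- distance_matrix(generate_centroids(seeds[n_cohorts + 1],
                                          n_nodes = cfg$n_nodes))
  flags <- vapply(seq_len(n_cohorts), function(i) {
    cfg$seed <- seeds[i]
    cohort <- generate_cohort(cfg)
    withr::with_seed(seeds[i] %% 1000000L + i, {
      g <- cohort_global_analysis(cohort, d, n_perm = n_perm,
                                  level = level, cut = cut, eta = eta)
      any(g$significant)
    })
  }, logical(1))
  list(fwer = mean(flags), n_flagged = sum(flags),
       n_cohorts = n_cohorts, flags = flags)
}

# Per-cohort path from subjects to the global test table: weights,
# per-sex 14-group thresholded averages, pooled emerging links, merged
# dataset, global analysis.
cohort_global_analysis <- function(cohort, d, n_perm, level = 0.05,
                                   cut = 0.2, eta = 1) {
  man <- cohort$manifest
  weights <- lapply(cohort$subjects, function(s) {
    subject_weights(s$f, d, cut = cut, eta = eta)$w
  })
  names(weights) <- man$subject_id
  grouped <- assign_groups(man, "fourteen")
  mats <- list()
  for (sx in c("M", "F")) {
    for (lab in unique(grouped$group_label[grouped$sex == sx])) {
      ids <- grouped$subject_id[grouped$sex == sx &
                                  grouped$group_label == lab]
      mats[[paste(sx, lab)]] <-
        second_threshold(average_group(weights[ids]))$wstar
    }
  }
  links <- extract_links(mats)
  dataset <- build_stat_dataset(man, weights,
                                tibble::as_tibble(links)[, c("node_i",
                                                             "node_j")])
  run_global_analysis(dataset, n_perm = n_perm, level = level)
}

#' Selection power of the local analysis for one injected link
#'
#' Estimates, as a function of the injected correlation increase `delta`,
#' the probability that the local analysis selects the target link at the
#' Holm-adjusted `level`, in the merged age group carrying the effect.
#' Only that group's subjects are simulated (the local test involves no
#' other subject); the link set defaults to the pooled 29-link reference
#' set L so the multiplicity burden matches the reference analysis.
#'
#' @param deltas vector of correlation increases to scan (0 gives the
#'   false-selection rate).
#' @param n_cohorts simulated replicates per delta.
#' @param n_perm Monte-Carlo permutations per local test.
#' @param seed master seed.
#' @param link target link (two node ids).
#' @param group merged-group label carrying the effect.
#' @param effect_sex sex receiving the effect.
#' @param links link set L (tibble `node_i`, `node_j`); default the pooled
#'   reference emerging links.
#' @param cfg cohort configuration template (community, correlations,
#'   series length).
#' @param level adjusted significance level for selection.
#' @param cut,eta first-threshold cut and distance weight.
#' @return tibble with columns `delta`, `power`, `n_cohorts`.
#' @export
simulate_link_power <- function(deltas = c(0, 0.25, 0.45, 0.54),
                                n_cohorts = 100, n_perm = 999, seed = 1,
                                link = c(31, 78), group = "71-79",
                                effect_sex = "F", links = NULL,
                                cfg = cohort_config(), level = 0.05,
                                cut = 0.2, eta = 1) {
  if (is.null(links)) links <- reference_link_union()
  merged <- load_fixture("merged_groups")
  row <- merged[merged$label == group, ]
  if (nrow(row) != 1) rlang::abort(sprintf("unknown merged group '%s'", group))
  d <- distance_matrix(generate_centroids(seed, n_nodes = cfg$n_nodes))
  link_row <- which(links$node_i == min(link) & links$node_j == max(link))
  if (length(link_row) != 1) rlang::abort("target link not in link set")
  out <- purrr::map(deltas, function(delta) {
    cfg$effects <- if (delta > 0) {
      tibble::tibble(node_i = min(link), node_j = max(link),
                     group = group, sex = effect_sex, delta = delta)
    } else NULL
    seeds <- withr::with_seed(seed + round(1000 * delta),
                              sample.int(.Machine$integer.max, n_cohorts))
    hits <- vapply(seq_len(n_cohorts), function(i) {
      withr::with_seed(seeds[i], {
        subs <- c(
          lapply(seq_len(row$n_male), function(k) {
            generate_subject(cfg, "M", sample(row$age_lo:row$age_hi, 1),
                             sprintf("M%02d", k))
          }),
          lapply(seq_len(row$n_female), function(k) {
            generate_subject(cfg, "F", sample(row$age_lo:row$age_hi, 1),
                             sprintf("F%02d", k))
          }))
        man <- tibble::tibble(
          subject_id = vapply(subs, `[[`, "", "subject_id"),
          sex = vapply(subs, `[[`, "", "sex"),
          age = vapply(subs, `[[`, 1L, "age"))
        weights <- lapply(subs, function(s) {
          subject_weights(s$f, d, cut = cut, eta = eta)$w
        })
        names(weights) <- man$subject_id
        dataset <- build_stat_dataset(man, weights, links)
        loc <- run_local_analysis(dataset, group, n_perm = n_perm,
                                  levels = c(level, 0.10))
        any(loc$significant & loc$node_i == min(link) &
              loc$node_j == max(link))
      })
    }, logical(1))
    tibble::tibble(delta = delta, power = mean(hits),
                   n_cohorts = n_cohorts)
  })
  dplyr::bind_rows(out)
}

#' The pooled reference emerging-link set L
#'
#' Union of the male and female emerging-link sets from the packaged
#' reference tables (Q = 29 links).
#'
#' @return tibble with columns `node_i`, `node_j`, sorted.
#' @export
reference_link_union <- function() {
  l <- dplyr::distinct(dplyr::bind_rows(
    load_fixture("link_frequencies_male")[, c("node_i", "node_j")],
    load_fixture("link_frequencies_female")[, c("node_i", "node_j")]))
  dplyr::arrange(l, .data$node_i, .data$node_j)
}
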