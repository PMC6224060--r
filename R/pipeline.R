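#' Load a packaged reference table
#'
#' Parses one of the plain-text reference tables shipped with the package
#' (see `inst/extdata/README.md` for provenance and known print defects).
#'
#' @param name one of `"atlas"`, `"cohort_groups"`, `"merged_groups"`,
#'   `"link_frequencies_male"`, `"link_frequencies_female"`,
#'   `"link_intensities_male"`, `"link_intensities_female"`,
#'   `"centrality_male"`, `"centrality_female"`,
#'   `"representative_vertices"`.
#' @return tibble.
#' @export
load_fixture <- function(name) {
  available <- c("atlas", "cohort_groups", "merged_groups",
                 "link_frequencies_male", "link_frequencies_female",
                 "link_intensities_male", "link_intensities_female",
                 "centrality_male", "centrality_female",
                 "representative_vertices")
  if (!name %in% available) {
    rlang::abort(sprintf("unknown fixture '%s'; available: %s",
                         name, paste(available, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "fdconnect", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable choice of the end-to-end analysis in one list.
#' Defaults match the reference analysis: first-threshold cut 0.2 (upper
#' edge of histogram bin 2), distance weight `eta = 1` on normalized
#' distances, top-decile-midpoint second threshold, 10 CI histogram bins,
#' secondary-vertex frequency 7, 9999 Monte-Carlo permutations, 5%/10%
#' significance levels, histogram-gap comparison threshold.
#'
#' @param cut first-threshold cut.
#' @param eta distance weight.
#' @param mask_zero_correlation restrict FD weights to the retained
#'   correlation support.
#' @param second_mode second-threshold construction, see
#'   [second_threshold()].
#' @param ci_bins CI histogram bins.
#' @param min_freq secondary-vertex minimum link frequency.
#' @param n_perm Monte-Carlo permutations.
#' @param exhaustive_limit see [permutation_test()].
#' @param seed integer seed for the permutation draws (mandatory for a
#'   reproducible run).
#' @param levels strict and weak significance levels.
#' @param comparison_mode threshold mode for [select_discrepant_links()].
#' @param comparison_threshold fixed threshold when
#'   `comparison_mode = "fixed"`.
#' @param output_dir optional directory where all intermediate artifacts
#'   and the JSON run report are written.
#' @return list of class `fd_pipeline_config`.
#' @export
fd_pipeline_config <- function(cut = 0.2, eta = 1,
                               mask_zero_correlation = FALSE,
                               second_mode = "top_decile_midpoint",
                               ci_bins = 10, min_freq = 7,
                               n_perm = 9999, exhaustive_limit = 20000,
                               seed = 1, levels = c(0.05, 0.10),
                               comparison_mode = "histogram_gap",
                               comparison_threshold = NULL,
                               output_dir = NULL) {
  structure(as.list(environment()), class = "fd_pipeline_config")
}

#' Run the end-to-end connectivity analysis
#'
#' Executes, in order: negative clipping, first thresholding, FD
#' weighting (per subject); 14-group averaging and second thresholding
#' (per sex); emerging-link extraction, centrality index and
#' representative-graph construction (per sex); merged-group global and
#' local permutation analyses on the pooled link set; and the FD versus
#' pure-correlation comparison. When only one sex is present the
#' statistical stage is skipped with a warning. Any stage error aborts
#' with the stage name.
#'
#' @param cohort an `fd_cohort` from [generate_cohort()], or a manifest
#'   path (see [read_cohort_manifest()]).
#' @param centroids centroid tibble, or `NULL` to use the cohort's own
#'   centroids (synthetic cohorts carry them).
#' @param distance optional precomputed normalized distance matrix; takes
#'   precedence over `centroids`.
#' @param config an [fd_pipeline_config()].
#' @return object of class `fd_pipeline_result`: list with per-stage
#'   outputs (`weights`, `group_matrices`, `links`, `centrality`,
#'   `graphs`, `graph_properties`, `global`, `local`, `comparison`) and a
#'   `report` list capturing config, seed and thresholds used.
#' @export
run_pipeline <- function(cohort, centroids = NULL, distance = NULL,
                         config = fd_pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  if (is.character(cohort)) {
    man <- read_cohort_manifest(cohort)
    subjects <- purrr::pmap(man, function(subject_id, sex, age, path, ...) {
      list(subject_id = subject_id, sex = sex, age = age,
           f = read_connectivity_matrix(path))
    })
    cohort <- list(subjects = subjects,
                   manifest = man[, c("subject_id", "sex", "age")],
                   centroids = NULL)
  }
  man <- cohort$manifest
  if (is.null(distance)) {
    cen <- if (!is.null(centroids)) centroids else cohort$centroids
    if (is.null(cen)) rlang::abort("need centroids or a distance matrix")
    n <- nrow(cohort$subjects[[1]]$f)
    distance <- stage("distance",
                      distance_matrix(cen, normalize = TRUE,
                                      nodes = seq_len(n)))
  }

  weights <- stage("fd_model", {
    w <- lapply(cohort$subjects, function(s) {
      subject_weights(s$f, distance, cut = config$cut, eta = config$eta,
                      mask_zero_correlation = config$mask_zero_correlation)
    })
    names(w) <- man$subject_id
    w
  })

  grouped <- stage("grouping", assign_groups(man, "fourteen"))
  sexes <- sort(unique(man$sex), decreasing = TRUE) # M before F
  group_matrices <- stage("group_average", {
    out <- list()
    for (sx in sexes) {
      labs <- unique(grouped$group_label[grouped$sex == sx])
      labs <- age_group_scheme("fourteen")$label[
        age_group_scheme("fourteen")$label %in% labs]
      mats <- lapply(labs, function(lab) {
        ids <- grouped$subject_id[grouped$sex == sx &
                                    grouped$group_label == lab]
        second_threshold(average_group(weights[ids]),
                         mode = config$second_mode)
      })
      names(mats) <- labs
      out[[sx]] <- mats
    }
    out
  })

  links <- stage("extract_links",
                 lapply(group_matrices, extract_links))
  centrality <- stage("centrality",
                      lapply(group_matrices, centrality_index))
  graphs <- stage("graph_builder", {
    purrr::map2(links, centrality, function(lt, ct) {
      representative_graph(lt, ct, n_bins = config$ci_bins,
                           min_freq = config$min_freq)
    })
  })
  props <- lapply(graphs, graph_properties)

  pooled_links <- dplyr::distinct(
    dplyr::bind_rows(lapply(links, function(l) {
      tibble::as_tibble(l)[, c("node_i", "node_j")]
    })))
  pooled_links <- dplyr::arrange(pooled_links, .data$node_i, .data$node_j)

  global <- local <- NULL
  if (length(sexes) == 2) {
    dataset <- stage("stat_dataset",
                     build_stat_dataset(man, weights, pooled_links))
    global <- stage("global_analysis",
                    run_global_analysis(dataset, n_perm = config$n_perm,
                                        seed = config$seed,
                                        level = config$levels[1],
                                        exhaustive_limit =
                                          config$exhaustive_limit))
    flagged <- global$group[global$significant]
    local <- lapply(flagged, function(gr) {
      run_local_analysis(dataset, gr, n_perm = config$n_perm,
                         seed = config$seed + 1L,
                         levels = config$levels,
                         exhaustive_limit = config$exhaustive_limit)
    })
    names(local) <- flagged
  } else {
    rlang::warn("only one sex present: statistical stage skipped")
  }

  comparison <- stage("model_comparison", {
    f_list <- lapply(cohort$subjects, function(s) clip_negatives(s$f))
    compare_models(weights, f_list,
                   threshold_mode = config$comparison_mode,
                   threshold = config$comparison_threshold)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("fdconnect")),
    n_subjects = nrow(man),
    sexes = as.list(table(man$sex)),
    config = unclass(config)[setdiff(names(config), "output_dir")],
    second_thresholds = lapply(group_matrices, function(g) {
      lapply(g, function(x) list(m = x$m, lam = x$lam))
    }),
    ci_cutoff = lapply(graphs, attr, "cutoff"),
    n_links = lapply(links, nrow),
    q_pooled = nrow(pooled_links),
    comparison_threshold = comparison$threshold)

  result <- structure(
    list(distance = distance, weights = weights,
         group_matrices = group_matrices, links = links,
         centrality = centrality, graphs = graphs,
         graph_properties = props, pooled_links = pooled_links,
         global = global, local = local, comparison = comparison,
         report = report),
    class = "fd_pipeline_result")
  if (!is.null(config$output_dir)) {
    write_pipeline_artifacts(result, cohort, config$output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_connectivity_matrix(result$distance,
                            file.path(dir, "distance.tsv"))
  for (sx in names(result$links)) {
    readr::write_tsv(tibble::as_tibble(result$links[[sx]]),
                     file.path(dir, paste0("links_", sx, ".tsv")))
    readr::write_tsv(result$centrality[[sx]],
                     file.path(dir, paste0("centrality_", sx, ".tsv")))
    g <- result$graphs[[sx]]
    readr::write_tsv(g$edges, file.path(dir, paste0("graph_", sx, ".tsv")))
    igraph::write_graph(g$graph,
                        file.path(dir, paste0("graph_", sx, ".graphml")),
                        format = "graphml")
  }
  if (!is.null(result$global)) {
    readr::write_tsv(tibble::as_tibble(result$global),
                     file.path(dir, "global_analysis.tsv"))
    for (gr in names(result$local)) {
      readr::write_tsv(tibble::as_tibble(result$local[[gr]]),
                       file.path(dir, paste0("local_", gr, ".tsv")))
    }
  }
  readr::write_tsv(result$comparison$selected,
                   file.path(dir, "comparison_links.tsv"))
  jsonlite::write_json(result$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.fd_pipeline_result <- function(x, ...) {
  cat(sprintf("<fd_pipeline_result> %d subjects, Q = %d pooled links\n",
              x$report$n_subjects, x$report$q_pooled))
  if (!is.null(x$global)) {
    cat(sprintf("  significant groups: %s\n",
                if (any(x$global$significant))
                  paste(x$global$group[x$global$significant],
                        collapse = ", ") else "none"))
  }
  invisible(x)
}
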