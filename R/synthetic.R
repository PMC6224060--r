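#' The default-mode-network-like node block
#'
#' The twelve nodes used as the correlated community in synthetic cohorts:
#' the union of the principal and secondary vertex sets identified on the
#' reference cohort, so that graph-recovery tests have a known ground
#' truth.
#'
#' @return integer vector of 12 node ids.
#' @export
dmn_block <- function() {
  c(1L, 22L, 28L, 29L, 30L, 31L, 48L, 69L, 75L, 76L, 77L, 78L)
}

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the reference study: the 14 age/sex group sizes of the
#' 133-subject cohort, 94 nodes with a 12-node DMN-like community,
#' within-community correlation 0.45 against a weak 0.05 background, and
#' 160 time points per subject (the acquisition length of the study).
#' Nodes outside the community share only the background correlation,
#' weak enough that background links rarely survive the 0.2 first
#' threshold, mirroring resting-state histograms whose mass sits in the
#' first two bins.
#'
#' @param group_sizes tibble with columns `label`, `age_lo`, `age_hi`,
#'   `n_male`, `n_female`; defaults to the packaged 14-group composition.
#' @param community integer vector of nodes forming the correlated block.
#' @param n_nodes total number of nodes.
#' @param rho_in,rho_out within-community and background correlations,
#'   `0 <= rho_out < rho_in < 1`.
#' @param t_points synthetic time-series length.
#' @param effects optional tibble of injected sex effects with columns
#'   `node_i`, `node_j`, `group` (merged-group label), `sex` (`"M"`/`"F"`),
#'   `delta` (target correlation increase, `>= 0`); applied to subjects of
#'   that sex in that merged age group.
#' @param seed integer seed controlling the whole cohort draw.
#' @return list of class `fd_cohort_config`.
#' @export
cohort_config <- function(group_sizes = NULL, community = dmn_block(),
                          n_nodes = 94, rho_in = 0.45, rho_out = 0.05,
                          t_points = 160, effects = NULL, seed = 1) {
  if (is.null(group_sizes)) {
    group_sizes <- load_fixture("cohort_groups")
  }
  if (!(rho_out >= 0 && rho_out < rho_in && rho_in < 1)) {
    rlang::abort("need 0 <= rho_out < rho_in < 1")
  }
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    stopifnot(all(c("node_i", "node_j", "group", "sex", "delta")
                  %in% names(effects)))
    if (any(effects$delta < 0)) rlang::abort("delta must be >= 0")
  }
  structure(list(group_sizes = tibble::as_tibble(group_sizes),
                 community = as.integer(community), n_nodes = n_nodes,
                 rho_in = rho_in, rho_out = rho_out, t_points = t_points,
                 effects = effects, seed = seed),
            class = "fd_cohort_config")
}

#' Synthetic mirrored-hemisphere centroids
#'
#' Draws 3-D centroids for nodes 1..47 in the left hemisphere (negative x)
#' and mirrors them across the midline for nodes 48..94, matching the
#' atlas' bilateral layout. Coordinates span a brain-sized box in
#' millimetres. No real centroid coordinates are distributed with the
#' package; these synthetic ones stand in for geometry-dependent tests and
#' simulations.
#'
#' @param seed integer seed.
#' @param n_nodes even node count (half per hemisphere).
#' @return tibble with columns `node_id`, `x`, `y`, `z`.
#' @export
generate_centroids <- function(seed = 1, n_nodes = 94) {
  stopifnot(n_nodes %% 2 == 0)
  half <- n_nodes / 2
  withr::with_seed(seed, {
    left <- tibble::tibble(
      node_id = seq_len(half),
      x = stats::runif(half, -70, -8),
      y = stats::runif(half, -105, 70),
      z = stats::runif(half, -45, 80))
  })
  right <- left
  right$node_id <- half + seq_len(half)
  right$x <- -right$x
  dplyr::bind_rows(left, right)
}

# Effect loading that raises the expected correlation of a pair from rho
# to rho + delta: add a * h to both endpoints, a^2 = delta / (1 - rho - delta).
effect_loading <- function(rho, delta) {
  if (rho + delta >= 1) {
    rlang::abort("injected effect too large: base correlation + delta >= 1")
  }
  sqrt(delta / (1 - rho - delta))
}

#' Generate one synthetic subject
#'
#' Node signals follow a latent-factor model: every node loads on a global
#' background factor (weight `sqrt(rho_out)`), community members
#' additionally load on a shared community factor (total within-community
#' correlation `rho_in`), and the remainder is node noise. The empirical
#' correlation matrix of the resulting time series is the subject's
#' connectivity matrix, which is symmetric, unit-diagonal and positive
#' semidefinite by construction. Injected effects add a shared latent
#' component to both endpoints of a link for subjects in the targeted
#' sex and merged age group, raising that link's expected correlation by
#' about `delta`.
#'
#' @param cfg an [cohort_config()] object.
#' @param sex `"M"` or `"F"`.
#' @param age integer age in 6..79.
#' @param subject_id identifier.
#' @param return_signals also return the generated time series (for
#'   verification).
#' @return list with `subject_id`, `sex`, `age`, `f` (correlation matrix)
#'   and optionally `signals`.
#' @export
generate_subject <- function(cfg, sex, age, subject_id = "S1",
                             return_signals = FALSE) {
  n <- cfg$n_nodes
  tt <- cfg$t_points
  comm <- cfg$community
  g <- stats::rnorm(tt)
  f_comm <- stats::rnorm(tt)
  x <- matrix(stats::rnorm(tt * n), tt, n)
  in_comm <- seq_len(n) %in% comm
  load_bg <- sqrt(cfg$rho_out)
  load_comm <- sqrt(cfg$rho_in - cfg$rho_out)
  noise_sd <- ifelse(in_comm, sqrt(1 - cfg$rho_in), sqrt(1 - cfg$rho_out))
  x <- sweep(x, 2, noise_sd, `*`)
  x <- x + load_bg * g
  x[, in_comm] <- x[, in_comm] + load_comm * f_comm
  if (!is.null(cfg$effects) && nrow(cfg$effects) > 0) {
    merged <- age_group_scheme("seven")
    gi <- findInterval(age, merged$age_lo)
    glab <- merged$label[gi]
    hits <- cfg$effects[cfg$effects$sex == sex &
                          cfg$effects$group == glab, ]
    if (nrow(hits) > 0) {
      for (r in seq_len(nrow(hits))) {
        i <- hits$node_i[r]
        j <- hits$node_j[r]
        rho <- if (i %in% comm && j %in% comm) cfg$rho_in else cfg$rho_out
        a <- effect_loading(rho, hits$delta[r])
        h <- stats::rnorm(tt)
        x[, i] <- x[, i] + a * h
        x[, j] <- x[, j] + a * h
      }
    }
  }
  out <- list(subject_id = subject_id, sex = sex, age = as.integer(age),
              f = stats::cor(x))
  if (return_signals) out$signals <- x
  out
}

#' Generate a synthetic cohort
#'
#' Draws every subject of the configured composition (default: the
#' reference cohort's 14 age/sex groups, 51 males and 82 females, 133
#' subjects), with integer ages uniform within each group's range. The
#' whole draw is reproducible from `cfg$seed`.
#'
#' @param cfg an [cohort_config()] object.
#' @return object of class `fd_cohort`: list with `subjects` (list of
#'   subject records), `manifest` (tibble `subject_id`, `sex`, `age`),
#'   `centroids`, `truth` (the injected effects, or `NULL`) and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  withr::with_seed(cfg$seed, {
    plan <- tidyr::pivot_longer(
      cfg$group_sizes[, c("age_lo", "age_hi", "n_male", "n_female")],
      cols = c("n_male", "n_female"),
      names_to = "sex", values_to = "n")
    plan$sex <- ifelse(plan$sex == "n_male", "M", "F")
    rows <- plan[rep(seq_len(nrow(plan)), plan$n), ]
    ages <- mapply(function(lo, hi) sample(lo:hi, 1),
                   rows$age_lo, rows$age_hi)
    ids <- sprintf("S%03d", seq_len(nrow(rows)))
    subjects <- purrr::pmap(
      list(ids, rows$sex, ages),
      function(id, sex, age) generate_subject(cfg, sex, age, id))
  })
  manifest <- tibble::tibble(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    sex = vapply(subjects, `[[`, "", "sex"),
    age = vapply(subjects, `[[`, 1L, "age"))
  structure(list(subjects = subjects, manifest = manifest,
                 centroids = generate_centroids(cfg$seed,
                                                n_nodes = cfg$n_nodes),
                 truth = cfg$effects, config = cfg),
            class = "fd_cohort")
}

#' @export
print.fd_cohort <- function(x, ...) {
  cat(sprintf("<fd_cohort> %d subjects (%d M, %d F), %d nodes, seed %d\n",
              nrow(x$manifest), sum(x$manifest$sex == "M"),
              sum(x$manifest$sex == "F"), x$config$n_nodes,
              x$config$seed))
  invisible(x)
}

#' Write a cohort to disk in the manifest + matrix layout
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$subjects, function(s) {
    p <- file.path(dir, paste0(s$subject_id, ".tsv"))
    write_connectivity_matrix(s$f, p)
    paste0(s$subject_id, ".tsv")
  }, "")
  man <- cohort$manifest
  man$path <- paths
  man_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, man_path)
  readr::write_tsv(cohort$centroids, file.path(dir, "centroids.tsv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(man_path)
}
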