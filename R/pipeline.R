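#' Run the full modularity and integration pipeline
#'
#' Orchestrates every stage of the analysis on one trait table:
#' population-structure adjustment, allometric size correction, per-group
#' correlation/covariance matrices with bootstrap repeatability and pairwise
#' Mantel comparisons, Mantel tests and likelihood comparison of the eleven
#' a priori modularity hypotheses per group, conditional-independence graphs
#' (on population-adjusted, non-size-corrected data) with connectivity and
#' strength metrics, the standardized eigenvalue-variance integration index
#' with pairwise bootstrap comparisons, random-skewers evolvability indices
#' (one shared skewer set across groups), and PCoA of among-group covariance
#' distances. Deterministic given `seed`.
#'
#' @param table A trait table (see [validate_trait_table()]); validated on
#'   entry.
#' @param by Grouping metadata columns.
#' @param n_permutations Mantel permutations per test.
#' @param n_iterations Bootstrap iterations (repeatability, VE and
#'   evolvability comparisons).
#' @param k_skewers Number of random selection vectors.
#' @param alpha Edge significance level for the conditional-independence
#'   graphs.
#' @param seed Integer root seed; every stochastic stage derives a child
#'   stream from it.
#' @param compare_groups Run the pairwise bootstrap VE/evolvability group
#'   comparisons (quadratic in the number of groups; the slowest stage).
#' @param min_group_n Warn when any group is smaller than this.
#' @return A `morph_report` list with elements `table_adjusted`,
#'   `allometry`, `matrices`, `repeatability`, `pairwise_mantel`,
#'   `hypothesis_tests`, `model_comparison`, `graphs`, `graph_metrics`,
#'   `integration`, `ve_comparisons`, `evolvability`,
#'   `evolvability_comparisons`, `pcoa`, `config`.
#' @examples
#' \donttest{
#' tab <- simulate_traits(sim_config(seed = 1))
#' rep <- run_morph_pipeline(tab, n_permutations = 199, n_iterations = 99,
#'                           k_skewers = 200, seed = 1,
#'                           compare_groups = FALSE)
#' rep$integration
#' }
#' @export
run_morph_pipeline <- function(table, by = c("sex", "age", "habitat"),
                               n_permutations = 999, n_iterations = 1000,
                               k_skewers = 1000, alpha = 0.05, seed = 1L,
                               compare_groups = TRUE, min_group_n = 15) {
  table <- validate_trait_table(table)
  sizes <- dplyr::count(table, dplyr::across(dplyr::all_of(by)))
  if (any(sizes$n < min_group_n)) {
    warning("group(s) with fewer than ", min_group_n, " individuals; ",
            "correlation estimates will be noisy", call. = FALSE)
  }

  pop_adj <- adjust_populations(table, by = by)
  allom <- fit_allometry(pop_adj, by = by)
  adjusted <- adjust_allometry(pop_adj, models = allom, by = by)

  mats <- group_matrices(adjusted, by = by, type = "correlation")
  covs <- group_matrices(adjusted, by = by, type = "covariance")

  adj_groups <- dplyr::group_split(
    dplyr::group_by(adjusted, dplyr::across(dplyr::all_of(by)))
  )
  adj_labels <- vapply(adj_groups,
                       function(d) group_label(d[1, by]), character(1))
  ord <- match(mats$label, adj_labels)
  adj_groups <- adj_groups[ord]

  rep_t <- vapply(seq_along(adj_groups), function(i) {
    repeatability(adj_groups[[i]], n_iterations = n_iterations,
                  seed = child_seed(seed, 100 + i))
  }, numeric(1))
  repeat_tbl <- tibble::tibble(label = mats$label, repeatability = rep_t)

  pairwise <- pairwise_group_comparison(mats, n_permutations = n_permutations,
                                        seed = child_seed(seed, 200))

  hyp <- purrr::map2_dfr(mats$matrix, mats$label, function(R, lab) {
    dplyr::mutate(
      test_hypotheses(R, n_permutations = n_permutations,
                      seed = child_seed(seed, 300 + match(lab, mats$label))),
      label = lab, .before = 1
    )
  })
  emmli <- purrr::map2(mats$matrix, mats$n, emmli_fit)
  names(emmli) <- mats$label

  pop_groups <- dplyr::group_split(
    dplyr::group_by(pop_adj, dplyr::across(dplyr::all_of(by)))
  )
  pop_labels <- vapply(pop_groups, function(d) group_label(d[1, by]),
                       character(1))
  pop_groups <- pop_groups[match(mats$label, pop_labels)]
  graphs <- purrr::map2(pop_groups, mats$label, function(d, lab) {
    build_ci_graph(d, alpha = alpha, group = lab)
  })
  names(graphs) <- mats$label
  gmetrics <- purrr::imap_dfr(graphs, function(g, lab) {
    dplyr::mutate(graph_metrics(g)$summary, label = lab, .before = 1)
  })

  integ <- purrr::map2_dfr(mats$matrix, mats$label, function(R, lab) {
    dplyr::mutate(tidy(ve_index(R)), label = lab, .before = 1)
  })

  skewers <- random_skewers(k_skewers, 14, seed = child_seed(seed, 400))
  evolv <- purrr::map2_dfr(covs$matrix, covs$label, function(S, lab) {
    dplyr::mutate(evolvability_indices(S, skewers), label = lab, .before = 1)
  })

  ve_cmp <- evo_cmp <- NULL
  if (compare_groups) {
    pairs <- utils::combn(length(adj_groups), 2)
    cmp <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      v <- compare_ve(adj_groups[[i1]], adj_groups[[i2]],
                      n_iterations = n_iterations,
                      seed = child_seed(seed, 500 + j))
      e <- compare_evolvability(adj_groups[[i1]], adj_groups[[i2]],
                                k = k_skewers, n_iterations = n_iterations,
                                seed = child_seed(seed, 700 + j))
      tibble::tibble(group1 = mats$label[i1], group2 = mats$label[i2],
                     ve_p = v$p, evolvability_p = e$p)
    })
    ve_cmp <- cmp[c("group1", "group2", "ve_p")]
    evo_cmp <- cmp[c("group1", "group2", "evolvability_p")]
  }

  D <- group_distance_matrix(covs)
  ordn <- pcoa(D, n_axes = 2)

  structure(
    list(
      table_adjusted = adjusted, allometry = allom, matrices = mats,
      covariances = covs, repeatability = repeat_tbl,
      pairwise_mantel = pairwise, hypothesis_tests = hyp,
      model_comparison = emmli, graphs = graphs, graph_metrics = gmetrics,
      integration = integ, ve_comparisons = ve_cmp, evolvability = evolv,
      evolvability_comparisons = evo_cmp, pcoa = ordn,
      config = list(by = by, n_permutations = n_permutations,
                    n_iterations = n_iterations, k_skewers = k_skewers,
                    alpha = alpha, seed = seed)
    ),
    class = "morph_report"
  )
}

#' @export
print.morph_report <- function(x, ...) {
  cat("<morph_report>\n")
  cat("  groups:", paste(x$matrices$label, collapse = ", "), "\n")
  cat("  pairwise Mantel comparisons:", nrow(x$pairwise_mantel), "\n")
  cat("  hypothesis tests:", nrow(x$hypothesis_tests), "\n")
  cat(sprintf("  VE_SD range: %.3f-%.3f\n",
              min(x$integration$VE_SD), max(x$integration$VE_SD)))
  cat(sprintf("  evolvability range: %.3f-%.3f\n",
              min(x$evolvability$evolvability),
              max(x$evolvability$evolvability)))
  invisible(x)
}
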