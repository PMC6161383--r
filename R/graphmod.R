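#' Full partial correlations from a correlation matrix
#'
#' The partial correlation between each pair of traits conditional on all
#' remaining traits, obtained from the precision matrix:
#' `partial_r(i, j) = -W[i, j] / sqrt(W[i, i] * W[j, j])` with `W = solve(R)`.
#' The diagonal is set to 1 by convention.
#'
#' @param R An invertible correlation (or covariance) matrix; an error is
#'   raised when the smallest eigenvalue is below 1e-10.
#' @return A symmetric matrix of partial correlations.
#' @examples
#' R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5; R[2, 3] <- R[3, 2] <- 0.5
#' R[1, 3] <- R[3, 1] <- 0.25
#' partial_correlation_matrix(R)[1, 3]  # 0: chain structure
#' @export
partial_correlation_matrix <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    stop("matrix is singular or near-singular (smallest eigenvalue ",
         signif(min(ev), 3), "); partial correlations undefined", call. = FALSE)
  }
  W <- solve(R)
  d <- 1 / sqrt(diag(W))
  P <- -W * outer(d, d)
  diag(P) <- 1
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(R)
  attr(P, "condition_number") <- max(ev) / min(ev)
  P
}

#' Edge-exclusion deviance of a partial correlation
#'
#' The deviance incurred by dropping one edge from a Gaussian graphical
#' model: `EED = -N * log(1 - partial_r^2)`. Compared against the chi-square
#' distribution with 1 degree of freedom; a pair is conditionally
#' independent when EED falls below the critical value (3.841 at p = 0.05).
#'
#' @param partial_r Partial correlation(s), |r| < 1 (vectorised).
#' @param n Sample size.
#' @return Non-negative deviance value(s).
#' @examples
#' edge_exclusion_deviance(0.3, 50)  # about 4.72
#' @export
edge_exclusion_deviance <- function(partial_r, n) {
  stopifnot(n >= 1)
  if (any(abs(partial_r) >= 1)) {
    stop("|partial_r| must be < 1", call. = FALSE)
  }
  -n * log(1 - partial_r^2)
}

#' Conditional-independence graph of one group
#'
#' Estimates the group's Pearson correlation matrix (from data that should be
#' population-adjusted but not allometry-adjusted), converts it to full
#' partial correlations, scores each pair with the edge-exclusion deviance,
#' and keeps the edges whose deviance reaches the chi-square critical value
#' at `alpha` (1 d.f.). Edges whose absolute partial correlation lies in the
#' top `1 - strong_quantile` fraction of the significant edges are flagged
#' strong.
#'
#' @param table One group's trait table.
#' @param traits Trait columns.
#' @param alpha Significance level of the edge test.
#' @param strong_quantile Quantile of |partial r| among significant edges
#'   above which an edge is marked strong.
#' @param group Optional group label stored on the result.
#' @return A `ci_graph` object: list with `nodes` (trait, module), `edges`
#'   (from, to, partial_r, eed, strong), `n`, `alpha`, `critical_value`.
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' g <- build_ci_graph(dplyr::filter(adjust_populations(tab),
#'                                   sex == "female", age == "adult",
#'                                   habitat == "closed"))
#' graph_metrics(g)$summary
#' @export
build_ci_graph <- function(table, traits = trait_names(), alpha = 0.05,
                           strong_quantile = 0.90, group = NULL) {
  R <- correlation_matrix(table, traits)
  n <- attr(R, "n")
  if (n <= nrow(R) + 2) {
    warning("sample size barely exceeds trait count; partial correlations ",
            "will be unstable", call. = FALSE)
  }
  P <- partial_correlation_matrix(R)
  crit <- stats::qchisq(1 - alpha, df = 1)
  idx <- which(lower.tri(P), arr.ind = TRUE)
  labs <- rownames(P)
  pr <- P[idx]
  eed <- edge_exclusion_deviance(pr, n)
  keep <- eed >= crit
  edges <- tibble::tibble(
    from = labs[idx[keep, 2]],
    to = labs[idx[keep, 1]],
    partial_r = pr[keep],
    eed = eed[keep]
  )
  edges$strong <- if (nrow(edges) > 0) {
    abs(edges$partial_r) >=
      stats::quantile(abs(edges$partial_r), strong_quantile)
  } else {
    logical(0)
  }
  mods <- trait_modules()
  nodes <- tibble::tibble(
    trait = labs,
    module = if (identical(labs, trait_names())) unname(mods[labs])
             else NA_character_
  )
  structure(
    list(nodes = nodes, edges = edges, n = n, alpha = alpha,
         critical_value = crit, group = group,
         partial_correlations = P),
    class = "ci_graph"
  )
}

#' @export
print.ci_graph <- function(x, ...) {
  cat(sprintf("<ci_graph>%s %d traits, %d significant edges (alpha = %g, N = %d)\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$nodes), nrow(x$edges), x$alpha, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ci_graph <- function(x, ...) x$edges

#' Connectivity and strength metrics of a conditional-independence graph
#'
#' Per-trait connectivity is the number of significant edges incident to the
#' trait, and per-trait strength the mean absolute partial correlation of
#' those edges. Summary metrics: average connectivity (`2 * edges / traits`),
#' average edge strength, and the fraction of potential edges present.
#'
#' @param graph A [build_ci_graph()] result.
#' @return A `graph_metrics` list with tibbles `per_trait` (trait, module,
#'   connectivity, strength) and `summary` (average_connectivity,
#'   average_strength, n_edges, fraction_present).
#' @export
graph_metrics <- function(graph) {
  stopifnot(inherits(graph, "ci_graph"))
  labs <- graph$nodes$trait
  deg <- stats::setNames(numeric(length(labs)), labs)
  str_sum <- deg
  for (j in seq_len(nrow(graph$edges))) {
    e <- graph$edges[j, ]
    for (v in c(e$from, e$to)) {
      deg[v] <- deg[v] + 1
      str_sum[v] <- str_sum[v] + abs(e$partial_r)
    }
  }
  per_trait <- tibble::tibble(
    trait = labs, module = graph$nodes$module,
    connectivity = unname(deg),
    strength = unname(ifelse(deg > 0, str_sum / deg, 0))
  )
  k <- length(labs)
  n_edges <- nrow(graph$edges)
  summary <- tibble::tibble(
    average_connectivity = 2 * n_edges / k,
    average_strength = if (n_edges > 0) mean(abs(graph$edges$partial_r)) else 0,
    n_edges = n_edges,
    fraction_present = n_edges / (k * (k - 1) / 2)
  )
  structure(list(per_trait = per_trait, summary = summary),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
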