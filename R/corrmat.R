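#' Per-group Pearson correlation or covariance matrix
#'
#' `correlation_matrix()` and `covariance_matrix()` compute the 14x14 (or
#' `length(traits)`-square) Pearson association matrix of one group's trait
#' values. `group_matrices()` maps them over every sex/age/habitat group and
#' returns a tibble with a matrix list-column — the shape all downstream
#' group-wise analyses consume.
#'
#' @param table A trait table (typically allometrically adjusted).
#' @param traits Trait columns.
#' @param by Grouping metadata columns (for `group_matrices()`).
#' @param type `"correlation"` or `"covariance"`.
#' @return A symmetric matrix with attribute `n` (sample size); for
#'   `group_matrices()`, a tibble with the grouping columns, `n`, `label` and
#'   list-column `matrix`.
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' gm <- group_matrices(tab)
#' gm$label
#' @export
correlation_matrix <- function(table, traits = trait_names()) {
  x <- as.matrix(table[intersect(traits, names(table))])
  if (nrow(x) < 3) stop("need at least 3 individuals", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  R <- stats::cor(x)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  attr(R, "n") <- nrow(x)
  R
}

#' @rdname correlation_matrix
#' @export
covariance_matrix <- function(table, traits = trait_names()) {
  x <- as.matrix(table[intersect(traits, names(table))])
  if (nrow(x) < 4) stop("need at least 4 individuals", call. = FALSE)
  S <- stats::cov(x)
  S <- (S + t(S)) / 2
  attr(S, "n") <- nrow(x)
  S
}

#' @rdname correlation_matrix
#' @export
group_matrices <- function(table, by = c("sex", "age", "habitat"),
                           traits = trait_names(),
                           type = c("correlation", "covariance")) {
  type <- match.arg(type)
  fn <- if (type == "correlation") correlation_matrix else covariance_matrix
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(n = nrow(d), matrix = list(fn(d, traits)))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = group_label(dplyr::pick(dplyr::all_of(by)))) |>
    dplyr::relocate("label")
}

# compact group label like "FAclosed" from sex/age/habitat metadata
group_label <- function(key) {
  if (all(c("sex", "age", "habitat") %in% names(key))) {
    paste0(toupper(substr(key$sex, 1, 1)), toupper(substr(key$age, 1, 1)),
           key$habitat)
  } else {
    do.call(paste, c(as.list(key), sep = "_"))
  }
}

# lower-triangle off-diagonal elements, column-major
lower_vec <- function(m) m[lower.tri(m)]

#' Matrix correlation between two trait association matrices
#'
#' The Pearson correlation over the off-diagonal lower-triangle elements of
#' the two matrices (91 elements for 14 traits). Diagonals never enter, so
#' correlation, covariance and binary connectivity matrices are all
#' comparable on the same footing.
#'
#' @param A,B Square symmetric matrices of identical dimension (and label
#'   order, if named).
#' @return A scalar in \[-1, 1\].
#' @examples
#' h <- builtin_hypotheses()$trunk_forelimbs_hindlimbs
#' R <- build_modular_correlation(h, 0.5, 0.1)
#' matrix_correlation(R, connectivity_matrix(h))
#' @export
matrix_correlation <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)),
            nrow(A) >= 3)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("matrices have mismatched labels", call. = FALSE)
  }
  a <- lower_vec(A)
  b <- lower_vec(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("matrix correlation undefined: zero variance among off-diagonal ",
         "elements", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Mantel permutation test of matrix association
#'
#' Tests whether two trait association matrices are more similar than
#' expected by chance by permuting the trait labels of `B` (rows and columns
#' jointly) and recomputing the matrix correlation each time. The one-tailed
#' p-value is `(number of permuted r >= observed r + 1) / (n_permutations +
#' 1)`, so the observed matrix is significantly similar at 0.05 when it
#' exceeds 95% of the permutation distribution.
#'
#' @inheritParams matrix_correlation
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Optional integer seed for the permutation stream.
#' @return A `mantel_test` object: list with `r_observed`, `p`,
#'   `n_permutations`, `seed`, `r_permuted`.
#' @examples
#' h <- builtin_hypotheses()$trunk_forelimbs_hindlimbs
#' R <- build_modular_correlation(h, 0.5, 0.1)
#' mantel_test(R, connectivity_matrix(h), n_permutations = 199, seed = 1)
#' @export
mantel_test <- function(A, B, n_permutations = 999, seed = NULL) {
  stopifnot(n_permutations >= 100)
  r_obs <- matrix_correlation(A, B)
  k <- nrow(B)
  a <- lower_vec(A)
  sa <- stats::sd(a)
  am <- mean(a)
  r_perm <- with_seed_opt(seed, {
    vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(k)
      bp <- lower_vec(B[p, p, drop = FALSE])
      # inline Pearson on the 91-vectors, B's off-diagonal variance is
      # permutation-invariant
      sum((a - am) * (bp - mean(bp))) / ((k * (k - 1) / 2 - 1) * sa * stats::sd(bp))
    }, numeric(1))
  })
  structure(
    list(r_observed = r_obs,
         p = (sum(r_perm >= r_obs) + 1) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations),
         seed = seed, r_permuted = r_perm),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r_observed, x$p, x$n_permutations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(r = x$r_observed, p = x$p, n_permutations = x$n_permutations)
}

#' Bootstrap repeatability of a group's correlation matrix
#'
#' Resamples the group's rows with replacement, re-estimates the correlation
#' matrix, and returns the mean matrix correlation between each bootstrap
#' matrix and the observed matrix — a Monte-Carlo gauge of how much sampling
#' error the matrix estimate carries (1 = perfectly repeatable). Bootstrap
#' draws that produce a constant trait are redrawn.
#'
#' @param table One group's trait table.
#' @param traits Trait columns.
#' @param n_iterations Bootstrap replicates.
#' @param seed Optional integer seed.
#' @return A scalar repeatability `t`, with the bootstrap correlations in
#'   attribute `bootstrap`.
#' @export
repeatability <- function(table, traits = trait_names(),
                          n_iterations = 1000, seed = NULL) {
  R <- correlation_matrix(table, traits)
  x <- table[intersect(traits, names(table))]
  n <- nrow(x)
  rs <- with_seed_opt(seed, {
    vapply(seq_len(n_iterations), function(i) {
      repeat {
        xb <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
        Rb <- tryCatch(correlation_matrix(xb, traits), error = function(e) NULL)
        if (!is.null(Rb)) return(matrix_correlation(R, Rb))
      }
    }, numeric(1))
  })
  structure(mean(rs), bootstrap = rs)
}

#' All pairwise matrix comparisons among groups
#'
#' Computes the matrix correlation and Mantel p-value for every unordered
#' pair of group matrices (28 pairs for 8 groups), and optionally each
#' group's bootstrap repeatability — the ingredients of the classic
#' "correlations below the diagonal, repeatability on it, p-values above"
#' summary.
#'
#' @param matrices A named list of matrices, or a [group_matrices()] tibble.
#' @param n_permutations,seed Passed to [mantel_test()].
#' @return A tibble with columns `group1`, `group2`, `r`, `p`.
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' gm <- group_matrices(adjust_allometry(adjust_populations(tab)))
#' pw <- pairwise_group_comparison(gm, n_permutations = 199, seed = 1)
#' nrow(pw)  # 28
#' @export
pairwise_group_comparison <- function(matrices, n_permutations = 999,
                                      seed = NULL) {
  if (is.data.frame(matrices)) {
    matrices <- stats::setNames(matrices$matrix, matrices$label)
  }
  stopifnot(is.list(matrices), length(matrices) >= 2)
  labs <- names(matrices)
  lab_sets <- lapply(matrices, rownames)
  if (length(unique(lab_sets)) != 1) {
    stop("matrices have mismatched labels", call. = FALSE)
  }
  pairs <- utils::combn(length(matrices), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    mt <- mantel_test(matrices[[i1]], matrices[[i2]],
                      n_permutations = n_permutations,
                      seed = if (is.null(seed)) NULL else child_seed(seed, j))
    tibble::tibble(group1 = labs[i1], group2 = labs[i2],
                   r = mt$r_observed, p = mt$p)
  })
}

#' Combined group-comparison matrix
#'
#' Arranges pairwise matrix correlations below the diagonal, per-group
#' repeatability on the diagonal and Mantel p-values above it, in one square
#' matrix — the standard compact report of among-group matrix similarity.
#'
#' @param pairwise Tibble from [pairwise_group_comparison()].
#' @param repeatabilities Named numeric vector of per-group repeatability
#'   (`NA` diagonal if omitted).
#' @return A square numeric matrix with group labels.
#' @export
comparison_matrix <- function(pairwise, repeatabilities = NULL) {
  labs <- unique(c(pairwise$group1, pairwise$group2))
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (j in seq_len(nrow(pairwise))) {
    i1 <- match(pairwise$group1[j], labs)
    i2 <- match(pairwise$group2[j], labs)
    m[max(i1, i2), min(i1, i2)] <- pairwise$r[j]
    m[min(i1, i2), max(i1, i2)] <- pairwise$p[j]
  }
  if (!is.null(repeatabilities)) diag(m) <- repeatabilities[labs]
  m
}
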