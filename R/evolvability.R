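#' Random selection skewers
#'
#' Draws `k` isotropic unit-length selection vectors (standard-normal draws
#' normalised to Euclidean norm 1) used to probe a phenotypic covariance
#' matrix. One shared skewer set across groups makes between-group
#' differences independent of skewer-sampling noise.
#'
#' @param k Number of vectors.
#' @param n_traits Dimension.
#' @param seed Optional integer seed.
#' @return A `k` x `n_traits` matrix of unit row vectors.
#' @examples
#' sk <- random_skewers(5, 14, seed = 1)
#' rowSums(sk^2)
#' @export
random_skewers <- function(k = 1000, n_traits = 14, seed = NULL) {
  stopifnot(k >= 1, n_traits >= 1)
  with_seed_opt(seed, {
    m <- matrix(stats::rnorm(k * n_traits), k, n_traits)
    m / sqrt(rowSums(m^2))
  })
}

#' Selection response under the multivariate breeder's equation
#'
#' The response to a selection gradient `beta` is `delta_z = P %*% beta`,
#' with the phenotypic covariance matrix `P` standing in for the genetic
#' covariance matrix.
#'
#' @param P Covariance matrix.
#' @param beta Selection vector (length `nrow(P)`).
#' @return The response vector.
#' @export
selection_response <- function(P, beta) {
  stopifnot(is.matrix(P), length(beta) == nrow(P))
  drop(P %*% beta)
}

#' Random-skewers evolvability (flexibility) index
#'
#' The mean cosine of the angle between each selection vector and its
#' response `P beta` over a skewer set: 1 when responses always align with
#' selection (isotropic P), approaching 0 as integration channels responses
#' away from the selection direction. Scale-invariant in `P`.
#'
#' @param P Positive-definite covariance matrix.
#' @param skewers Matrix of unit selection vectors from [random_skewers()].
#' @return Mean cosine in (0, 1\].
#' @examples
#' sk <- random_skewers(200, 4, seed = 1)
#' evolvability_index(diag(4), sk)  # exactly 1
#' @export
evolvability_index <- function(P, skewers) {
  check_pd(P)
  resp <- skewers %*% P
  num <- rowSums(skewers * resp)
  den <- sqrt(rowSums(resp^2))
  mean(num / den)
}

#' Conditional evolvability index
#'
#' The mean over skewers of `1 / (beta' P^{-1} beta)` for unit `beta`: the
#' variance available along the selection direction when all orthogonal
#' directions are held fixed by stabilising selection. Never exceeds the
#' directional evolvability `beta' P beta`. Scales linearly with `P`.
#'
#' @inheritParams evolvability_index
#' @return Positive scalar (units of `P`).
#' @export
conditional_evolvability_index <- function(P, skewers) {
  check_pd(P)
  Pi <- solve(P)
  mean(1 / rowSums((skewers %*% Pi) * skewers))
}

#' Constraints index (alignment of responses with PC1)
#'
#' The mean absolute cosine of the angle between each response vector
#' `P beta` and the leading eigenvector of `P` — the relative influence of
#' the major axis of phenotypic variance on the response to selection.
#' Invariant to the sign of the eigenvector and to the scale of `P`.
#'
#' @inheritParams evolvability_index
#' @return Value in \[0, 1\].
#' @export
constraints_index <- function(P, skewers) {
  check_pd(P)
  eig <- eigen(P, symmetric = TRUE)
  if (nrow(P) > 1 && (eig$values[1] - eig$values[2]) / eig$values[1] < 1e-8) {
    warning("leading eigenvalue is nearly tied; PC1 direction is unstable",
            call. = FALSE)
  }
  v1 <- eig$vectors[, 1]
  resp <- skewers %*% P
  mean(abs(drop(resp %*% v1)) / sqrt(rowSums(resp^2)))
}

check_pd <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev))) {
    stop("covariance matrix is singular or not positive definite",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' All three evolvability indices of one covariance matrix
#'
#' @inheritParams evolvability_index
#' @return A one-row tibble: `evolvability`, `conditional_evolvability`,
#'   `constraints`.
#' @export
evolvability_indices <- function(P, skewers) {
  tibble::tibble(
    evolvability = evolvability_index(P, skewers),
    conditional_evolvability = conditional_evolvability_index(P, skewers),
    constraints = constraints_index(P, skewers)
  )
}

#' Bootstrap comparison of an evolvability index between two groups
#'
#' Applies the same paired-bootstrap resampling logic as [compare_ve()] to
#' the chosen random-skewers index, recomputing each group's covariance
#' matrix per bootstrap draw against one shared skewer set.
#'
#' @inheritParams compare_ve
#' @param index Which index to compare.
#' @param k Number of skewers per evaluation.
#' @return A tibble with the two observed index values, `p`, `n_iterations`.
#' @export
compare_evolvability <- function(table_a, table_b, traits = trait_names(),
                                 index = c("evolvability",
                                           "conditional_evolvability",
                                           "constraints"),
                                 k = 1000, n_iterations = 1000, seed = NULL,
                                 pairing = c("paired", "all")) {
  index <- match.arg(index)
  skewers <- random_skewers(k, length(traits),
                            seed = if (is.null(seed)) NULL
                                   else child_seed(seed, 99))
  fn <- switch(index,
    evolvability = evolvability_index,
    conditional_evolvability = conditional_evolvability_index,
    constraints = constraints_index
  )
  compare_bootstrap_index(
    table_a, table_b, traits, n_iterations, seed, match.arg(pairing),
    function(x) fn(stats::cov(as.matrix(x)), skewers),
    paste0(index, c("_a", "_b"))
  )
}
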