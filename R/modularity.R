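#' Mantel tests of a priori modularity hypotheses
#'
#' Compares one group's correlation matrix to the binary connectivity matrix
#' of each modularity hypothesis with a Mantel permutation test. A hypothesis
#' is "visible" in the group when the observed matrix correlation exceeds
#' 95% of the permutation distribution (one-tailed p <= 0.05).
#'
#' @param R A group correlation matrix.
#' @param hypotheses A named list of [module_hypothesis()] objects (default:
#'   the eleven built-ins).
#' @param n_permutations,seed Passed to [mantel_test()].
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with one row per hypothesis: `hypothesis`, `r`, `p`,
#'   `significant`.
#' @examples
#' R <- build_modular_correlation(builtin_hypotheses()$trunk, 0.6, 0.1)
#' test_hypotheses(R, n_permutations = 199, seed = 1)
#' @export
test_hypotheses <- function(R, hypotheses = builtin_hypotheses(),
                            n_permutations = 999, seed = NULL, alpha = 0.05) {
  purrr::imap_dfr(hypotheses, function(h, nm) {
    B <- connectivity_matrix(h, nrow(R), labels = rownames(R))
    mt <- mantel_test(R, B, n_permutations = n_permutations,
                      seed = if (is.null(seed)) NULL
                             else child_seed(seed, match(nm, names(hypotheses))))
    tibble::tibble(hypothesis = nm, r = mt$r_observed, p = mt$p,
                   significant = mt$p <= alpha)
  })
}

# class id per lower-triangle pair: 0 = between/background, i = within set i
pair_classes <- function(hypothesis, n_traits) {
  mem <- hypothesis_membership(hypothesis)
  idx <- which(lower.tri(diag(n_traits)), arr.ind = TRUE)
  cls <- integer(nrow(idx))
  same <- !is.na(mem[idx[, 1]]) & !is.na(mem[idx[, 2]]) &
    mem[idx[, 1]] == mem[idx[, 2]]
  cls[same] <- mem[idx[, 1]][same]
  cls
}

#' Likelihood comparison of modularity hypotheses (EMMLi-style)
#'
#' Fits each modularity hypothesis as a model for the 91 off-diagonal
#' correlations: pairs within each module share one correlation parameter,
#' and all remaining pairs (between modules or involving background traits)
#' share one pooled parameter. Each observed correlation is modelled through
#' Fisher's z-transform as normal with mean `z(rho_class)` and variance
#' `1/(n - 3)`, so the maximum-likelihood estimate per class is
#' `tanh(mean(z(r)))` and the maximised log-likelihood has closed form.
#' Models are compared by AICc (sample size = number of correlation
#' coefficients) and Akaike-weight posterior probabilities.
#'
#' @param R A group correlation matrix.
#' @param n Sample size behind `R` (taken from `attr(R, "n")` if missing).
#' @param hypotheses Named list of hypotheses to compare.
#' @param include_null Add a null model with a single pooled correlation.
#' @return An `emmli_fit` object: a tibble with one row per model (`model`,
#'   `k`, `lnL`, `AICc`, `delta_AICc`, `posterior`), ordered by AICc, with
#'   the per-class estimates in the `rho` list-column.
#' @examples
#' h <- builtin_hypotheses()
#' R <- build_modular_correlation(h$trunk_forelimbs_hindlimbs, 0.5, 0.1)
#' fit <- emmli_fit(R, n = 150)
#' fit$model[1]
#' @export
emmli_fit <- function(R, n = attr(R, "n"), hypotheses = builtin_hypotheses(),
                      include_null = TRUE) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (is.null(n)) stop("sample size n is required", call. = FALSE)
  if (n <= 3) stop("need n > 3 for the Fisher-z variance 1/(n - 3)",
                   call. = FALSE)
  p <- nrow(R)
  m <- p * (p - 1) / 2
  r <- lower_vec(R)
  if (any(abs(r) >= 1)) {
    warning("correlation(s) with |r| = 1 clipped to 0.9999 for the Fisher ",
            "transform", call. = FALSE)
    r <- pmin(pmax(r, -0.9999), 0.9999)
  }
  z <- atanh(r)
  sdz <- sqrt(1 / (n - 3))
  fit_classes <- function(cls) {
    zbar <- tapply(z, cls, mean)
    mu <- zbar[as.character(cls)]
    list(
      lnL = sum(stats::dnorm(z, mu, sdz, log = TRUE)),
      k = length(zbar),
      rho = stats::setNames(as.numeric(tanh(zbar)), names(zbar))
    )
  }
  models <- purrr::imap(hypotheses, function(h, nm) {
    cls <- pair_classes(h, p)
    f <- fit_classes(cls)
    names(f$rho) <- vapply(as.integer(names(f$rho)), function(i) {
      if (i == 0) "between"
      else paste0("within_", paste(h$sets[[i]], collapse = "."))
    }, character(1))
    f
  })
  if (include_null) {
    f0 <- fit_classes(rep(0L, m))
    names(f0$rho) <- "pooled"
    models <- c(models, list(null = f0))
  }
  k <- vapply(models, `[[`, numeric(1), "k")
  if (any(m - k - 1 <= 0)) {
    stop("AICc undefined: m - k - 1 <= 0 for some model", call. = FALSE)
  }
  lnL <- vapply(models, `[[`, numeric(1), "lnL")
  aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / (m - k - 1)
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  out <- tibble::tibble(
    model = names(models), k = as.integer(unname(k)), lnL = unname(lnL),
    AICc = unname(aicc), delta_AICc = unname(d),
    posterior = unname(w / sum(w)),
    rho = purrr::map(models, "rho")
  ) |>
    dplyr::arrange(.data$AICc)
  class(out) <- c("emmli_fit", class(out))
  attr(out, "n") <- n
  attr(out, "m") <- m
  out
}

#' @exportS3Method generics::tidy
tidy.emmli_fit <- function(x, ...) {
  tibble::as_tibble(x[c("model", "k", "lnL", "AICc", "delta_AICc", "posterior")])
}

#' @exportS3Method generics::glance
glance.emmli_fit <- function(x, ...) {
  tibble::tibble(
    best_model = x$model[1], best_posterior = x$posterior[1],
    n_models = nrow(x), n = attr(x, "n"), m = attr(x, "m")
  )
}

#' Likelihood-ratio comparison of two hypotheses
#'
#' Twice the absolute difference of two maximised log-likelihoods, gated at
#' the chi-square critical value with 1 degree of freedom at `alpha` (3.841
#' for alpha = 0.05): one hypothesis is significantly better than the other
#' when the statistic exceeds that threshold.
#'
#' @param lnL1,lnL2 Maximised log-likelihoods.
#' @param alpha Significance level.
#' @return A tibble with `statistic`, `critical_value`, `significant`.
#' @examples
#' likelihood_ratio_test(10, 8)   # 4 > 3.841: significant
#' likelihood_ratio_test(10, 8.1) # 3.8: not
#' @export
likelihood_ratio_test <- function(lnL1, lnL2, alpha = 0.05) {
  crit <- stats::qchisq(1 - alpha, df = 1)
  stat <- 2 * abs(lnL1 - lnL2)
  tibble::tibble(statistic = stat, critical_value = crit,
                 significant = stat > crit)
}
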