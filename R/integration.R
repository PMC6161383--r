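#' Eigenvalue-variance index of integration
#'
#' Overall integration of a correlation matrix measured as the variance of
#' its eigenvalues around their known mean of 1, `VE = mean((lambda - 1)^2)`,
#' standardised by the maximum possible value `N - 1` (attained when all
#' correlations are 1): `VE_SD = VE / (N - 1)`, an index in \[0, 1\]. For an
#' equicorrelated matrix with correlation rho, `VE_SD = rho^2` exactly.
#'
#' @param R A correlation matrix.
#' @return A `ve_index` list: `VE`, `VE_SD`, `eigenvalues`, `n_traits`.
#' @examples
#' ve_index(diag(14))$VE_SD                       # 0
#' R <- build_modular_correlation(builtin_hypotheses()$trunk, 0.5, 0.5)
#' ve_index(R)$VE_SD                              # 0.25
#' @export
ve_index <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  N <- nrow(R)
  VE <- mean((lambda - 1)^2)
  structure(
    list(VE = VE, VE_SD = VE / (N - 1), eigenvalues = lambda, n_traits = N),
    class = "ve_index"
  )
}

#' @export
print.ve_index <- function(x, ...) {
  cat(sprintf("VE = %.4f, VE_SD = %.4f (%d traits)\n", x$VE, x$VE_SD,
              x$n_traits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ve_index <- function(x, ...) {
  tibble::tibble(VE = x$VE, VE_SD = x$VE_SD, n_traits = x$n_traits)
}

# bootstrap VE_SD distribution for one group's trait table
bootstrap_ve <- function(x, n_iterations, seed = NULL) {
  n <- nrow(x)
  with_seed_opt(seed, {
    vapply(seq_len(n_iterations), function(i) {
      repeat {
        xb <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
        R <- tryCatch(correlation_matrix(xb), error = function(e) NULL)
        if (!is.null(R)) return(ve_index(R)$VE_SD)
      }
    }, numeric(1))
  })
}

#' Bootstrap comparison of integration between two groups
#'
#' Bootstraps each group's rows with replacement, recomputes the
#' standardized eigenvalue variance per iteration, and compares the group
#' with the smaller point estimate to the one with the larger: the p-value
#' is the fraction of (paired) iterations in which the smaller group's
#' bootstrap value reaches or exceeds the larger group's.
#'
#' @param table_a,table_b Trait tables of the two groups.
#' @param traits Trait columns.
#' @param n_iterations Bootstrap iterations.
#' @param seed Optional integer seed.
#' @param pairing `"paired"` compares iteration i with iteration i;
#'   `"all"` compares every bootstrap value of one group with every value of
#'   the other.
#' @return A tibble with `VE_SD_a`, `VE_SD_b`, `p`, `n_iterations`.
#' @examples
#' cfg <- sim_config(group_specs = default_group_specs()[c(2, 4), ], seed = 3)
#' tab <- simulate_traits(cfg)
#' parts <- split(tab, tab$habitat)
#' compare_ve(parts$open, parts$closed, n_iterations = 100, seed = 1)
#' @export
compare_ve <- function(table_a, table_b, traits = trait_names(),
                       n_iterations = 1000, seed = NULL,
                       pairing = c("paired", "all")) {
  compare_bootstrap_index(
    table_a, table_b, traits, n_iterations, seed, match.arg(pairing),
    function(x) ve_index(correlation_matrix(x))$VE_SD,
    c("VE_SD_a", "VE_SD_b")
  )
}

# shared bootstrap-comparison engine for VE and the evolvability indices
compare_bootstrap_index <- function(table_a, table_b, traits, n_iterations,
                                    seed, pairing, stat, names_ab) {
  xa <- table_a[intersect(traits, names(table_a))]
  xb <- table_b[intersect(traits, names(table_b))]
  stopifnot(nrow(xa) >= 4, nrow(xb) >= 4)
  obs_a <- stat(xa)
  obs_b <- stat(xb)
  boot_one <- function(x, s) {
    n <- nrow(x)
    with_seed_opt(s, {
      vapply(seq_len(n_iterations), function(i) {
        repeat {
          xi <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
          v <- tryCatch(stat(xi), error = function(e) NULL)
          if (!is.null(v) && is.finite(v)) return(v)
        }
      }, numeric(1))
    })
  }
  ba <- boot_one(xa, if (is.null(seed)) NULL else child_seed(seed, 1))
  bb <- boot_one(xb, if (is.null(seed)) NULL else child_seed(seed, 2))
  if (obs_a <= obs_b) { smaller <- ba; larger <- bb } else { smaller <- bb; larger <- ba }
  p <- if (pairing == "paired") {
    mean(smaller >= larger)
  } else {
    mean(outer(smaller, larger, `>=`))
  }
  out <- tibble::tibble(a = obs_a, b = obs_b, p = p,
                        n_iterations = as.integer(n_iterations))
  names(out)[1:2] <- names_ab
  out
}
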