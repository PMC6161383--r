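# Shared fixtures and independent oracles used across test files.

# single-group sim config: one adult/female/open group of n individuals
one_group_config <- function(n, rho_within = 0.4, rho_between = 0.1,
                             slopes = rep(0, 14), residual_sd = 0.05,
                             sd_log_size = 0.12,
                             partition = builtin_hypotheses()$trunk_forelimbs_hindlimbs,
                             seed = 1) {
  gs <- tibble::tibble(sex = "female", age = "adult", habitat = "open",
                       n = as.integer(n), mean_log_size = 0,
                       sd_log_size = sd_log_size)
  pops <- tibble::tibble(name = "open_A", habitat = "open",
                         offset = list(rep(0, 14)))
  sim_config(group_specs = gs, populations = pops,
             allometry_slopes = stats::setNames(slopes, trait_names()),
             partition = partition, rho_within = rho_within,
             rho_between = rho_between, residual_sd = residual_sd,
             seed = seed)
}

# random correlation matrix from n rows of iid normal data
random_corr <- function(p = 14, n = 30) {
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}

# independent oracle: partial correlation by recursive elimination of the
# conditioning set, one variable at a time
partial_cor_recursive <- function(R, i, j, cond) {
  if (length(cond) == 0) return(R[i, j])
  k <- cond[1]
  rest <- cond[-1]
  rij <- partial_cor_recursive(R, i, j, rest)
  rik <- partial_cor_recursive(R, i, k, rest)
  rjk <- partial_cor_recursive(R, j, k, rest)
  (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
}

# full partial-correlation matrix via the recursive oracle
partial_matrix_oracle <- function(R) {
  p <- nrow(R)
  P <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      P[i, j] <- P[j, i] <- partial_cor_recursive(R, i, j, setdiff(1:p, c(i, j)))
    }
  }
  P
}

# tiny trait table with arbitrary metadata for toy tests (k traits named
# after the canonical list)
toy_table <- function(values, population = "open_A", sex = "female",
                      age = "adult", habitat = "open") {
  values <- as.data.frame(values)
  names(values) <- trait_names()[seq_len(ncol(values))]
  dplyr::bind_cols(
    tibble::tibble(
      id = paste0("t", seq_len(nrow(values))),
      population = rep_len(population, nrow(values)),
      habitat = habitat, sex = sex, age = age
    ),
    values
  )
}
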