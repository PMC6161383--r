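#' Block-modular correlation matrix
#'
#' Realises a modularity hypothesis as a correlation matrix: unit diagonal,
#' `rho_within` for pairs of traits in the same module, `rho_between` for
#' pairs in different modules and for pairs involving traits outside every
#' module (unpartitioned traits behave as singleton modules).
#'
#' @param partition A [module_hypothesis()].
#' @param rho_within,rho_between Correlations in (-1, 1); the result must be
#'   positive semi-definite or an error is raised.
#' @param n_traits Matrix dimension.
#' @return A symmetric `n_traits` x `n_traits` correlation matrix.
#' @examples
#' h <- builtin_hypotheses()$trunk_forelimbs_hindlimbs
#' R <- build_modular_correlation(h, 0.5, 0.1)
#' range(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
#' @export
build_modular_correlation <- function(partition, rho_within, rho_between,
                                      n_traits = partition$n_traits) {
  stopifnot(inherits(partition, "module_hypothesis"),
            rho_within > -1, rho_within < 1,
            rho_between > -1, rho_between < 1)
  B <- connectivity_matrix(partition, n_traits)
  R <- matrix(rho_between, n_traits, n_traits)
  R[B == 1] <- rho_within
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("correlation parameters give a non-positive-semi-definite matrix ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  }
  if (n_traits == 14L) dimnames(R) <- list(trait_names(), trait_names())
  R
}

#' Default group design of the simulator
#'
#' Eight sex/age/habitat groups of 70 individuals each. Adults are larger
#' than subadults and males slightly larger than females on the log-size
#' scale; residual integration (`rho_within`) is higher in subadults than
#' adults, in closed than open habitats, and marginally higher in females —
#' the qualitative gradients the analysis is designed to detect. `NA` in
#' `rho_within` means "use the config-level value".
#'
#' @return A tibble with columns `sex`, `age`, `habitat`, `n`,
#'   `mean_log_size`, `sd_log_size`, `rho_within`.
#' @export
default_group_specs <- function() {
  g <- tidyr::expand_grid(
    sex = c("female", "male"),
    age = c("subadult", "adult"),
    habitat = c("open", "closed")
  )
  g$n <- 70L
  g$mean_log_size <- ifelse(g$age == "adult", 0.06, -0.08) +
    ifelse(g$sex == "male", 0.02, 0)
  g$sd_log_size <- 0.12
  g$rho_within <- 0.30 +
    ifelse(g$age == "subadult", 0.08, 0) +
    ifelse(g$habitat == "closed", 0.10, 0) +
    ifelse(g$sex == "female", 0.02, 0)
  g
}

#' Default populations (two localities per habitat)
#'
#' Each population carries a small per-trait mean offset on the log scale,
#' emulating locality-level structuring that the preprocessing stage must
#' remove. Offsets are fixed, non-empirical values.
#'
#' @return A tibble with columns `name`, `habitat` and a list-column `offset`
#'   of length-14 numeric vectors.
#' @export
default_populations <- function() {
  tibble::tibble(
    name = c("open_A", "open_B", "closed_A", "closed_B"),
    habitat = c("open", "open", "closed", "closed"),
    offset = list(
      rep(0, 14),
      rep(0.035, 14),
      rep(0, 14),
      seq(0.02, 0.045, length.out = 14)
    )
  )
}

# plausible adult roe-deer-scale baselines (cm at log-size 0); non-empirical
default_trait_baselines <- function() {
  stats::setNames(
    c(30, 25, 12, 92, 24, 30, 62, 35, 4.5, 3.0, 72, 40, 4.6, 3.1),
    trait_names()
  )
}

# per-trait allometric exponents, mean 1 so slopes are recovered directly
default_allometry_slopes <- function() {
  stats::setNames(
    c(0.85, 0.95, 1.20, 1.05, 1.15, 1.10, 1.00, 0.95, 0.90, 0.85,
      1.05, 1.00, 0.95, 1.00),
    trait_names()
  )
}

#' Simulation configuration
#'
#' Bundles the generating model of the synthetic trait tables: per-group
#' sample sizes and log-size distributions, population offsets, per-trait
#' allometric slopes and baselines, the generating modular partition and its
#' within/between residual correlations, the residual scale and the root
#' seed. Traits are generated on the log scale,
#' `log y_t = log(baseline_t) + b_t * s + offset_t + e`, with `s` the shared
#' normal log-size factor and `e` multivariate normal with block-modular
#' correlation, then exponentiated — so the power-law allometric model used
#' by the preprocessing stage is exactly correct for generated data.
#'
#' @param group_specs Tibble as [default_group_specs()]; a `rho_within`
#'   column may override the global value per group (`NA` = global).
#' @param populations Tibble as [default_populations()].
#' @param allometry_slopes,trait_baselines Named length-14 numeric vectors.
#' @param partition Generating [module_hypothesis()].
#' @param rho_within,rho_between Residual correlations within/between modules.
#' @param residual_sd Residual standard deviation on the log scale; scalar or
#'   length-14 vector.
#' @param seed Integer root seed; per-group child streams are derived from it
#'   deterministically so any group can be regenerated independently.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' tab <- simulate_traits(cfg)
#' dplyr::count(tab, sex, age, habitat)
#' @export
sim_config <- function(group_specs = default_group_specs(),
                       populations = default_populations(),
                       allometry_slopes = default_allometry_slopes(),
                       trait_baselines = default_trait_baselines(),
                       partition = builtin_hypotheses()$trunk_forelimbs_hindlimbs,
                       rho_within = 0.40,
                       rho_between = 0.10,
                       residual_sd = 0.05,
                       seed = 1L) {
  group_specs <- tibble::as_tibble(group_specs)
  if (!"rho_within" %in% names(group_specs)) group_specs$rho_within <- NA_real_
  if (!"sd_log_size" %in% names(group_specs)) group_specs$sd_log_size <- 0.12
  stopifnot(
    all(c("sex", "age", "habitat", "n", "mean_log_size") %in% names(group_specs)),
    all(group_specs$n >= 2),
    rho_between > -1, rho_between <= rho_within, rho_within < 1,
    length(allometry_slopes) == 14, length(trait_baselines) == 14,
    all(trait_baselines > 0),
    length(residual_sd) %in% c(1L, 14L), all(residual_sd >= 0)
  )
  if (!all(group_specs$habitat %in% populations$habitat)) {
    stop("every group habitat needs at least one population", call. = FALSE)
  }
  structure(
    list(group_specs = group_specs, populations = tibble::as_tibble(populations),
         allometry_slopes = allometry_slopes, trait_baselines = trait_baselines,
         partition = partition, rho_within = rho_within,
         rho_between = rho_between,
         residual_sd = rep(residual_sd, length.out = 14),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a trait table
#'
#' Draws a complete individuals-by-traits table under a [sim_config()]:
#' a lognormal shared size factor with trait-specific allometric exponents,
#' additive population offsets on the log scale, and block-modular
#' multivariate-normal residuals. Deterministic given the config (including
#' its seed); each group uses its own child RNG stream.
#'
#' @param config A [sim_config()].
#' @return A validated trait tibble (see [validate_trait_table()]).
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$group_specs
  base_lt <- log(config$trait_baselines)
  b <- config$allometry_slopes
  D <- diag(config$residual_sd)
  rows <- purrr::map(seq_len(nrow(gs)), function(g) {
    spec <- gs[g, ]
    rw <- if (is.na(spec$rho_within)) config$rho_within else spec$rho_within
    R <- build_modular_correlation(config$partition, rw, config$rho_between, 14L)
    Sigma <- D %*% R %*% D
    # symmetric square root: exact for zero residual_sd and PSD-boundary R
    es <- eigen(Sigma, symmetric = TRUE)
    cS <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
    pops <- config$populations[config$populations$habitat == spec$habitat, ]
    n <- spec$n
    withr::with_seed(child_seed(config$seed, g), {
      pop_idx <- sample(rep_len(seq_len(nrow(pops)), n))
      s <- stats::rnorm(n, spec$mean_log_size, spec$sd_log_size)
      eps <- matrix(stats::rnorm(n * 14), n, 14) %*% cS
      off <- do.call(rbind, pops$offset[pop_idx])
      logy <- matrix(base_lt, n, 14, byrow = TRUE) + outer(s, b) + off + eps
    })
    out <- tibble::as_tibble(stats::setNames(as.data.frame(exp(logy)),
                                             trait_names()))
    dplyr::bind_cols(
      tibble::tibble(
        id = sprintf("g%02d_%04d", g, seq_len(n)),
        population = pops$name[pop_idx],
        habitat = spec$habitat, sex = spec$sex, age = spec$age
      ),
      out
    )
  })
  validate_trait_table(dplyr::bind_rows(rows))
}
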