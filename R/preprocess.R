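#' Remove population structuring from trait means
#'
#' Within each analysis group, every population's values for each trait are
#' shifted additively up to the maximum population mean, so that all
#' population means coincide while within-population deviations (and hence
#' within-population covariance matrices) are preserved exactly. With two
#' populations this adds the difference in means to the population with the
#' smaller mean; with more populations every population is raised to the
#' largest mean. Idempotent.
#'
#' @param table A trait table (see [validate_trait_table()]).
#' @param by Grouping metadata columns defining the analysis groups.
#' @param traits Trait columns to adjust.
#' @return The adjusted tibble, flagged with attribute
#'   `population_adjusted = TRUE` (see [adjustment_flags()]).
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' adj <- adjust_populations(tab)
#' @export
adjust_populations <- function(table, by = c("sex", "age", "habitat"),
                               traits = trait_names()) {
  stopifnot(all(c(by, traits, "population") %in% names(table)))
  singletons <- table |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "population")))) |>
    dplyr::filter(.data$n < 2)
  if (nrow(singletons) > 0) {
    warning("population(s) with a single individual within a group; ",
            "adjusted anyway but downstream resampling may be unstable",
            call. = FALSE)
  }
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(traits),
      function(x) {
        pm <- tapply(x, .data$population, mean)
        x + as.vector((max(pm) - pm)[.data$population])
      }
    )) |>
    dplyr::ungroup()
  set_flag(out, "population_adjusted")
}

#' Geometric mean body size of one individual
#'
#' The overall size measure: the geometric mean of the 14 (or any supplied)
#' strictly positive trait values, computed as `exp(mean(log(x)))`.
#'
#' @param x Numeric vector of trait values; names are used in error messages.
#' @return A positive scalar.
#' @examples
#' geometric_mean_size(c(HL = 1, NL = 4))  # 2
#' @export
geometric_mean_size <- function(x) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0) {
    nm <- if (is.null(names(x))) as.character(bad) else names(x)[bad]
    stop("non-positive trait value(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  exp(mean(log(x)))
}

# per-row GM over the trait columns
row_gm <- function(table, traits = trait_names()) {
  exp(rowMeans(log(as.matrix(table[traits]))))
}

#' Fit per-group trait allometry
#'
#' Within each group, regresses each log-transformed trait on the log of the
#' individual geometric-mean size (ordinary least squares), giving the
#' power-law allometric exponent `b` per trait. The group reference size `X0`
#' is the geometric mean of the individual sizes.
#'
#' @inheritParams adjust_populations
#' @return A tibble of class `allometry_models` with one row per group x
#'   trait: grouping columns, `X0`, `trait`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' fits <- fit_allometry(tab)
#' head(fits)
#' @export
fit_allometry <- function(table, by = c("sex", "age", "habitat"),
                          traits = trait_names()) {
  stopifnot(all(c(by, traits) %in% names(table)))
  fits <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("need at least 3 individuals per group", call. = FALSE)
      gm <- row_gm(d, traits)
      lx <- log(gm)
      if (stats::var(lx) <= .Machine$double.eps * 100) {
        stop("zero size variance within a group; allometry undefined",
             call. = FALSE)
      }
      X0 <- exp(mean(lx))
      lxc <- lx - mean(lx)
      purrr::map_dfr(traits, function(tr) {
        ly <- log(d[[tr]])
        b <- sum(lxc * (ly - mean(ly))) / sum(lxc^2)
        a <- mean(ly) - b * mean(lx)
        res <- ly - (a + b * lx)
        tibble::tibble(
          X0 = X0, trait = tr, slope = b, intercept = a,
          r_squared = 1 - sum(res^2) / sum((ly - mean(ly))^2),
          n = nrow(d)
        )
      })
    }) |>
    dplyr::ungroup()
  class(fits) <- c("allometry_models", class(fits))
  fits
}

#' Allometric size correction (power-law normalisation)
#'
#' Applies the power-law correction `Y* = Y * (X0 / X)^b` to every trait of
#' every individual, where `X` is the individual's geometric-mean size, `X0`
#' the group reference size and `b` the fitted allometric exponent — bringing
#' each individual to the group average size. To make groups comparable, the
#' corrected values are then divided by `X0`, scaling all individuals in all
#' groups to a theoretical body size of 1.
#'
#' @inheritParams adjust_populations
#' @param models An `allometry_models` tibble from [fit_allometry()]; fitted
#'   from `table` if `NULL`.
#' @param rescale_to_unit_size Divide corrected traits by the group `X0`
#'   (default `TRUE`).
#' @return The adjusted tibble, flagged `allometry_adjusted` (and
#'   `size_standardized` when rescaled).
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' adj <- adjust_allometry(adjust_populations(tab))
#' @export
adjust_allometry <- function(table, models = NULL,
                             by = c("sex", "age", "habitat"),
                             traits = trait_names(),
                             rescale_to_unit_size = TRUE) {
  if (is.null(models)) models <- fit_allometry(table, by = by, traits = traits)
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      m <- dplyr::inner_join(key, models, by = by)
      if (nrow(m) != length(traits)) {
        stop("no fitted allometry model for group ",
             paste(unlist(key), collapse = "/"), call. = FALSE)
      }
      gm <- row_gm(d, traits)
      if (any(gm <= 0)) stop("non-positive individual size", call. = FALSE)
      X0 <- m$X0[1]
      for (tr in traits) {
        b <- m$slope[m$trait == tr]
        d[[tr]] <- d[[tr]] * (X0 / gm)^b
        if (rescale_to_unit_size) d[[tr]] <- d[[tr]] / X0
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(intersect(
      c("id", "population", "habitat", "sex", "age"), names(table)
    )))
  out <- set_flag(out, "allometry_adjusted")
  if (rescale_to_unit_size) out <- set_flag(out, "size_standardized")
  copy_flag(out, table, "population_adjusted")
}

#' Preprocessing flags carried by adjusted tables
#'
#' @param table A trait table.
#' @return Named logical vector with elements `population_adjusted`,
#'   `allometry_adjusted`, `size_standardized`.
#' @export
adjustment_flags <- function(table) {
  flags <- c("population_adjusted", "allometry_adjusted", "size_standardized")
  stats::setNames(vapply(flags, function(f) isTRUE(attr(table, f)), logical(1)),
                  flags)
}

set_flag <- function(table, flag) {
  attr(table, flag) <- TRUE
  table
}

copy_flag <- function(to, from, flag) {
  if (isTRUE(attr(from, flag))) attr(to, flag) <- TRUE
  to
}
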