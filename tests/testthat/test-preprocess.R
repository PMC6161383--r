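test_that("population adjustment raises every population to the largest mean", {
  # two populations, means 10 and 12 on the first trait
  tab <- toy_table(matrix(c(9, 10, 11, 11, 12, 13), ncol = 1),
                   population = rep(c("a", "b"), each = 3))
  adj <- adjust_populations(tab, traits = "HL")
  means <- tapply(adj$HL, adj$population, mean)
  expect_equal(as.numeric(means), c(12, 12))
  # the smaller-mean population was shifted by exactly +2
  expect_equal(adj$HL[1:3], tab$HL[1:3] + 2)

  # one population: unchanged
  tab1 <- toy_table(matrix(rnorm(10, 50, 2), ncol = 1))
  expect_equal(adjust_populations(tab1, traits = "HL")$HL, tab1$HL)
})

test_that("three populations shift by +3, +2, 0 and keep deviations", {
  set.seed(11)
  dev <- rnorm(12, 0, 0.5)
  vals <- rep(c(8, 9, 11), each = 4) + dev
  tab <- toy_table(matrix(vals, ncol = 1),
                   population = rep(c("a", "b", "c"), each = 4))
  # force exact population means 8, 9, 11
  for (p in c("a", "b", "c")) {
    i <- tab$population == p
    tab$HL[i] <- tab$HL[i] - mean(tab$HL[i]) + c(a = 8, b = 9, c = 11)[p]
  }
  adj <- adjust_populations(tab, traits = "HL")
  expect_equal(as.numeric(tapply(adj$HL, adj$population, mean)), c(11, 11, 11))
  expect_equal(adj$HL - ave(adj$HL, adj$population),
               tab$HL - ave(tab$HL, tab$population))
})

test_that("population adjustment preserves within-population covariance and is idempotent", {
  tab <- simulate_traits(sim_config(seed = 5))
  adj <- adjust_populations(tab)
  grp <- tab$sex == "female" & tab$age == "adult" & tab$habitat == "open"
  for (p in unique(tab$population[grp])) {
    i <- grp & tab$population == p
    expect_lt(max(abs(stats::cov(tab[i, trait_names()]) -
                      stats::cov(adj[i, trait_names()]))), 1e-10)
  }
  twice <- adjust_populations(adj)
  expect_equal(as.data.frame(twice[trait_names()]),
               as.data.frame(adj[trait_names()]), tolerance = 1e-12)
})

test_that("singleton populations warn but are still adjusted", {
  tab <- toy_table(matrix(c(10, 11, 12, 20), ncol = 1),
                   population = c("a", "a", "a", "b"))
  expect_warning(adj <- adjust_populations(tab, traits = "HL"), "single")
  expect_equal(as.numeric(tapply(adj$HL, adj$population, mean)), c(20, 20))
})

test_that("geometric mean size matches both textbook formulas", {
  expect_equal(geometric_mean_size(rep(7, 14)), 7)
  expect_equal(geometric_mean_size(c(1, 4)), 2)
  set.seed(3)
  x <- stats::setNames(exp(rnorm(14, 1, 0.5)), trait_names())
  expect_equal(geometric_mean_size(x), prod(x)^(1 / 14), tolerance = 1e-12)
  expect_equal(geometric_mean_size(rev(x)), geometric_mean_size(x))
  expect_error(geometric_mean_size(c(HL = 1, NL = -2)), "NL")
})

test_that("allometry fit is exact on noise-free data and errors degenerate", {
  cfg <- one_group_config(30, slopes = rep(1, 14), residual_sd = 0,
                          sd_log_size = 0.2)
  fits <- fit_allometry(simulate_traits(cfg))
  expect_equal(fits$slope, rep(1, 14), tolerance = 1e-9)
  expect_equal(fits$r_squared, rep(1, 14), tolerance = 1e-9)

  const <- toy_table(matrix(5, nrow = 10, ncol = 14))
  expect_error(fit_allometry(const), "variance")
  expect_error(fit_allometry(toy_table(matrix(rnorm(28, 10), 2, 14))),
               "3 individuals")
})

test_that("allometry slopes are recovered from noisy data at n = 2000", {
  cfg <- one_group_config(2000, slopes = unname(default_allometry_slopes()),
                          residual_sd = 0.05, sd_log_size = 0.15, seed = 9)
  fits <- fit_allometry(simulate_traits(cfg))
  expect_lt(max(abs(fits$slope - default_allometry_slopes()[fits$trait])), 0.05)
})

test_that("power-law correction evaluates the quoted formula", {
  # two traits chosen so the individual GM is 2; X0 = 1 and b = (2, 0)
  tab <- toy_table(matrix(c(10, 0.4), nrow = 1))
  models <- tibble::tibble(
    sex = "female", age = "adult", habitat = "open",
    X0 = 1, trait = c("HL", "NL"), slope = c(2, 0), intercept = 0,
    r_squared = 1, n = 1
  )
  adj <- adjust_allometry(tab, models = models, traits = c("HL", "NL"),
                          rescale_to_unit_size = FALSE)
  expect_equal(adj$HL, 10 * (1 / 2)^2) # 2.5
  expect_equal(adj$NL, 0.4)            # b = 0: size has no effect
})

test_that("b = 1 identity traits collapse to the group mean size", {
  cfg <- one_group_config(25, slopes = rep(1, 14), residual_sd = 0,
                          sd_log_size = 0.2)
  tab <- simulate_traits(cfg)
  fits <- fit_allometry(tab)
  adj <- adjust_allometry(tab, models = fits, rescale_to_unit_size = FALSE)
  # Y_i proportional to X_i with b = 1 -> Y* constant within group
  for (tr in trait_names()) {
    expect_lt(diff(range(adj[[tr]])), 1e-9 * mean(adj[[tr]]))
  }
})

test_that("allometric adjustment removes the size signal", {
  cfg <- one_group_config(2000, slopes = unname(default_allometry_slopes()),
                          residual_sd = 0.05, sd_log_size = 0.15, seed = 13)
  tab <- simulate_traits(cfg)
  gm <- exp(rowMeans(log(as.matrix(tab[trait_names()]))))
  adj <- adjust_allometry(tab)
  for (tr in trait_names()) {
    expect_lt(abs(stats::cor(log(adj[[tr]]), log(gm))), 0.05)
  }
  expect_true(all(adjustment_flags(adj)[c("allometry_adjusted",
                                          "size_standardized")]))
})

test_that("adjusted traits sit at theoretical body size 1", {
  tab <- simulate_traits(one_group_config(50, slopes = rep(1, 14),
                                          residual_sd = 0, sd_log_size = 0.2))
  adj <- adjust_allometry(tab)
  gm_adj <- exp(rowMeans(log(as.matrix(adj[trait_names()]))))
  expect_equal(gm_adj, rep(1, 50), tolerance = 1e-9)
})
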