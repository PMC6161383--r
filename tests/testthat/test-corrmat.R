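test_that("Pearson matrices match hand computations", {
  # duplicated trait
  set.seed(1)
  v <- rnorm(10, 50, 3)
  tab <- toy_table(cbind(v, v))
  R <- correlation_matrix(tab, traits = c("HL", "NL"))
  expect_equal(R["HL", "NL"], 1)

  # printed 3-row toy: (1,2), (2,3), (3,5) -> r = 0.9820
  toy <- toy_table(cbind(c(1, 2, 3), c(2, 3, 5)))
  R <- correlation_matrix(toy, traits = c("HL", "NL"))
  expect_equal(round(R["HL", "NL"], 4), 0.9820)

  expect_error(correlation_matrix(toy_table(cbind(1:5, rep(2, 5))),
                                  traits = c("HL", "NL")),
               "NL")
})

test_that("group correlation matrices recover the generating structure", {
  cfg <- one_group_config(2000, rho_within = 0.5, rho_between = 0.1, seed = 21)
  tab <- simulate_traits(cfg)
  R <- correlation_matrix(tab)
  Rt <- build_modular_correlation(cfg$partition, 0.5, 0.1)
  expect_lt(max(abs(R - Rt)), 0.06)
  expect_identical(attr(R, "n"), 2000L)
  expect_true(isSymmetric(unclass(R)))
})

test_that("matrix correlation equals Pearson on the 91 off-diagonal elements", {
  set.seed(2)
  A <- random_corr(14)
  dimnames(A) <- list(trait_names(), trait_names())
  B <- random_corr(14)
  dimnames(B) <- list(trait_names(), trait_names())
  # brute-force oracle: collect the lower triangle by explicit loops
  a <- b <- c()
  for (i in 2:14) for (j in 1:(i - 1)) {
    a <- c(a, A[i, j]); b <- c(b, B[i, j])
  }
  expect_length(a, 91)
  expect_equal(matrix_correlation(A, B), stats::cor(a, b), tolerance = 1e-12)

  expect_equal(matrix_correlation(A, A), 1)
  expect_equal(matrix_correlation(A, B), matrix_correlation(B, A))

  # perfectly reversed 3x3 off-diagonals
  m1 <- diag(3); m1[lower.tri(m1)] <- c(0.1, 0.2, 0.3)
  m1[upper.tri(m1)] <- t(m1)[upper.tri(m1)]
  m2 <- diag(3); m2[lower.tri(m2)] <- c(0.3, 0.2, 0.1)
  m2[upper.tri(m2)] <- t(m2)[upper.tri(m2)]
  expect_equal(matrix_correlation(m1, m2), -1)

  expect_error(matrix_correlation(A, matrix(0, 14, 14)), "zero variance")
})

test_that("matrix correlation is invariant to a shared relabeling", {
  set.seed(4)
  A <- random_corr(14); B <- random_corr(14)
  p <- sample(14)
  expect_equal(matrix_correlation(A, B), matrix_correlation(A[p, p], B[p, p]),
               tolerance = 1e-12)
})

test_that("Mantel test honours its permutation conventions", {
  set.seed(5)
  A <- random_corr(14)
  # self-comparison: no permutation of a generic matrix recreates r = 1
  mt <- mantel_test(A, A, n_permutations = 999, seed = 1)
  expect_equal(mt$r_observed, 1)
  expect_equal(mt$p, 1 / 1000)

  # a constant (equicorrelated) matrix has no off-diagonal variance: the
  # matrix correlation, and hence the test, is undefined
  B <- matrix(0.3, 14, 14); diag(B) <- 1
  expect_error(mantel_test(A, B, n_permutations = 199, seed = 1),
               "zero variance")

  # one-tailed: a strongly anti-patterned pair cannot look significant
  mt3 <- mantel_test(A, -A + 2 * diag(diag(A)), n_permutations = 199, seed = 2)
  expect_equal(mt3$r_observed, -1)
  expect_gt(mt3$p, 0.5)

  # determinism
  C <- random_corr(14)
  mt1 <- mantel_test(A, C, n_permutations = 199, seed = 3)
  mt2 <- mantel_test(A, C, n_permutations = 199, seed = 3)
  expect_identical(mt1$p, mt2$p)
  expect_identical(mt1$r_permuted, mt2$r_permuted)
  expect_error(mantel_test(A, A, n_permutations = 50), "n_permutations")
})

test_that("Mantel statistic agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(6)
  cfg <- one_group_config(150, rho_within = 0.5, rho_between = 0.1, seed = 31)
  R <- correlation_matrix(simulate_traits(cfg))
  B <- connectivity_matrix(builtin_hypotheses()$trunk_forelimbs_hindlimbs)
  ours <- mantel_test(R, B, n_permutations = 499, seed = 1)
  ref <- vegan::mantel(stats::as.dist(R), stats::as.dist(B),
                       permutations = 499)
  expect_equal(ours$r_observed, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(ours$p, 0.05)
  expect_lt(ref$signif, 0.05)
})

test_that("repeatability saturates, decreases with noise, and is seeded", {
  set.seed(7)
  base <- matrix(rnorm(3 * 14), 3, 14) * 2 + 50
  tab <- toy_table(base[rep(1:3, length.out = 501), ])
  t_sat <- repeatability(tab, n_iterations = 200, seed = 1)
  expect_gt(t_sat, 0.99)

  cfg <- one_group_config(60, rho_within = 0.6, rho_between = 0.1, seed = 8)
  tab <- simulate_traits(cfg)
  x <- as.matrix(tab[trait_names()])
  ts <- vapply(c(0, 1, 4), function(sd_noise) {
    set.seed(99)
    noisy <- tab
    noisy[trait_names()] <- x + matrix(rnorm(length(x), 0, sd_noise), nrow(x))
    repeatability(noisy, n_iterations = 150, seed = 2)
  }, numeric(1))
  expect_true(all(diff(ts) <= 0))

  expect_identical(
    as.numeric(repeatability(tab, n_iterations = 100, seed = 5)),
    as.numeric(repeatability(tab, n_iterations = 100, seed = 5))
  )
})

test_that("pairwise comparison enumerates all unordered group pairs", {
  set.seed(9)
  mats <- purrr::map(1:8, ~random_corr(14, 40))
  mats <- purrr::map(mats, function(m) {
    dimnames(m) <- list(trait_names(), trait_names()); m
  })
  names(mats) <- paste0("g", 1:8)
  pw <- pairwise_group_comparison(mats, n_permutations = 199, seed = 1)
  expect_equal(nrow(pw), 28L)
  expect_equal(nrow(pairwise_group_comparison(mats[1:2],
                                              n_permutations = 199, seed = 1)),
               1L)

  same <- pairwise_group_comparison(list(a = mats[[1]], b = mats[[1]],
                                         c = mats[[1]]),
                                    n_permutations = 199, seed = 1)
  expect_true(all(same$r == 1))

  cm <- comparison_matrix(pw, stats::setNames(rep(0.95, 8), names(mats)))
  expect_equal(dim(cm), c(8L, 8L))
  expect_equal(unname(diag(cm)), rep(0.95, 8))
  expect_equal(cm["g2", "g1"], pw$r[pw$group1 == "g1" & pw$group2 == "g2"])
  expect_equal(cm["g1", "g2"], pw$p[pw$group1 == "g1" & pw$group2 == "g2"])
})
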