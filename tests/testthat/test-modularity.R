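test_that("the eleven built-in hypotheses carry the canonical partitions", {
  h <- builtin_hypotheses()
  expect_length(h, 11L)
  expect_equal(h$head_neck$sets, list(1:3))
  expect_equal(h$trunk_forelimbs_hindlimbs$sets, list(4:6, 7:10, 11:14))
  expect_equal(h$forelimbs_hindlimbs$sets, list(7:10, 11:14))
  expect_equal(h$head_neck_trunk$sets, list(1:3, 4:6))
  expect_equal(h$head_neck_trunk_hindlimbs$sets, list(1:3, 4:6, 11:14))
})

test_that("connectivity matrices count sum-of-choose-2 ones", {
  h <- builtin_hypotheses()
  for (nm in names(h)) {
    B <- connectivity_matrix(h[[nm]])
    expected <- sum(choose(lengths(h[[nm]]$sets), 2))
    expect_equal(sum(B[lower.tri(B)]), expected, info = nm)
    expect_true(all(B %in% c(0, 1)))
    expect_true(isSymmetric(B))
    expect_equal(unname(diag(B)), rep(0, 14))
  }
  expect_equal(sum(connectivity_matrix(h$head_neck)[lower.tri(diag(14))]), 3)
  expect_equal(sum(connectivity_matrix(
    h$trunk_forelimbs_hindlimbs)[lower.tri(diag(14))]), 15)

  # singleton sets contribute no edges
  hs <- module_hypothesis("with_singleton", list(1:3, list(9)[[1]]))
  Bs <- connectivity_matrix(hs)
  expect_equal(sum(Bs), sum(connectivity_matrix(
    module_hypothesis("plain", list(1:3)))))
})

test_that("hypothesis Mantel screening flags the generating structure", {
  cfg <- one_group_config(150, rho_within = 0.5, rho_between = 0.1, seed = 17)
  R <- correlation_matrix(simulate_traits(cfg))
  res <- test_hypotheses(R, n_permutations = 499, seed = 2)
  expect_equal(nrow(res), 11L)
  expect_true(res$significant[res$hypothesis == "trunk_forelimbs_hindlimbs"])
  expect_identical(res,
                   test_hypotheses(R, n_permutations = 499, seed = 2))
})

test_that("equicorrelated truth yields only the nominal significance rate", {
  h <- module_hypothesis("all", list(1:14))
  sig <- 0
  for (s in 1:20) {
    cfg <- one_group_config(100, rho_within = 0.3, rho_between = 0.3,
                            partition = h, seed = 400 + s)
    R <- correlation_matrix(simulate_traits(cfg))
    res <- test_hypotheses(R, n_permutations = 199, seed = s)
    sig <- sig + sum(res$significant)
  }
  # 220 hypothesis tests at alpha = 0.05: nominal expectation 11
  expect_lte(sig / 220, 0.12)
})

test_that("likelihood fit is exact in the degenerate equicorrelated case", {
  R <- matrix(0.3, 14, 14); diag(R) <- 1
  dimnames(R) <- list(trait_names(), trait_names())
  fit <- emmli_fit(R, n = 100, hypotheses = list(), include_null = TRUE)
  expect_equal(fit$model, "null")
  expect_equal(unname(fit$rho[[1]]), 0.3, tolerance = 1e-12)
  sdz <- sqrt(1 / 97)
  expect_equal(fit$lnL, 91 * stats::dnorm(0, 0, sdz, log = TRUE),
               tolerance = 1e-10)
})

test_that("posterior probabilities normalise and AICc follows its formula", {
  cfg <- one_group_config(120, rho_within = 0.5, rho_between = 0.1, seed = 23)
  R <- correlation_matrix(simulate_traits(cfg))
  fit <- emmli_fit(R, n = 120)
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-9)
  expect_equal(min(fit$delta_AICc), 0)
  expect_equal(fit$AICc,
               -2 * fit$lnL + 2 * fit$k +
                 2 * fit$k * (fit$k + 1) / (91 - fit$k - 1),
               tolerance = 1e-10)
  # trunk+forelimbs+hindlimbs: 3 within classes + 1 pooled between
  expect_equal(fit$k[fit$model == "trunk_forelimbs_hindlimbs"], 4L)
  expect_equal(fit$k[fit$model == "null"], 1L)
})

test_that("log-likelihood is invariant to consistent trait relabeling", {
  cfg <- one_group_config(100, seed = 29)
  R <- correlation_matrix(simulate_traits(cfg))
  h <- builtin_hypotheses()["trunk_forelimbs_hindlimbs"]
  fit <- emmli_fit(R, n = 100, hypotheses = h, include_null = FALSE)
  p <- sample(14)
  inv <- order(p)
  h_perm <- list(trunk_forelimbs_hindlimbs = module_hypothesis(
    "perm", lapply(h[[1]]$sets, function(s) inv[s])
  ))
  Rp <- R[p, p]
  fit_p <- emmli_fit(Rp, n = 100, hypotheses = h_perm, include_null = FALSE)
  expect_equal(fit$lnL, fit_p$lnL, tolerance = 1e-10)
})

test_that("refining the null into a modular model never loses likelihood", {
  for (s in 1:5) {
    R <- correlation_matrix(simulate_traits(one_group_config(80, seed = s)))
    fit <- emmli_fit(R, n = 80,
                     hypotheses = builtin_hypotheses()["head_neck"],
                     include_null = TRUE)
    expect_gte(fit$lnL[fit$model == "head_neck"],
               fit$lnL[fit$model == "null"] - 1e-10)
  }
})

test_that("near-unit correlations are clipped with a warning", {
  v <- c(1, 2, 3, 4.001)
  tab <- cbind(v, v + c(0, 1e-9, 0, 0), matrix(rnorm(8, 10), 4, 2))
  R <- stats::cor(tab)
  R[1, 2] <- R[2, 1] <- 1
  expect_warning(fit <- emmli_fit(R, n = 50, hypotheses = list()), "clip")
  expect_true(is.finite(fit$lnL))
})

test_that("likelihood-ratio gate uses the chi-square critical value", {
  expect_equal(likelihood_ratio_test(5, 5)$statistic, 0)
  expect_false(likelihood_ratio_test(5, 5)$significant)
  lr <- likelihood_ratio_test(10, 8)
  expect_equal(lr$statistic, 4)
  expect_true(lr$significant)
  expect_false(likelihood_ratio_test(10, 8.1)$significant)
  expect_equal(lr$critical_value, stats::qchisq(0.95, 1))
  # symmetric in its arguments
  expect_equal(likelihood_ratio_test(8, 10)$statistic, 4)
})
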