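test_that("fit error is the absolute per-network difference, symmetric,
           zero iff equal", {
  sim <- data.frame(network = c("A", "B"), synchrony = c(0.5, 0.6),
                    metastability = c(0.20, 0.25))
  emp <- data.frame(network = c("B", "A"), synchrony = c(0.55, 0.5),
                    metastability = c(0.18, 0.20))
  fe <- fit_error(sim, emp)
  expect_equal(fe$metastability_error[fe$network == "B"], 0.07)
  expect_equal(fe$synchrony_error[fe$network == "A"], 0)
  expect_equal(fe$metastability_error[fe$network == "A"], 0)
  # symmetry
  fe_rev <- fit_error(emp, sim)
  expect_equal(sort(fe_rev$synchrony_error), sort(fe$synchrony_error))
  # identical summaries -> all zeros
  expect_true(all(fit_error(sim, sim)$synchrony_error == 0))
  expect_error(fit_error(sim, emp[1, ]), "labels differ")
})

test_that("optimal coupling takes the argmax of metastability with
           smallest-k tie-breaking, and min-error recovers a planted k", {
  sweep <- data.frame(k = rep(1:3, 2), network = rep(c("A", "B"), each = 3),
                      synchrony = 0.5,
                      metastability = c(0.1, 0.3, 0.2, 0.3, 0.3, 0.1))
  opt <- optimal_coupling(sweep)
  expect_equal(opt$k_opt[opt$network == "A"], 2)
  expect_equal(opt$k_opt[opt$network == "B"], 1)  # tie -> smaller k

  # planted perturbation: error minimal at the generating k
  set.seed(31)
  emp <- data.frame(network = "A", synchrony = 0.42, metastability = 0.17)
  ks <- 1:7
  pert <- abs(rnorm(length(ks), 0, 0.05)); pert[4] <- 0.001
  sim <- data.frame(k = ks, network = "A", synchrony = 0.42 + pert,
                    metastability = 0.17 + pert)
  errs <- do.call(rbind, lapply(split(sim, sim$k), fit_error, emp = emp))
  sim$synchrony_error <- errs$synchrony_error
  sim$metastability_error <- errs$metastability_error
  expect_equal(optimal_coupling(sim, "min_error")$k_opt, 4)
  expect_error(optimal_coupling(sweep[0, ]), "empty")
})

test_that("bootstrap correlation matches the closed-form r, is seeded
           reproducibly, and degenerates correctly on an exact line", {
  x <- c(1.2, 2.1, 2.9, 4.4, 5.0)
  y <- c(0.9, 2.3, 3.3, 3.9, 5.3)
  bs <- bootstrap_correlation(x, y, n_boot = 200, seed = 8)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(bs$estimate, r_direct, tolerance = 1e-12)
  expect_equal(bs$p, cor.test(x, y)$p.value)
  expect_true(bs$ci_low <= bs$estimate && bs$estimate <= bs$ci_high)
  # bit-for-bit reproducibility given (data, n_boot, seed)
  bs2 <- bootstrap_correlation(x, y, n_boot = 200, seed = 8)
  expect_identical(unclass(bs), unclass(bs2))

  lin <- bootstrap_correlation(1:10, 2 * (1:10) + 1, n_boot = 100, seed = 1)
  expect_equal(lin$estimate, 1)
  expect_equal(lin$ci_low, 1)
  expect_equal(lin$ci_high, 1)
  expect_error(bootstrap_correlation(1:5, rep(2, 5)), "zero variance")
  expect_error(bootstrap_correlation(1:2, 2:3), ">= 3")
})

test_that("one-way bootstrap ANOVA reproduces the hand-computed F and the
           covariate adjustment reduces to identity for constants", {
  groups <- list(c(1, 2, 3), c(4, 5, 6))
  # SSB = 13.5 on df1 = 1, MSW = 1 -> F = 13.5
  ba <- bootstrap_anova(groups, n_boot = 200, seed = 2)
  expect_equal(ba$estimate, 13.5, tolerance = 1e-10)
  expect_equal(ba$df1, 1L)
  expect_equal(ba$df2, 4L)
  expect_equal(ba$p, pf(13.5, 1, 4, lower.tail = FALSE))

  # identical groups: F ~ 0
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_lt(bootstrap_anova(same, n_boot = 50, seed = 1)$estimate, 1e-10)

  # constant covariates leave the F unchanged
  covs <- data.frame(size = rep(5, 6), age = rep(30, 6))
  ba_cov <- bootstrap_anova(groups, n_boot = 200, seed = 2,
                            covariates = covs)
  expect_equal(ba_cov$estimate, ba$estimate)
  expect_error(bootstrap_anova(list(1:3)), ">= 2 groups")
})

test_that("Levene's test is zero for equal-dispersion groups and detects a
           25-fold variance ratio", {
  # identical values within each group -> W = 0
  lv0 <- levene_test(list(rep(2, 4), rep(7, 4)))
  expect_equal(lv0$statistic, 0)
  # mirrored dispersion patterns -> absolute deviations identical -> W = 0
  lv_sym <- levene_test(list(c(-1, 0, 1), c(9, 10, 11)))
  expect_equal(lv_sym$statistic, 0, tolerance = 1e-12)

  set.seed(33)
  reject <- vapply(1:5, function(i) {
    g <- list(rnorm(50, sd = 1), rnorm(50, sd = 5))
    levene_test(g)$p < 0.01
  }, logical(1))
  expect_true(all(reject))
})

test_that("KS normality check accepts normal samples and rejects
           exponential ones", {
  set.seed(34)
  p_norm <- vapply(1:5, function(i) ks_normality(rnorm(200))$p, numeric(1))
  expect_gt(median(p_norm), 0.1)
  p_exp <- vapply(1:5, function(i) ks_normality(rexp(200))$p, numeric(1))
  expect_true(all(p_exp < 0.01))
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  # uncorrected variant returns the plain KS statistic
  x <- rnorm(50)
  expect_gt(ks_normality(x, correct = FALSE)$p, 0)
})

test_that("residualization removes a linear covariate effect", {
  set.seed(35)
  cov <- runif(40, 0, 10)
  y <- 3 * cov + rnorm(40, sd = 0.1)
  adj <- residualize(y, data.frame(cov = cov))
  expect_lt(abs(cor(adj, cov)), 1e-8)
  expect_equal(mean(adj), mean(y))
})

test_that("pairwise Bonferroni comparisons scale p by the number of
           pairs", {
  set.seed(36)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 5))
  pw <- pairwise_bonferroni(g)
  expect_equal(nrow(pw), 3)
  raw_ab <- t.test(g$a, g$b)$p.value
  expect_equal(pw$p_bonferroni[pw$group1 == "a" & pw$group2 == "b"],
               min(1, raw_ab * 3))
  expect_lt(pw$p_bonferroni[pw$group2 == "c" & pw$group1 == "a"], 0.001)
})
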