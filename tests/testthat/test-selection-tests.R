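test_that("LRT statistic and p-value follow the chi-squared contract", {
  r <- lrt_pvalue(-100, -100, 2)
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 1)
  # chi-squared quantile oracle: qchisq(0.95, 2)/2 above the null lnL
  stat <- qchisq(0.95, 2)
  r2 <- lrt_pvalue(-100, -100 + stat / 2, 2)
  expect_equal(r2$p_value, 0.05, tolerance = 1e-12)
  expect_equal(r2$statistic, stat, tolerance = 1e-12)
  # optimizer noise is clamped with a warning
  expect_warning(r3 <- lrt_pvalue(-100, -100.01, 1), "clamped")
  expect_identical(r3$statistic, 0)
  expect_identical(r3$p_value, 1)
  expect_error(lrt_pvalue(-Inf, -100, 1), "finite")
  expect_error(lrt_pvalue(-100, -99, 0), "df")
  # monotone decreasing in the statistic for fixed df
  stats <- seq(0, 20, by = 0.5)
  ps <- vapply(stats, function(s) lrt_pvalue(-100, -100 + s / 2, 2)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("model comparisons use the conventional degrees of freedom", {
  tr <- triplet_tree()
  sim <- sim_m0()
  m0 <- fit_model(tr, sim$alignment, "M0", options = fast_opts())
  opt <- fast_opts(fix_branch_lengths = TRUE, kappa_init = m0$mle$kappa)
  p1 <- fit_model_pair(m0$tree, sim$alignment, "M1a/M2a", options = opt)
  lrt <- model_comparison("M1a/M2a", p1)
  expect_identical(lrt$df, 2L)
  expect_equal(lrt$statistic, max(0, 2 * (p1$alt$lnL - p1$null$lnL)),
               tolerance = 1e-12)
  tops <- enumerate_foreground_topologies(m0$tree)
  pb <- fit_model_pair(tops[[1]], sim$alignment, "branch", options = opt)
  expect_identical(model_comparison("branch", pb)$df, 1L)
  # model mismatch and data mismatch are both rejected
  expect_error(model_comparison("M7/M8", p1), "do not match")
  other <- simulate_alignment(simulation_spec(tr, "M0",
                                              list(kappa = 2, omega = 0.5),
                                              60, seed = 999))
  m1b <- fit_model(m0$tree, other$alignment, "M1a", options = opt)
  expect_error(model_comparison("M1a/M2a", list(null = m1b, alt = p1$alt)),
               "different data")
})

test_that("NEB posteriors identify strongly selected sites and normalize", {
  tr <- triplet_tree()
  sim <- simulate_alignment(simulation_spec(
    tr, "M2a", list(kappa = 2, f1 = 0.45, f2 = 0.6, omega0 = 0.1, omega2 = 8),
    300, seed = 51))
  m0 <- fit_model(tr, sim$alignment, "M0", options = fast_opts())
  opt <- fast_opts(fix_branch_lengths = TRUE, kappa_init = m0$mle$kappa)
  p <- fit_model_pair(m0$tree, sim$alignment, "M1a/M2a", options = opt)
  lrt <- model_comparison("M1a/M2a", p)
  expect_lt(lrt$p_value, 0.05)
  rec <- site_posteriors(p$alt, "NEB", lrt = lrt)
  expect_identical(nrow(rec), 300L)
  expect_true(all(rec$posterior >= 0 & rec$posterior <= 1))
  # posteriors over all classes sum to one per site
  post <- omegascan:::class_posteriors(p$alt$per_site_class_loglik,
                                       p$alt$proportions)
  expect_equal(rowSums(post), rep(1, 300), tolerance = 1e-9)
  # true positive sites get systematically higher posteriors
  truth <- sim$omega_background > 1
  expect_gt(mean(rec$posterior[truth]), mean(rec$posterior[!truth]) + 0.2)
  # flagged sites are strongly enriched for true positives (the positive
  # class holds ~22% of sites a priori)
  flagged <- rec$codon_index[rec$significant]
  if (length(flagged) >= 5)
    expect_gte(mean(truth[flagged]), 0.6)

  # conditionality: a non-significant LRT yields an empty record set
  fake <- lrt; fake$p_value <- 0.5
  expect_identical(nrow(site_posteriors(p$alt, "NEB", lrt = fake)), 0L)
})

test_that("fits without a positive class produce no site records", {
  tr <- triplet_tree()
  sim <- sim_m0()
  m0 <- fit_model(tr, sim$alignment, "M0", options = fast_opts())
  opt <- fast_opts(fix_branch_lengths = TRUE, kappa_init = m0$mle$kappa)
  f1 <- fit_model(m0$tree, sim$alignment, "M1a", options = opt)
  f2 <- fit_model(m0$tree, sim$alignment, "M2a", options = opt, warm_from = f1)
  if (all(f2$omega_foreground <= 1))
    expect_identical(nrow(site_posteriors(f2, "NEB")), 0L)
  expect_error(site_posteriors(f1, "NEB"), "M2a, M8")
})

test_that("BEB agrees with NEB on informative data", {
  tr <- triplet_tree()
  sim <- simulate_alignment(simulation_spec(
    tr, "M2a", list(kappa = 2, f1 = 0.45, f2 = 0.6, omega0 = 0.1, omega2 = 8),
    200, seed = 61))
  m0 <- fit_model(tr, sim$alignment, "M0", options = fast_opts())
  opt <- fast_opts(fix_branch_lengths = TRUE, kappa_init = m0$mle$kappa)
  p <- fit_model_pair(m0$tree, sim$alignment, "M1a/M2a", options = opt)
  neb <- site_posteriors(p$alt, "NEB")
  beb <- site_posteriors(p$alt, "BEB")
  expect_identical(nrow(beb), 200L)
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
  expect_gt(cor(neb$posterior, beb$posterior), 0.9)
  expect_error(site_posteriors(p$alt, "BEB", lrt = NULL, s = 0.05), NA)
})
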