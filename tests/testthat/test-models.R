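test_that("nested pairs never lose likelihood (warm-started alternatives)", {
  tr <- triplet_tree()
  sim <- simulate_alignment(simulation_spec(
    tr, "M2a", list(kappa = 2, f1 = 0.6, f2 = 0.7, omega0 = 0.3, omega2 = 4),
    150, seed = 21))
  m0 <- fit_model(tr, sim$alignment, "M0", options = fast_opts())
  opt <- fast_opts(fix_branch_lengths = TRUE, kappa_init = m0$mle$kappa)
  p1 <- fit_model_pair(m0$tree, sim$alignment, "M1a/M2a", options = opt)
  p2 <- fit_model_pair(m0$tree, sim$alignment, "M7/M8", options = opt)
  expect_gte(p1$alt$lnL, p1$null$lnL)
  expect_gte(p2$alt$lnL, p2$null$lnL)
  # free-parameter counts differ by the comparison's degrees of freedom
  expect_identical(p1$alt$npar - p1$null$npar, 2L)
  expect_identical(p2$alt$npar - p2$null$npar, 2L)

  tops <- enumerate_foreground_topologies(m0$tree)
  pb <- fit_model_pair(tops[[1]], sim$alignment, "branch", options = opt)
  pbs <- fit_model_pair(tops[[1]], sim$alignment, "branch-site", options = opt)
  expect_gte(pb$alt$lnL, pb$null$lnL)
  expect_gte(pbs$alt$lnL, pbs$null$lnL)
  expect_identical(pb$alt$npar - pb$null$npar, 1L)
  expect_identical(pbs$alt$npar - pbs$null$npar, 1L)
})

test_that("M0 recovers its generating parameters on long alignments", {
  tr <- triplet_tree()
  sim <- simulate_alignment(simulation_spec(tr, "M0",
                                            list(kappa = 2, omega = 0.4),
                                            2000, seed = 31))
  fit <- fit_model(tr, sim$alignment, "M0",
                   options = fast_opts(pi = codon_frequencies(estimator = "equal")))
  expect_lt(abs(unname(fit$mle$model_pars["omega"]) - 0.4), 0.12)
  expect_lt(abs(fit$mle$kappa - 2), 0.5)
  expect_lt(abs(sum(fit$mle$branch_lengths) - sum(tr$edge.length)), 0.12)
})

test_that("M2a recovers a positive-selection class", {
  tr <- triplet_tree()
  # 10% of sites at omega = 4: the scenario the positive-selection class
  # is designed for
  sim <- simulate_alignment(simulation_spec(
    tr, "M2a", list(kappa = 2, f1 = 0.6, f2 = 0.75, omega0 = 0.2, omega2 = 4),
    600, seed = 41))
  m0 <- fit_model(tr, sim$alignment, "M0", options = fast_opts())
  opt <- fast_opts(fix_branch_lengths = TRUE, kappa_init = m0$mle$kappa)
  f1 <- fit_model(m0$tree, sim$alignment, "M1a", options = opt)
  f2 <- fit_model(m0$tree, sim$alignment, "M2a", options = opt, warm_from = f1)
  expect_gt(unname(f2$mle$model_pars["omega2"]), 1)
  p2_hat <- (1 - f2$mle$model_pars[["f1"]]) * (1 - f2$mle$model_pars[["f2"]])
  # true positive-class proportion 0.1; sampling error on a 3-taxon tree
  # at 600 codons is substantial
  expect_lt(abs(unname(p2_hat) - 0.1), 0.12)
})

test_that("mixture definitions respect their constraints", {
  mix <- omegascan:::model_mixture("M2a",
                                   list(f1 = 0.5, f2 = 0.4, omega0 = 0.3, omega2 = 2))
  expect_equal(sum(mix$props), 1)
  expect_true(all(mix$props >= 0))
  expect_identical(mix$w_bg[2], 1)

  bs <- omegascan:::model_mixture("branch-site-alt",
                                  list(f1 = 0.5, f2 = 0.4, omega0 = 0.3, omega2 = 3))
  expect_equal(sum(bs$props), 1)
  # 2a/2b split inherits the 0/1 ratio
  expect_equal(bs$props[3] / bs$props[4], bs$props[1] / bs$props[2])
  expect_identical(bs$w_fg[3], 3)
  expect_identical(bs$w_bg[3], 0.3)
  # the null pins omega2 at 1
  bs0 <- omegascan:::model_mixture("branch-site-null",
                                   list(f1 = 0.5, f2 = 0.4, omega0 = 0.3))
  expect_identical(bs0$w_fg[3], 1)

  m8 <- omegascan:::model_mixture("M8",
                                  list(p = 0.5, q = 1.5, p0 = 0.9, omega_s = 2))
  expect_equal(sum(m8$props), 1)
  expect_length(m8$props, 11)
  expect_gte(m8$w_bg[11], 1)
})

test_that("branch and branch-site models require a labelled topology", {
  tr <- triplet_tree()
  aln <- sim_m0()$alignment
  expect_error(fit_model(tr, aln, "branch-alt", options = fast_opts()),
               "labelled_topology")
})
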