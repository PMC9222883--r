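test_that("invariant sites are not called selected", {
  tr <- triplet_tree()
  aln <- codon_alignment(c(outgroup = strrep("ATGAAACCCTGG", 3),
                           speciesA = strrep("ATGAAACCCTGG", 3),
                           speciesB = strrep("ATGAAACCCTGG", 3)))
  scan <- fel_scan(tr, aln, options = fast_opts())
  expect_identical(nrow(scan), 12L)
  expect_true(all(scan$direction == "none"))
  expect_identical(attr(scan, "n_positive") + attr(scan, "n_negative"), 0L)
})

test_that("FEL recovers the direction of selection per site", {
  # per-site tests need more than a handful of taxa to have power: use an
  # 8-taxon tree with moderate divergence
  set.seed(1)
  tr <- ape::unroot(ape::rtree(8, br = function(n) runif(n, 0.1, 0.5)))
  tr$tip.label <- paste0("s", 1:8)
  # strong purifying and strong positive blocks
  neg <- simulate_alignment(simulation_spec(tr, "M0",
                                            list(kappa = 2, omega = 0.05),
                                            40, seed = 71))
  pos <- simulate_alignment(simulation_spec(tr, "M0",
                                            list(kappa = 2, omega = 8),
                                            40, seed = 72))
  aln <- codon_alignment(cbind(neg$alignment$codons, pos$alignment$codons),
                         neg$alignment$taxa)
  scan <- fel_scan(tr, aln, options = fast_opts())
  expect_identical(nrow(scan), 80L)
  # lnL_free >= lnL_constrained site-wise, p in [0,1], partition of calls
  expect_true(all(scan$lnL_free >= scan$lnL_constrained - 1e-6))
  expect_true(all(scan$p_value >= 0 & scan$p_value <= 1))
  expect_identical(sum(scan$direction %in% c("positive", "negative", "none")),
                   80L)
  neg_calls <- scan$direction[1:40]
  pos_calls <- scan$direction[41:80]
  # directions that are called must match the generating regime
  expect_gt(sum(neg_calls == "negative"), 0)
  expect_gt(sum(pos_calls == "positive"), 0)
  expect_identical(sum(neg_calls == "positive"), 0L)
  expect_identical(sum(pos_calls == "negative"), 0L)
  # alpha/beta ordering matches the regime on significant sites
  sig <- scan[scan$direction != "none", ]
  expect_true(all((sig$beta > sig$alpha) == (sig$direction == "positive")))
})

test_that("free per-site fits can only improve on the shared-omega baseline", {
  tr <- triplet_tree()
  sim <- sim_m0()
  baseline <- fit_global_baseline(tr, sim$alignment, options = fast_opts())
  scan <- fel_scan(tr, sim$alignment, baseline = baseline)
  expect_gte(sum(scan$lnL_free), baseline$fit$lnL - 1e-6)
  # baseline consistency: site_likelihoods at the M0 optimum reproduces lnL
  sl <- site_likelihoods(baseline$fit$tree, sim$alignment, "M0",
                         list(kappa = baseline$fit$mle$kappa,
                              omega = unname(baseline$fit$mle$model_pars["omega"])),
                         pi = baseline$fit$pi)
  expect_equal(sl$lnL, baseline$fit$lnL, tolerance = 1e-6)
})

test_that("fel_site_test works on a single column", {
  tr <- triplet_tree()
  sim <- sim_m0()
  baseline <- fit_global_baseline(tr, sim$alignment, options = fast_opts())
  r <- fel_site_test(5, baseline)
  expect_identical(r$codon_index, 5L)
  expect_true(all(c("alpha", "beta", "p_value", "direction") %in% names(r)))
  expect_gte(r$lnL_free, r$lnL_constrained - 1e-8)
})
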