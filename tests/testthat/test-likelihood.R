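pi_eq <- codon_frequencies(estimator = "equal")

test_that("identical sequences on a zero-length tree give lnL = sum log pi", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  aln <- codon_alignment(c(A = "ATGAAACCC", B = "ATGAAACCC", C = "ATGAAACCC"))
  sl <- site_likelihoods(tr, aln, "M0", list(kappa = 2, omega = 1), pi = pi_eq)
  expect_equal(sl$lnL, 3 * log(1 / 61), tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on 3- and 4-taxon trees", {
  tr3 <- ape::read.tree(text = "(A:0.2,B:0.3,C:0.1);")
  sim3 <- simulate_alignment(simulation_spec(tr3, "M0",
                                             list(kappa = 2, omega = 0.5),
                                             30, seed = 11))
  mix <- omegascan:::model_mixture("M0", list(omega = 0.5))
  bf <- brute_force_site_loglik(tr3, sim3$alignment, 2, mix, pi_eq)
  sl <- site_likelihoods(tr3, sim3$alignment, "M0",
                         list(kappa = 2, omega = 0.5), pi = pi_eq)
  expect_equal(rowSums(sl$per_site), bf, tolerance = 1e-8)

  # 4 taxa, one internal node pair; mixture model with two classes
  tr4 <- ape::unroot(ape::read.tree(text = "((A:0.2,B:0.1):0.15,(C:0.3,D:0.05):0.1);"))
  sim4 <- simulate_alignment(simulation_spec(tr4, "M1a",
                                             list(kappa = 3, p0 = 0.6, omega0 = 0.2),
                                             20, seed = 5))
  mix4 <- omegascan:::model_mixture("M1a", list(p0 = 0.6, omega0 = 0.2))
  bf4 <- brute_force_site_loglik(tr4, sim4$alignment, 3, mix4, pi_eq)
  sl4 <- site_likelihoods(tr4, sim4$alignment, "M1a",
                          list(kappa = 3, p0 = 0.6, omega0 = 0.2), pi = pi_eq)
  per_site <- vapply(seq_len(nrow(sl4$per_site)), function(j) {
    v <- sl4$per_site[j, ] + log(sl4$proportions)
    m <- max(v); m + log(sum(exp(v - m)))
  }, numeric(1))
  expect_equal(per_site, bf4, tolerance = 1e-8)
  expect_lt(max(abs((per_site - bf4) / bf4)), 1e-8)
})

test_that("branch-site likelihoods honour the foreground assignment", {
  tr <- triplet_tree()
  tops <- enumerate_foreground_topologies(tr)
  topo <- tops[[2]]
  sim <- simulate_alignment(simulation_spec(
    topo, "branch-site-alt",
    list(f1 = 0.6, f2 = 0.7, omega0 = 0.2, omega2 = 4, kappa = 2), 25, seed = 9))
  params <- list(kappa = 2, f1 = 0.6, f2 = 0.7, omega0 = 0.2, omega2 = 4)
  mix <- omegascan:::model_mixture("branch-site-alt", params)
  fg <- seq_len(nrow(topo$tree$edge)) == topo$foreground_edge
  bf <- brute_force_site_loglik(topo$tree, sim$alignment, 2, mix, pi_eq,
                                fg_edge = fg)
  sl <- site_likelihoods(topo, sim$alignment, "branch-site-alt", params,
                         pi = pi_eq)
  per_site <- vapply(seq_len(nrow(sl$per_site)), function(j) {
    v <- sl$per_site[j, ] + log(sl$proportions)
    m <- max(v); m + log(sum(exp(v - m)))
  }, numeric(1))
  expect_equal(per_site, bf, tolerance = 1e-8)
  # a foreground omega2 > 1 must change the likelihood relative to omega2 = 1
  sl_null <- site_likelihoods(topo, sim$alignment, "branch-site-null",
                              list(kappa = 2, f1 = 0.6, f2 = 0.7, omega0 = 0.2),
                              pi = pi_eq)
  expect_false(isTRUE(all.equal(sl$lnL, sl_null$lnL)))
})

test_that("duplicating a site column adds exactly its contribution", {
  tr <- triplet_tree()
  sim <- sim_m0()
  aln <- sim$alignment
  dup <- codon_alignment(cbind(aln$codons, aln$codons[, 7, drop = FALSE]),
                         aln$taxa)
  p <- list(kappa = 2, omega = 0.5)
  sl1 <- site_likelihoods(tr, aln, "M0", p, pi = pi_eq)
  sl2 <- site_likelihoods(tr, dup, "M0", p, pi = pi_eq)
  expect_equal(sl2$lnL - sl1$lnL, rowSums(sl1$per_site)[7], tolerance = 1e-9)
})

test_that("likelihood is invariant under taxon reordering", {
  tr <- triplet_tree()
  aln <- sim_m0()$alignment
  perm <- codon_alignment(aln$codons[c(3, 1, 2), ], aln$taxa[c(3, 1, 2)])
  p <- list(kappa = 2, omega = 0.5)
  expect_equal(site_likelihoods(tr, aln, "M0", p, pi = pi_eq)$lnL,
               site_likelihoods(tr, perm, "M0", p, pi = pi_eq)$lnL,
               tolerance = 1e-10)
})

test_that("unclean codons are rejected with a clear message", {
  tr <- triplet_tree()
  bad <- codon_alignment(c(outgroup = "ATGTAA", speciesA = "ATGAAA",
                           speciesB = "ATGAAA"))
  expect_error(site_likelihoods(tr, bad, "M0", list(kappa = 2, omega = 1)),
               "not a sense codon")
})
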