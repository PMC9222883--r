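test_that("zero branch lengths copy the root; omega 0 forbids amino-acid change", {
  tr0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  sim <- simulate_alignment(simulation_spec(tr0, "M0",
                                            list(kappa = 2, omega = 1),
                                            50, seed = 1))
  expect_identical(sim$alignment$codons[1, ], sim$alignment$codons[2, ])
  expect_identical(sim$alignment$codons[1, ], sim$alignment$codons[3, ])

  sim0 <- simulate_alignment(simulation_spec(triplet_tree(), "M0",
                                             list(kappa = 2, omega = 0),
                                             80, seed = 2))
  code <- genetic_code()
  aa <- matrix(code$table[sim0$alignment$codons], nrow = 3)
  expect_true(all(aa[1, ] == aa[2, ] & aa[1, ] == aa[3, ]))
})

test_that("simulation is deterministic in the seed and labels classes truly", {
  sp <- simulation_spec(triplet_tree(), "M1a",
                        list(kappa = 2, p0 = 0.7, omega0 = 0.2), 40, seed = 5)
  a <- simulate_alignment(sp)
  b <- simulate_alignment(sp)
  expect_identical(a$alignment$codons, b$alignment$codons)
  expect_identical(a$site_class, b$site_class)
  expect_setequal(unique(a$omega_background), c(0.2, 1))
  sp2 <- sp; sp2$seed <- 6L
  expect_false(identical(simulate_alignment(sp2)$alignment$codons,
                         a$alignment$codons))
})

test_that("simulated codon usage converges to the stationary frequencies", {
  tr <- triplet_tree()
  pi <- f3x4_frequencies(codon_alignment(c(a = "ATGAAACCCGGGTTTACGTAC",
                                           b = "ATGAAACCAGGCTTCACATAT")))
  sim <- simulate_alignment(simulation_spec(tr, "M0",
                                            list(kappa = 2, omega = 1),
                                            10000, pi = pi, seed = 8))
  emp <- table(factor(sim$alignment$codons, levels = names(pi)))
  emp <- as.numeric(emp) / sum(emp)
  # multinomial error at n = 30000 draws: compare in aggregate
  expect_lt(max(abs(emp - as.numeric(pi))), 0.012)
  expect_gt(cor(emp, as.numeric(pi)), 0.98)
})

test_that("branch-site simulation puts extra nonsynonymous change on the foreground", {
  tops <- enumerate_foreground_topologies(triplet_tree())
  topo <- tops[[1]]  # foreground: the outgroup terminal branch
  sim <- simulate_alignment(simulation_spec(
    topo, "branch-site-alt",
    list(kappa = 2, f1 = 0.2, f2 = 0.5, omega0 = 0.1, omega2 = 10),
    400, seed = 9))
  expect_length(sim$omega_foreground, 400)
  expect_true(any(sim$omega_foreground > 1))
  expect_true(all(sim$omega_background <= 1))
})

test_that("experiment tables are well-formed and empty at zero replicates", {
  empty <- type1_power_experiment(list(), 0)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("spec", "comparison", "rate", "ci_lower", "ci_upper") %in%
                    names(empty)))
  specs <- list(null = list(
    spec = simulation_spec(triplet_tree(), "M0", list(kappa = 2, omega = 1), 60),
    comparisons = "M1a/M2a"))
  tab <- type1_power_experiment(specs, 2, options = fast_opts(), seed = 3)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$replicates, 2L)
  expect_true(tab$rate >= 0 && tab$rate <= 1)
  expect_true(tab$ci_lower <= tab$rate && tab$rate <= tab$ci_upper)
})
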