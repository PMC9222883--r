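# Shared fixtures and independent oracles for the test suite.

# light optimizer settings for unit tests (acceptance tests choose their own)
fast_opts <- function(...) {
  args <- utils::modifyList(list(restarts = 0, max_iter = 60, rel_tol = 1e-8),
                            list(...))
  do.call(omegascan::fit_options, args)
}

triplet_tree <- function() omegascan::example_tree("triplet")

# small simulated alignment memoized across tests
sim_m0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_alignment(simulation_spec(
        triplet_tree(), "M0", list(kappa = 2, omega = 0.5), 60, seed = 101))
    cache
  }
})

# Brute-force likelihood oracle: sums over all internal-node states of the
# tree instead of pruning. Only feasible for <= 4 taxa / 2 internal nodes.
brute_force_site_loglik <- function(tree, alignment, kappa, mixture, pi,
                                    code = genetic_code(), fg_edge = NULL) {
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  internal <- sort(unique(edge[, 1]))
  stopifnot(length(internal) <= 2)
  root <- edge[1, 1]
  if (is.null(fg_edge)) fg_edge <- rep(FALSE, nrow(edge))
  pi <- as.numeric(pi)

  parts <- omegascan:::rate_matrix_parts(kappa, pi, code)
  scale <- omegascan:::mixture_scale(parts, mixture)
  w_fg <- if (is.null(mixture$w_fg)) mixture$w_bg else mixture$w_fg
  pmat <- function(w, t) {
    Q <- (parts$Qs + w * parts$Qn) / scale
    es <- omegascan:::eigen_system_cpp(Q, pi)
    omegascan:::pmat_cpp(es$A, es$C, es$lambda, t)
  }
  Pk <- lapply(seq_along(mixture$props), function(k)
    lapply(seq_len(nrow(edge)), function(e)
      pmat(if (fg_edge[e]) w_fg[k] else mixture$w_bg[k], tree$edge.length[e])))

  states <- apply(alignment$codons[match(tree$tip.label, alignment$taxa), ,
                                   drop = FALSE],
                  2, function(cd) match(cd, code$sense_codons))
  ns <- length(pi)
  other <- setdiff(internal, root)
  vapply(seq_len(ncol(states)), function(j) {
    s <- states[, j]
    tot <- 0
    xr <- seq_len(ns)
    xo <- if (length(other)) seq_len(ns) else 1L
    for (k in seq_along(mixture$props)) {
      lik_k <- 0
      for (r in xr) for (x in xo) {
        pr <- pi[r]
        for (e in seq_len(nrow(edge))) {
          pa <- edge[e, 1]; ch <- edge[e, 2]
          ps <- if (pa == root) r else x
          cs <- if (ch <= ntip) s[ch] else x
          pr <- pr * Pk[[k]][[e]][ps, cs]
        }
        lik_k <- lik_k + pr
      }
      tot <- tot + mixture$props[k] * lik_k
    }
    log(tot)
  }, numeric(1))
}

# write a complete pipeline input set (fasta + tree + ctl) into a directory
write_pipeline_inputs <- function(dir, ncodons = 30, seed = 3,
                                  model = "M0",
                                  params = list(kappa = 2, omega = 0.8)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- triplet_tree()
  sim <- simulate_alignment(simulation_spec(tr, model, params, ncodons, seed = seed))
  write_codon_fasta(sim$alignment, file.path(dir, "aln.fasta"))
  writeLines(ape::write.tree(tr), file.path(dir, "tree.tre"))
  writeLines(c("seqfile = aln.fasta", "Treefile = tree.tre"),
             file.path(dir, "example.ctl"))
  invisible(sim)
}

# read all pipeline output files as one named list of character vectors
read_run_outputs <- function(run_dir) {
  files <- sort(list.files(run_dir, recursive = FALSE, full.names = TRUE))
  files <- files[!dir.exists(files)]
  stats::setNames(lapply(files, readLines), basename(files))
}
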