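test_that("ctl parsing applies defaults, overrides and key validation", {
  wd <- file.path(tempdir(), "cfgtest")
  write_pipeline_inputs(wd)
  cfgs <- parse_config(wd)
  expect_length(cfgs, 1)
  cfg <- cfgs[[1]]
  expect_identical(cfg$tests, c("1", "2", "3", "h"))
  expect_identical(cfg$significance, 0.05)
  expect_identical(cfg$params$CodonFreq, 2)
  expect_identical(cfg$params$icode, 0)
  expect_identical(cfg$params$omega, 1)
  expect_identical(cfg$params$Small_Diff, 0.5e-6)
  expect_identical(cfg$seqfile, "aln.fasta")
  expect_identical(cfg$treefile, "tree.tre")  # 'Treefile' key, case-insensitive

  cfg2 <- parse_config(wd, overrides = list(omega = 0.5, tests = "1h",
                                            significance = 0.01))[[1]]
  expect_identical(cfg2$params$omega, 0.5)
  expect_identical(cfg2$tests, c("1", "h"))
  expect_identical(cfg2$significance, 0.01)

  expect_error(parse_config(wd, overrides = list(bogus_key = 1)), "unknown")
  expect_error(parse_config(wd, overrides = list(tests = "59")), "valid tests")
  # no-op codeml keys are accepted and tracked
  cfg3 <- parse_config(wd, overrides = list(Mgene = 9, rho = 34))[[1]]
  expect_true(all(c("Mgene", "rho") %in% cfg3$noop_keys))
  expect_error(parse_config(file.path(tempdir(), "definitely-empty-dir")),
               "no .ctl files")
})

test_that("task counts follow 4·[1] + 2B·[2] + 2B·[3] + [h]", {
  wd <- file.path(tempdir(), "queuetest")
  sim <- write_pipeline_inputs(wd)
  tree <- parse_newick(file = file.path(wd, "tree.tre"))$tree
  B <- length(enumerate_foreground_topologies(tree))  # 3 for a triplet
  count_for <- function(tests) {
    cfg <- parse_config(wd, overrides = list(tests = tests))[[1]]
    nrow(build_task_queue(cfg, tree, sim$alignment))
  }
  expect_identical(count_for("123h"), 4L + 2L * B + 2L * B + 1L)  # 17
  expect_identical(count_for("1"), 4L)
  expect_identical(count_for("h"), 1L)
  expect_identical(count_for("23"), 4L * B)
  expect_identical(count_for("1h"), 5L)
  # 25-taxon bifurcating tree: 47 topologies, test 2 alone gives 94 tasks
  tr25 <- example_tree("taxa25")
  aln25 <- simulate_alignment(simulation_spec(tr25, "M0",
                                              list(kappa = 2, omega = 1),
                                              5, seed = 1))$alignment
  cfg2 <- parse_config(wd, overrides = list(tests = "2"))[[1]]
  expect_identical(nrow(build_task_queue(cfg2, tr25, aln25)), 94L)
  # fingerprints are unique per task and stable across rebuilds
  cfg <- parse_config(wd)[[1]]
  q1 <- build_task_queue(cfg, tree, sim$alignment)
  q2 <- build_task_queue(cfg, tree, sim$alignment)
  expect_identical(q1$fingerprint, q2$fingerprint)
  expect_false(anyDuplicated(q1$fingerprint) > 0)
})

test_that("pipeline runs, resumes identically, and is thread-invariant", {
  wd <- file.path(tempdir(), paste0("pipe", as.integer(Sys.time())))
  write_pipeline_inputs(wd, ncodons = 25, seed = 13)
  opts <- fast_opts(max_iter = 40)

  cfg <- parse_config(wd, overrides = list(keep_dirs = TRUE))[[1]]
  dir1 <- file.path(wd, "run1")
  res1 <- run_pipeline(cfg, run_dir = dir1, fit_opts = opts)
  out1 <- read_run_outputs(dir1)
  expect_true(all(c("summary.txt", "codons.tsv", "highlighted.fasta") %in%
                    names(out1)))
  expect_identical(nrow(res1$failed), 0L)

  # interrupted run: drop some completed tasks, resume, outputs identical
  dir2 <- file.path(wd, "run2")
  res2a <- run_pipeline(cfg, run_dir = dir2, fit_opts = opts)
  tdirs <- list.dirs(file.path(dir2, "tasks"), recursive = FALSE)
  unlink(tdirs[seq(1, length(tdirs), by = 3)], recursive = TRUE)
  res2 <- run_pipeline(cfg, run_dir = dir2, fit_opts = opts)
  expect_identical(read_run_outputs(dir2), out1)

  # resume skips tasks whose fingerprints match: results are reloaded
  info <- status_and_cleanup(dir2, "info")
  expect_identical(sort(unique(info$state)), "done")

  # thread count must not change any output byte
  cfg4 <- cfg; cfg4$threads <- 4L
  dir3 <- file.path(wd, "run3")
  run_pipeline(cfg4, run_dir = dir3, fit_opts = opts)
  expect_identical(read_run_outputs(dir3), out1)

  # status and cleanup: clean removes task dirs and is idempotent
  status_and_cleanup(dir1, "clean")
  expect_identical(nrow(status_and_cleanup(dir1, "info")), 0L)
  expect_silent(status_and_cleanup(dir1, "clean"))
  # the report files survive cleaning
  expect_true(file.exists(file.path(dir1, "summary.txt")))
})

test_that("input problems surface as errors before any fitting", {
  wd <- file.path(tempdir(), "badinputs")
  write_pipeline_inputs(wd)
  # stop codon in the alignment
  aln <- read_codon_fasta(file.path(wd, "aln.fasta"))
  aln$codons[1, 2] <- "TAA"
  write_codon_fasta(aln, file.path(wd, "aln.fasta"))
  cfg <- parse_config(wd)[[1]]
  expect_error(run_pipeline(cfg, run_dir = file.path(wd, "r")), "analysis-ready")
  # name mismatch between tree and alignment
  write_pipeline_inputs(wd)
  writeLines("(outgroup:0.4,speciesA:0.2,speciesX:0.2);",
             file.path(wd, "tree.tre"))
  expect_error(run_pipeline(parse_config(wd)[[1]],
                            run_dir = file.path(wd, "r2")), "mismatch")
})
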