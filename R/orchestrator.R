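# Control layer: ctl-file configuration, task-graph construction, parallel
# execution with safe restart/resume, status and cleanup.

# recognised ctl keys and their defaults; keys marked no-op are accepted
# and validated for compatibility with conventional codeml ctl files but
# have no effect on the native likelihood core
CTL_DEFAULTS <- list(
  CodonFreq = 2, Malpha = 0, Mgene = 0, RateAncestor = 0,
  Small_Diff = 0.5e-6, aaDist = 0, alpha = 0, cleandata = 1, clock = 0,
  fix_alpha = 1, fix_blength = -1, fix_rho = 1, getSE = 0, icode = 0,
  method = 0, ndata = 1, omega = 1, outfile = "mlc", rho = 0, runmode = 0,
  seqtype = 1)

CTL_ACTIVE_KEYS <- c("CodonFreq", "Small_Diff", "cleandata", "fix_blength",
                     "icode", "omega", "outfile", "seqtype")

#' Parse ctl configuration files
#'
#' Reads `key = value` configuration files naming the sequence and tree
#' inputs (`seqfile`, `treefile`). When `files` is not given, every file
#' with suffix `.ctl` in `path` is used. Keys are matched
#' case-insensitively with whitespace tolerance; unspecified model
#' parameters take the conventional defaults (`CodonFreq 2`, `icode 0`,
#' `cleandata 1`, initial `omega 1`, `Small_Diff 0.5e-6`, ...). Unknown
#' keys are rejected; keys without effect on the native core (e.g.
#' `Mgene`, `rho`, `clock`) are accepted and recorded as no-ops.
#'
#' @param path Directory to scan for ctl files.
#' @param files Optional explicit ctl file paths.
#' @param overrides Named list of command-line parameter overrides
#'   (ctl keys, plus `tests`, `threads`, `significance`, `keep_dirs`).
#' @return A list of `run_config` objects, one per ctl file, each with
#'   `label`, `seqfile`, `treefile`, `tests`, `threads`, `significance`,
#'   `keep_dirs`, `params` (full ctl key set) and `noop_keys`.
#' @export
parse_config <- function(path = ".", files = NULL, overrides = list()) {
  if (is.null(files)) {
    files <- list.files(path, pattern = "\\.ctl$", full.names = TRUE)
    if (!length(files)) stop("no .ctl files found in ", path)
  }
  lapply(sort(files), function(f) parse_one_ctl(f, overrides))
}

parse_one_ctl <- function(file, overrides = list()) {
  if (!file.exists(file)) stop("cannot read ctl file: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("[*#].*$", "", lines)  # comments
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z_0-9]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse ctl line in ", file, ": '", ln, "'")
    kv[[m[2]]] <- trimws(m[3])
  }
  build_run_config(kv, overrides, label = sub("\\.ctl$", "", basename(file)),
                   dir = dirname(file))
}

build_run_config <- function(kv, overrides, label, dir = ".") {
  # case-insensitive key resolution
  resolve <- function(keys, pool) {
    hit <- match(tolower(keys), tolower(names(pool)))
    stats::setNames(pool[hit[!is.na(hit)]], keys[!is.na(hit)])
  }
  known <- c("seqfile", "treefile", names(CTL_DEFAULTS),
             "tests", "threads", "significance", "keep_dirs", "seed")
  for (pool in list(kv, overrides)) {
    bad <- setdiff(tolower(names(pool)), tolower(known))
    if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  get1 <- function(key, default = NULL) {
    for (pool in list(overrides, kv)) {
      hit <- which(tolower(names(pool)) == tolower(key))
      if (length(hit)) return(pool[[hit[1]]])
    }
    default
  }
  seqfile <- get1("seqfile"); treefile <- get1("treefile")
  if (is.null(seqfile)) stop("ctl '", label, "' does not name a seqfile")
  if (is.null(treefile)) stop("ctl '", label, "' does not name a treefile")
  tests <- parse_tests(get1("tests", "123h"))
  s <- as.numeric(get1("significance", 0.05))
  if (is.na(s) || s <= 0 || s >= 1) stop("significance must be in (0,1)")
  threads <- as.integer(get1("threads", 1L))
  if (is.na(threads) || threads < 1L) stop("threads must be >= 1")
  params <- CTL_DEFAULTS
  for (key in names(CTL_DEFAULTS)) {
    v <- get1(key)
    if (!is.null(v)) {
      params[[key]] <- if (is.character(v) && key != "outfile") {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) v else num
      } else v
    }
  }
  noop <- setdiff(names(CTL_DEFAULTS), CTL_ACTIVE_KEYS)
  structure(list(label = label, dir = dir,
                 seqfile = seqfile, treefile = treefile,
                 tests = tests, threads = threads, significance = s,
                 keep_dirs = isTRUE(as.logical(get1("keep_dirs", FALSE))),
                 seed = get1("seed"),
                 params = params, noop_keys = noop),
            class = "run_config")
}

parse_tests <- function(x) {
  x <- gsub("[^123h]", "", tolower(paste(x, collapse = "")))
  tests <- intersect(c("1", "2", "3", "h"), strsplit(x, "")[[1]])
  if (!length(tests)) stop("no valid tests selected (choose from 1, 2, 3, h)")
  tests
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:", x$label, "\n")
  cat("  seqfile:", x$seqfile, " treefile:", x$treefile, "\n")
  cat("  tests:", paste(x$tests, collapse = ""),
      " threads:", x$threads, " significance:", x$significance, "\n")
  invisible(x)
}

#' Build the deterministic task queue
#'
#' Expands a configuration into its fit tasks: test 1 adds the four site
#' models (M1a, M2a, M7, M8); tests 2 and 3 add a null and an alternative
#' fit per enumerated foreground branch; test h adds one FEL scan task. So
#' a fully resolved n-taxon tree has `4 + 2B + 2B + 1` tasks with
#' `B = 2n - 3` branches when all tests run.
#'
#' @param config A `run_config`.
#' @param tree A `phylo` (or [parse_newick()] result).
#' @param alignment The cleaned [codon_alignment()].
#' @return A data frame of task records: `id`, `test`, `model`,
#'   `topology_index`, `state`, `fingerprint`.
#' @export
build_task_queue <- function(config, tree, alignment) {
  tree <- as_phylo(tree)
  check_tree_alignment(tree, alignment)
  ntopo <- if (any(c("2", "3") %in% config$tests))
    length(enumerate_foreground_topologies(tree)) else 0L
  rows <- list()
  add <- function(id, test, model, topo = NA_integer_)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, test = test, model = model, topology_index = topo,
      stringsAsFactors = FALSE)
  if ("1" %in% config$tests)
    for (m in c("M1a", "M2a", "M7", "M8"))
      add(paste0("test1:", m), "1", m)
  if ("2" %in% config$tests)
    for (i in seq_len(ntopo)) {
      add(sprintf("test2:%03d:null", i), "2", "branch-site-null", i)
      add(sprintf("test2:%03d:alt", i), "2", "branch-site-alt", i)
    }
  if ("3" %in% config$tests)
    for (i in seq_len(ntopo)) {
      add(sprintf("test3:%03d:null", i), "3", "branch-null", i)
      add(sprintf("test3:%03d:alt", i), "3", "branch-alt", i)
    }
  if ("h" %in% config$tests)
    add("testh:fel", "h", "fel")
  out <- do.call(rbind, rows)
  out$state <- "pending"
  key_params <- config$params[CTL_ACTIVE_KEYS]
  out$fingerprint <- vapply(seq_len(nrow(out)), function(i)
    object_md5(list(alignment$codons, alignment$taxa,
                    ape::write.tree(tree), out$id[i], key_params,
                    config$significance)), "")
  out
}

#' Run the full analysis pipeline
#'
#' Executes the task queue with at most `config$threads` concurrent
#' processes, persisting each task's result (write-then-rename, so an
#' interrupted run never leaves corrupt state) in its own subdirectory of
#' `run_dir`. On restart, completed tasks whose input fingerprints match
#' are loaded instead of recomputed, so an interrupted-then-resumed run
#' produces output identical to an uninterrupted one. Tasks run in two
#' waves (null models, then warm-started alternatives), and aggregation is
#' by task id, so results do not depend on completion order or thread
#' count.
#'
#' @param config A `run_config` from [parse_config()].
#' @param run_dir Working directory for task state and outputs (default
#'   `<label>.run` next to the ctl file).
#' @param fit_opts [fit_options()] applied to every fit.
#' @param code A [genetic_code()].
#' @return The [compile_results()] object, invisibly; summary, codon
#'   table, highlighted FASTA and annotated trees are written to
#'   `run_dir`.
#' @export
run_pipeline <- function(config, run_dir = NULL,
                         fit_opts = fit_options(), code = genetic_code()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(run_dir)) run_dir <- file.path(config$dir, paste0(config$label, ".run"))
  dir.create(file.path(run_dir, "tasks"), recursive = TRUE, showWarnings = FALSE)

  inputs <- load_run_inputs(config, code)
  queue <- build_task_queue(config, inputs$tree, inputs$alignment)
  fit_opts$omega_init <- config$params$omega
  fit_opts$tol <- config$params$Small_Diff

  topologies <- if (any(queue$test %in% c("2", "3")))
    enumerate_foreground_topologies(inputs$tree) else list()

  run_wave <- function(tasks, prior) {
    if (!nrow(tasks)) return(list())
    worker <- function(i) {
      task <- tasks[i, ]
      run_single_task(task, inputs, topologies, config, fit_opts, run_dir,
                      prior, code)
    }
    nthreads <- max(1L, min(config$threads, nrow(tasks)))
    res <- if (nthreads > 1L && .Platform$OS.type == "unix")
      parallel::mclapply(seq_len(nrow(tasks)), worker, mc.cores = nthreads)
    else lapply(seq_len(nrow(tasks)), worker)
    stats::setNames(res, tasks$id)
  }
  is_alt <- grepl(":alt$", queue$id) | queue$model %in% c("M2a", "M8")
  wave1 <- run_wave(queue[!is_alt, , drop = FALSE], list())
  wave2 <- run_wave(queue[is_alt, , drop = FALSE], wave1)
  results <- c(wave1, wave2)[queue$id]

  failed <- do.call(rbind, lapply(queue$id, function(id) {
    r <- results[[id]]
    if (inherits(r, "task_failure"))
      data.frame(task = id, error = r$message, stringsAsFactors = FALSE)
    else NULL
  })) %||% data.frame(task = character(), error = character())

  getfit <- function(id) {
    r <- results[[id]]
    if (inherits(r, "task_failure")) NULL else r
  }
  pair_entries <- function(test) {
    ids <- queue$id[queue$test == test & grepl(":null$", queue$id)]
    entries <- lapply(ids, function(nid) {
      aid <- sub(":null$", ":alt", nid)
      null <- getfit(nid); alt <- getfit(aid)
      if (is.null(null) || is.null(alt)) return(NULL)
      i <- queue$topology_index[queue$id == nid]
      list(topology = topologies[[i]], null = null, alt = alt)
    })
    entries[!vapply(entries, is.null, TRUE)]
  }
  outputs <- list(
    label = config$label, s = config$significance,
    alignment = inputs$alignment, column_map = inputs$column_map,
    tests = config$tests,
    site_fits = if ("1" %in% config$tests)
      Filter(Negate(is.null),
             list(M1a = getfit("test1:M1a"), M2a = getfit("test1:M2a"),
                  M7 = getfit("test1:M7"), M8 = getfit("test1:M8"))),
    branch_site = if ("2" %in% config$tests) pair_entries("2") else NULL,
    branch = if ("3" %in% config$tests) pair_entries("3") else NULL,
    fel = if ("h" %in% config$tests) getfit("testh:fel") else NULL,
    failed = failed)
  compiled <- compile_results(outputs, code)
  write_run_outputs(compiled, run_dir, code)
  if (!config$keep_dirs) unlink(file.path(run_dir, "tasks"), recursive = TRUE)
  invisible(compiled)
}

load_run_inputs <- function(config, code = genetic_code()) {
  seqpath <- file.path(config$dir, config$seqfile)
  treepath <- file.path(config$dir, config$treefile)
  if (!file.exists(seqpath)) stop("seqfile not found: ", seqpath)
  if (!file.exists(treepath)) stop("treefile not found: ", treepath)
  aln <- read_codon_fasta(seqpath)
  cleaned <- remove_gap_codons(aln)
  report <- validate_cds_alignment(cleaned$alignment, code)
  if (nrow(report))
    stop("alignment is not analysis-ready:\n  ",
         paste(report$message, collapse = "\n  "))
  tree <- parse_newick(file = treepath)$tree
  check_tree_alignment(tree, cleaned$alignment)
  list(alignment = cleaned$alignment, column_map = cleaned$column_map,
       tree = tree)
}

# Execute (or resume) one task; results are persisted atomically and
# reloaded when the stored fingerprint matches.
run_single_task <- function(task, inputs, topologies, config, fit_opts,
                            run_dir, prior, code) {
  tdir <- file.path(run_dir, "tasks", gsub("[^A-Za-z0-9._-]", "_", task$id))
  marker <- file.path(tdir, "done")
  resfile <- file.path(tdir, "result.rds")
  if (file.exists(marker) && file.exists(resfile) &&
      identical(readLines(marker, warn = FALSE)[1], task$fingerprint)) {
    return(readRDS(resfile))
  }
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch({
    if (task$model == "fel") {
      fel_scan(inputs$tree, inputs$alignment, s = config$significance,
               options = fit_opts, code = code)
    } else {
      tr <- if (!is.na(task$topology_index)) topologies[[task$topology_index]]
            else inputs$tree
      warm <- NULL
      if (task$model %in% c("M2a", "M8", "branch-alt", "branch-site-alt")) {
        null_id <- switch(task$model, "M2a" = "test1:M1a", "M8" = "test1:M7",
                          sub(":alt$", ":null", task$id))
        w <- prior[[null_id]]
        if (!is.null(w) && !inherits(w, "task_failure")) warm <- w
      }
      fit_model(tr, inputs$alignment, task$model, options = fit_opts,
                warm_from = warm, code = code)
    }
  }, error = function(e) structure(list(message = conditionMessage(e)),
                                   class = "task_failure"))
  tmp <- paste0(resfile, ".tmp")
  saveRDS(res, tmp)
  file.rename(tmp, resfile)
  writeLines(task$fingerprint, marker)
  res
}

write_run_outputs <- function(compiled, run_dir, code = genetic_code()) {
  writeLines(summary_text(compiled), file.path(run_dir, "summary.txt"))
  utils::write.table(codon_overview_table(compiled, code),
                     file.path(run_dir, "codons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  writeLines(highlight_fasta(compiled$alignment, significant_sites(compiled)),
             file.path(run_dir, "highlighted.fasta"))
  for (w in c("branch", "branch-site")) {
    lines <- annotated_trees(compiled, w)
    if (length(lines))
      writeLines(lines, file.path(run_dir, paste0("trees_", w, ".txt")))
  }
  invisible(run_dir)
}

#' Status information and cleanup of run directories
#'
#' `mode = "info"` lists the task states of a run directory; `mode =
#' "clean"` removes all temporary task subdirectories (idempotent).
#'
#' @param run_dir A run directory created by [run_pipeline()].
#' @param mode `"info"` or `"clean"`.
#' @return For `"info"`, a data frame of task ids and states; for
#'   `"clean"`, the removed paths, invisibly.
#' @export
status_and_cleanup <- function(run_dir, mode = c("info", "clean")) {
  mode <- match.arg(mode)
  tasks_dir <- file.path(run_dir, "tasks")
  dirs <- if (dir.exists(tasks_dir))
    list.dirs(tasks_dir, recursive = FALSE) else character(0)
  if (mode == "info") {
    if (!length(dirs))
      return(data.frame(task = character(), state = character(),
                        stringsAsFactors = FALSE))
    state <- vapply(dirs, function(d) {
      if (file.exists(file.path(d, "done"))) "done"
      else if (file.exists(file.path(d, "result.rds"))) "running"
      else "pending"
    }, "")
    return(data.frame(task = basename(dirs), state = unname(state),
                      stringsAsFactors = FALSE))
  }
  unlink(tasks_dir, recursive = TRUE)
  invisible(dirs)
}
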