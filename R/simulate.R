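# Phylogenetic codon-sequence simulation under the implemented models, and
# replicated type-I error / power experiments built on it.

#' Specify a codon-alignment simulation
#'
#' Describes one synthetic dataset: a tree with branch lengths (expected
#' substitutions per codon), a generating model with parameter values, the
#' number of codons, codon frequencies and a seed that fully determines the
#' output. Site classes are drawn independently per codon from the model's
#' mixture, matching the assumption of the site-class models themselves.
#'
#' @param tree A `phylo` with branch lengths, or a `labelled_topology` for
#'   branch / branch-site generating models.
#' @param model Generating model name (as in [fit_model()]).
#' @param params Named list of model parameters (see [fit_model()]).
#' @param ncodons Number of codon sites.
#' @param pi Codon frequencies (default equal, 1/61).
#' @param seed Integer seed.
#' @param code A [genetic_code()].
#' @param ncat_beta Beta categories for M7/M8 generators.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, model, params, ncodons, pi = NULL,
                            seed = 1L, code = genetic_code(), ncat_beta = 10L) {
  model <- match.arg(model, MODEL_NAMES)
  fg_edge <- NULL
  if (inherits(tree, "labelled_topology")) {
    fg_edge <- seq_len(nrow(tree$tree$edge)) == tree$foreground_edge
    tree <- tree$tree
  } else {
    tree <- as_phylo(tree)
    if (model %in% NEEDS_TOPOLOGY)
      stop("generating model '", model, "' needs a labelled_topology")
  }
  if (is.null(tree$edge.length)) stop("simulation tree must have branch lengths")
  mix <- model_mixture(model, params, ncat_beta)  # validates parameters
  if (any(mix$props < 0) || abs(sum(mix$props) - 1) > 1e-8)
    stop("invalid mixture proportions")
  if (is.null(pi)) pi <- codon_frequencies(estimator = "equal", code = code)
  structure(list(tree = tree, fg_edge = fg_edge, model = model,
                 params = params, ncodons = as.integer(ncodons),
                 pi = normalize_pi(pi, code$sense_codons),
                 seed = as.integer(seed), code = code,
                 ncat_beta = as.integer(ncat_beta)),
            class = "simulation_spec")
}

#' Simulate a codon alignment along a tree
#'
#' Draws root codons from the stationary frequencies and evolves them along
#' every branch using the transition probabilities of each site's class
#' (with the foreground omega of the class on labelled branches). The
#' output is deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `alignment` (a [codon_alignment()]), `site_class`
#'   (integer class label per codon), `omega_background` and
#'   `omega_foreground` (true omega per codon).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- spec$tree
  edge <- tree$edge
  E <- nrow(edge)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- edge[1, 1]
  mix <- model_mixture(spec$model, spec$params, spec$ncat_beta)
  K <- length(mix$props)
  w_fg <- if (is.null(mix$w_fg)) mix$w_bg else mix$w_fg
  fg_edge <- if (is.null(spec$fg_edge)) rep(FALSE, E) else spec$fg_edge
  sense <- spec$code$sense_codons
  ns <- length(sense)

  with_local_seed(spec$seed, {
    cls <- sample.int(K, spec$ncodons, replace = TRUE, prob = mix$props)
    states <- matrix(NA_integer_, nnode, spec$ncodons)
    states[root, ] <- sample.int(ns, spec$ncodons, replace = TRUE, prob = spec$pi)
    cache <- new.env(parent = emptyenv())
    # same rate convention as the likelihood: classes share the mixture-
    # average scale, so branch lengths mean substitutions per codon
    # averaged over classes
    scale <- mixture_scale(cached_parts(cache, spec$params$kappa, spec$pi, spec$code),
                           mix)
    for (e in seq_len(E)) {  # cladewise order: parents precede children
      t <- tree$edge.length[e]
      for (k in unique(cls)) {
        w <- if (fg_edge[e]) w_fg[k] else mix$w_bg[k]
        es <- cached_es(cache, spec$params$kappa, w, spec$pi, spec$code, scale)
        P <- pmat_cpp(es$A, es$C, es$lambda, t)
        sites <- which(cls == k)
        par_states <- states[edge[e, 1], sites]
        for (s in unique(par_states)) {
          i <- sites[par_states == s]
          pr <- pmax(P[s, ], 0)
          states[edge[e, 2], i] <- sample.int(ns, length(i), replace = TRUE,
                                              prob = pr / sum(pr))
        }
      }
    }
    cods <- matrix(sense[states[seq_len(ntip), , drop = FALSE]],
                   ntip, spec$ncodons, dimnames = list(tree$tip.label, NULL))
    list(alignment = codon_alignment(cods),
         site_class = cls,
         omega_background = mix$w_bg[cls],
         omega_foreground = w_fg[cls])
  })
}

#' Built-in fixture trees
#'
#' Two reference shapes used throughout examples and tests: a small
#' three-taxon tree (an outgroup plus two ingroup species, the smallest
#' alignment the selection tests accept, sized like a short primate exon
#' comparison) and a 25-taxon fully resolved tree whose 47 branches
#' exercise foreground enumeration at the scale of a typical species-rich
#' gene family study. Branch lengths are expected substitutions per codon;
#' the 25-taxon tree is scaled to a total length of 4.
#'
#' @param name `"triplet"` or `"taxa25"`.
#' @return A `phylo` with branch lengths.
#' @export
example_tree <- function(name = c("triplet", "taxa25")) {
  name <- match.arg(name)
  if (name == "triplet")
    return(ape::read.tree(text = "(outgroup:0.4,speciesA:0.2,speciesB:0.2);"))
  tr <- with_local_seed(250L, ape::rtree(25, br = stats::runif))
  tr$tip.label <- sprintf("t%02d", seq_len(25))
  tr <- ape::unroot(tr)
  tr$edge.length <- tr$edge.length * 4 / sum(tr$edge.length)
  tr
}

#' Replicated type-I error and power experiment
#'
#' Simulates replicate alignments under each spec and records the rejection
#' rate of the requested model comparisons at significance level `s`. Used
#' to verify that the likelihood-ratio tests hold their nominal level under
#' null-true regimes and have power under positive-selection regimes.
#'
#' @param specs Named list; each element is a list with `spec` (a
#'   [simulation_spec()]; its seed is re-derived per replicate) and
#'   `comparisons` (subset of `"M1a/M2a"`, `"M7/M8"`, `"branch"`,
#'   `"branch-site"`, `"fel"`).
#' @param replicates Number of replicates per spec (0 gives an empty table).
#' @param s Significance level (default 0.05).
#' @param options [fit_options()] used for all fits.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param fel_s Significance level for per-site FEL rejections (defaults to
#'   `s`).
#' @param two_stage If `TRUE` (default), each replicate is fit in two
#'   stages: an M0 fit estimates kappa and branch lengths, which are then
#'   frozen for the mixture-model fits. This mirrors common practice for
#'   large screens and keeps replicated experiments affordable; set to
#'   `FALSE` to re-optimize branch lengths under every model.
#' @return A data frame with one row per (spec, comparison): `spec`,
#'   `comparison`, `replicates`, `rejections`, `rate`, `ci_lower`,
#'   `ci_upper` (exact binomial 95% CI). For `"fel"` the rate is the mean
#'   per-site rejection fraction and the CI columns are `NA`.
#' @export
type1_power_experiment <- function(specs, replicates, s = 0.05,
                                   options = fit_options(), seed = 1L,
                                   fel_s = s, two_stage = TRUE) {
  rows <- list()
  if (replicates > 0) for (nm in names(specs)) {
    entry <- specs[[nm]]
    pvals <- list()
    fel_fracs <- numeric(0)
    for (r in seq_len(replicates)) {
      sp <- entry$spec
      sp$seed <- (seed * 10000L + r * 131L + match(nm, names(specs))) %% 2147483647L
      sim <- simulate_alignment(sp)
      target_fg <- if (!is.null(sp$fg_edge))
        branch_id(sp$tree, sp$tree$edge[which(sp$fg_edge), 2]) else NULL
      fit_opts <- options
      fit_tree <- sp$tree
      if (two_stage) {
        o0 <- options; o0$fix_branch_lengths <- FALSE
        m0 <- fit_model(sp$tree, sim$alignment, "M0", options = o0)
        fit_tree <- m0$tree
        fit_opts$fix_branch_lengths <- TRUE
        fit_opts$kappa_init <- m0$mle$kappa
      }
      for (cmp in entry$comparisons) {
        if (cmp == "fel") {
          scan <- fel_scan(sp$tree, sim$alignment, s = fel_s, options = options)
          fel_fracs <- c(fel_fracs, mean(scan$p_value <= fel_s))
        } else {
          tr <- if (cmp %in% c("branch", "branch-site")) {
            tops <- enumerate_foreground_topologies(fit_tree)
            fgs <- vapply(tops, `[[`, "", "foreground")
            tops[[if (is.null(target_fg)) 1L else match(target_fg, fgs)]]
          } else fit_tree
          fits <- fit_model_pair(tr, sim$alignment, cmp, options = fit_opts)
          lrt <- model_comparison(cmp, fits)
          pvals[[cmp]] <- c(pvals[[cmp]], lrt$p_value)
        }
      }
    }
    for (cmp in entry$comparisons) {
      if (cmp == "fel") {
        rows[[length(rows) + 1L]] <- data.frame(
          spec = nm, comparison = "fel", replicates = as.integer(replicates),
          rejections = NA_integer_, rate = mean(fel_fracs),
          ci_lower = NA_real_, ci_upper = NA_real_, stringsAsFactors = FALSE)
      } else {
        rej <- sum(pvals[[cmp]] <= s)
        ci <- stats::binom.test(rej, replicates)$conf.int
        rows[[length(rows) + 1L]] <- data.frame(
          spec = nm, comparison = cmp, replicates = as.integer(replicates),
          rejections = rej, rate = rej / replicates,
          ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(spec = character(), comparison = character(),
                      replicates = integer(), rejections = integer(),
                      rate = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
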