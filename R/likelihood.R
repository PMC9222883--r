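# Likelihood machinery shared by all model fits: tip-state encoding, site
# pattern compression, eigen-system caching and the mixture log-likelihood.

# Encode a cleaned alignment against a tree into 1-based sense-codon state
# indices (tips in tree order) and compress identical site columns.
prepare_likelihood_data <- function(tree, alignment, code = genetic_code(),
                                    fg_edge = NULL, pi = NULL) {
  tree <- as_phylo(tree)
  check_tree_alignment(tree, alignment)
  sense <- code$sense_codons
  cods <- alignment$codons[match(tree$tip.label, alignment$taxa), , drop = FALSE]
  states <- matrix(match(cods, sense), nrow(cods), ncol(cods))
  if (anyNA(states)) {
    bad <- which(is.na(states), arr.ind = TRUE)[1, ]
    stop(sprintf("codon '%s' (taxon '%s', site %d) is not a sense codon; clean the alignment first",
                 cods[bad[1], bad[2]], tree$tip.label[bad[1]], bad[2]))
  }
  key <- apply(states, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  index <- match(key, key[upat])
  if (is.null(pi)) pi <- f3x4_frequencies(alignment, code)
  pi <- normalize_pi(pi, sense)
  E <- nrow(tree$edge)
  if (is.null(fg_edge)) fg_edge <- rep(FALSE, E)
  list(tree = tree, edge = tree$edge, ntip = ape::Ntip(tree),
       patterns = states[, upat, drop = FALSE],
       weights = as.numeric(tabulate(index, sum(upat))),
       site_index = index, nsite = ncol(states),
       fg_edge = fg_edge, pi = pi, code = code)
}

# Memoization for the likelihood hot path. Entries are keyed by parameter
# values; an approximate byte count triggers a wipe (keeping only the
# cheap-to-rebuild kappa-specific generator parts) so long optimizations
# stay within a bounded memory footprint.
cache_account <- function(cache, bytes) {
  tot <- (if (is.null(cache$.bytes)) 0 else cache$.bytes) + bytes
  if (tot > 3e8) {
    keep <- grep("^parts\\|", ls(cache), value = TRUE)
    kept <- mget(keep, envir = cache)
    rm(list = ls(cache), envir = cache)
    for (k in keep) cache[[k]] <- kept[[k]]
    tot <- bytes
  }
  cache$.bytes <- tot
}

cached_parts <- function(cache, kappa, pi, code) {
  pkey <- sprintf("parts|%.15g", kappa)
  parts <- cache[[pkey]]
  if (is.null(parts)) {
    parts <- rate_matrix_parts(kappa, normalize_pi(pi, code$sense_codons), code)
    cache[[pkey]] <- parts
  }
  parts
}

# eigen-system for (kappa, omega); each new omega costs one axpy plus one
# symmetric eigendecomposition. `scale` is the rate normalization divisor;
# NULL self-scales the matrix to mean rate 1 (single-class convention),
# while mixtures pass their shared mixture-average rate.
cached_es <- function(cache, kappa, omega, pi, code, scale = NULL) {
  parts <- cached_parts(cache, kappa, pi, code)
  if (is.null(scale)) scale <- parts$mean_syn + omega * parts$mean_non
  key <- sprintf("%.15g|%.15g|%.15g", kappa, omega, scale)
  es <- cache[[key]]
  if (is.null(es)) {
    Q <- (parts$Qs + omega * parts$Qn) / scale
    es <- eigen_system_cpp(Q, normalize_pi(pi, code$sense_codons))
    es$pi <- pi
    cache_account(cache, 8 * (2 * length(Q) + nrow(Q)))
    cache[[key]] <- es
  }
  es
}

# transition-probability cube (one P(t_e) slice per edge) for (kappa,
# omega) at fixed branch lengths, memoized alongside the eigen systems
cached_pcube <- function(cache, kappa, omega, tvec, tkey, prep, scale = NULL) {
  key <- sprintf("P|%.15g|%.15g|%.15g|%s", kappa, omega,
                 if (is.null(scale)) -1 else scale, tkey)
  cube <- cache[[key]]
  if (is.null(cube)) {
    es <- cached_es(cache, kappa, omega, prep$pi, prep$code, scale)
    cube <- pcube_cpp(es$A, es$C, es$lambda, tvec)
    cache_account(cache, 8 * length(cube))
    cache[[key]] <- cube
  }
  cube
}

# mixture-average substitution rate divisor: one expected substitution per
# codon per unit time averaged over the site classes, so omega > 1 classes
# evolve faster than omega < 1 classes on the same branch
mixture_scale <- function(parts, mixture) {
  parts$mean_syn + sum(mixture$props * mixture$w_bg) * parts$mean_non
}

# Per-pattern per-class log-likelihood for a site-class mixture.
# mixture: list(props, w_bg, w_fg) of equal length K.
pattern_class_loglik <- function(prep, kappa, mixture, tvec, cache = NULL,
                                 scale = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  w_fg <- if (is.null(mixture$w_fg)) mixture$w_bg else mixture$w_fg
  if (is.null(scale))
    scale <- mixture_scale(cached_parts(cache, kappa, prep$pi, prep$code), mixture)
  tkey <- paste(sprintf("%.15g", tvec), collapse = ",")
  any_fg <- any(prep$fg_edge)
  cubes <- lapply(seq_along(mixture$props), function(k) {
    cube <- cached_pcube(cache, kappa, mixture$w_bg[k], tvec, tkey, prep, scale)
    if (any_fg && w_fg[k] != mixture$w_bg[k]) {
      fgc <- cached_pcube(cache, kappa, w_fg[k], tvec, tkey, prep, scale)
      cube[, , prep$fg_edge] <- fgc[, , prep$fg_edge]
    }
    cube
  })
  prune_loglik_cubes_cpp(prep$edge, prep$ntip, prep$patterns, cubes, prep$pi)
}

# total lnL of the mixture from a pattern x class log-likelihood matrix
mixture_total_loglik <- function(ll, props, weights) {
  lp <- log(props)
  M <- sweep(ll, 2, lp, "+")
  m <- apply(M, 1, max)
  site <- m + log(rowSums(exp(M - m)))
  site[!is.finite(m)] <- -Inf
  sum(weights * site)
}

#' Site-wise log-likelihoods under a codon site-class mixture
#'
#' Computes, by Felsenstein pruning over the tree, the log-likelihood of
#' every codon site under every site class of a model, and the total
#' mixture log-likelihood. For branch-site models the foreground omega of
#' each class applies on the labelled branch and the background omega
#' elsewhere.
#'
#' @param tree A `phylo` (branch lengths required) or a `labelled_topology`
#'   for branch/branch-site models.
#' @param alignment A cleaned [codon_alignment()].
#' @param model Model name: `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`,
#'   `"branch-null"`, `"branch-alt"`, `"branch-site-null"`,
#'   `"branch-site-alt"`.
#' @param params Named list of model parameters (`kappa` plus the
#'   model-specific parameters, see [fit_model()]).
#' @param pi Codon frequencies (default: F3x4 from the alignment).
#' @param code A [genetic_code()].
#' @return List with `per_site` (site x class matrix of log-likelihoods),
#'   `proportions`, `omega_background`, `omega_foreground` and `lnL`.
#' @export
site_likelihoods <- function(tree, alignment, model, params, pi = NULL,
                             code = genetic_code()) {
  fg_edge <- NULL
  if (inherits(tree, "labelled_topology")) {
    fg_edge <- seq_len(nrow(tree$tree$edge)) == tree$foreground_edge
    tree <- tree$tree
  }
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths (fit a model or supply them)")
  prep <- prepare_likelihood_data(tree, alignment, code, fg_edge, pi)
  mix <- model_mixture(model, params)
  ll <- pattern_class_loglik(prep, params$kappa, mix, tree$edge.length)
  per_site <- ll[prep$site_index, , drop = FALSE]
  total <- mixture_total_loglik(ll, mix$props, prep$weights)
  if (!is.finite(total))
    stop("zero-probability site under all classes: data and model are inconsistent")
  list(per_site = per_site, proportions = mix$props,
       omega_background = mix$w_bg,
       omega_foreground = if (is.null(mix$w_fg)) mix$w_bg else mix$w_fg,
       lnL = total)
}

# md5 fingerprint of an R object (used to tie fits to their inputs and to
# derive reproducible optimizer seeds)
object_md5 <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

seed_from_fingerprint <- function(fp) {
  strtoi(substr(fp, 1, 7), 16L) %% 2147483646L + 1L
}

# run an expression with a locally-seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
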