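# Site-class mixture definitions and maximum-likelihood fitting for all
# model families: one shared box-constrained optimizer over (kappa, model
# parameters, branch lengths).

MODEL_NAMES <- c("M0", "M1a", "M2a", "M7", "M8",
                 "branch-null", "branch-alt",
                 "branch-site-null", "branch-site-alt")

NEEDS_TOPOLOGY <- c("branch-null", "branch-alt",
                    "branch-site-null", "branch-site-alt")

# Mixture structure (proportions + background/foreground omega per class)
# for a model at given parameter values.
#   M0:   omega
#   M1a:  p0, omega0            (class 1: omega0 < 1; class 2: omega = 1)
#   M2a:  f1, f2, omega0, omega2  (stick-breaking props; extra class >= 1)
#   M7:   p, q                  (beta(p,q) in K = ncat equal classes)
#   M8:   p, q, p0, omega_s     (beta with weight p0 plus omega_s >= 1)
#   branch-*:       omega_bg (+ omega_fg for the alternative)
#   branch-site-*:  f1, f2, omega0 (+ omega2 for the alternative)
model_mixture <- function(model, params, ncat = 10L) {
  p <- params
  switch(model,
    "M0" = list(props = 1, w_bg = p$omega),
    "M1a" = list(props = c(p$p0, 1 - p$p0), w_bg = c(p$omega0, 1)),
    "M2a" = {
      p0 <- p$f1; p1 <- (1 - p$f1) * p$f2; p2 <- (1 - p$f1) * (1 - p$f2)
      list(props = c(p0, p1, p2), w_bg = c(p$omega0, 1, p$omega2))
    },
    "M7" = {
      d <- discretize_beta(p$p, p$q, ncat)
      list(props = d$proportion, w_bg = d$omega)
    },
    "M8" = {
      d <- discretize_beta(p$p, p$q, ncat)
      list(props = c(p$p0 * d$proportion, 1 - p$p0),
           w_bg = c(d$omega, p$omega_s))
    },
    "branch-null" = list(props = 1, w_bg = p$omega_bg, w_fg = 1),
    "branch-alt"  = list(props = 1, w_bg = p$omega_bg, w_fg = p$omega_fg),
    "branch-site-null" = branch_site_mixture(p$f1, p$f2, p$omega0, 1),
    "branch-site-alt"  = branch_site_mixture(p$f1, p$f2, p$omega0, p$omega2),
    stop("unknown model: ", model))
}

# The four-class branch-site grid: classes 0 and 1 behave identically on
# all branches (omega0 < 1 and 1); classes 2a/2b take omega2 on the
# foreground branch while keeping omega0 / 1 in the background. The 2a/2b
# split inherits the 0/1 ratio: p2a/p2b = p0/p1.
branch_site_mixture <- function(f1, f2, omega0, omega2) {
  p0 <- f1; p1 <- (1 - f1) * f2; rest <- (1 - f1) * (1 - f2)
  denom <- p0 + p1
  if (denom <= 0) { p0 <- 1e-12; p1 <- 1e-12; denom <- p0 + p1 }
  list(props = c(p0, p1, rest * p0 / denom, rest * p1 / denom),
       w_bg = c(omega0, 1, omega0, 1),
       w_fg = c(omega0, 1, omega2, omega2))
}

# free-parameter table per model: names, box bounds, default starts
model_parinfo <- function(model, options) {
  w0s <- min(max(options$omega_init, 0.02), 0.9)
  wfree <- max(options$omega_init, 1e-4)
  ws <- max(options$omega_init, 1.5)
  tab <- switch(model,
    "M0" = list(names = "omega", lower = 1e-6, upper = 999, start = wfree),
    "M1a" = list(names = c("p0", "omega0"),
                 lower = c(0, 1e-6), upper = c(1, 1 - 1e-6),
                 start = c(0.7, w0s)),
    "M2a" = list(names = c("f1", "f2", "omega0", "omega2"),
                 lower = c(0, 0, 1e-6, 1), upper = c(1, 1, 1 - 1e-6, 999),
                 start = c(0.6, 0.8, w0s, ws)),
    "M7" = list(names = c("p", "q"),
                lower = c(0.005, 0.005), upper = c(99, 99),
                start = c(0.5, 1.5)),
    "M8" = list(names = c("p", "q", "p0", "omega_s"),
                lower = c(0.005, 0.005, 0, 1), upper = c(99, 99, 1, 999),
                start = c(0.5, 1.5, 0.9, ws)),
    "branch-null" = list(names = "omega_bg", lower = 1e-6, upper = 999, start = wfree),
    "branch-alt" = list(names = c("omega_bg", "omega_fg"),
                        lower = rep(1e-6, 2), upper = rep(999, 2),
                        start = c(wfree, 1)),
    "branch-site-null" = list(names = c("f1", "f2", "omega0"),
                              lower = c(0, 0, 1e-6), upper = c(1, 1, 1 - 1e-6),
                              start = c(0.6, 0.8, w0s)),
    "branch-site-alt" = list(names = c("f1", "f2", "omega0", "omega2"),
                             lower = c(0, 0, 1e-6, 1), upper = c(1, 1, 1 - 1e-6, 999),
                             start = c(0.6, 0.8, w0s, 1.5)),
    stop("unknown model: ", model))
  tab
}

# embed a fitted null model's MLEs as a start point of its alternative,
# chosen so the alternative likelihood at the start equals the null optimum
embed_null_start <- function(model, null_fit) {
  nm <- null_fit$model
  mp <- null_fit$mle$model_pars
  switch(paste(nm, model, sep = "->"),
    "M1a->M2a" = c(f1 = unname(mp["p0"]), f2 = 1,
                   omega0 = unname(mp["omega0"]), omega2 = 1),
    "M7->M8" = c(p = unname(mp["p"]), q = unname(mp["q"]), p0 = 1, omega_s = 1.5),
    "branch-null->branch-alt" = c(omega_bg = unname(mp["omega_bg"]), omega_fg = 1),
    "branch-site-null->branch-site-alt" =
      c(f1 = unname(mp["f1"]), f2 = unname(mp["f2"]),
        omega0 = unname(mp["omega0"]), omega2 = 1),
    NULL)
}

#' Fitting options
#'
#' Collects the tunable knobs of [fit_model()]. Defaults mirror the common
#' conventions of codon-model software: initial omega 1, F3x4 codon
#' frequencies, 10 beta categories, kappa in [0.01, 100], omega in
#' [1e-6, 999], branch lengths in [0, 50] re-estimated under every model,
#' and a convergence tolerance tied to a parameter-improvement threshold of
#' 5e-7.
#'
#' @param kappa_init,omega_init Initial values for kappa and omega.
#' @param ncat_beta Number of discrete beta categories for M7/M8.
#' @param restarts Number of jittered optimizer restarts after the primary
#'   start (default 3).
#' @param fix_branch_lengths If `TRUE`, branch lengths are frozen at the
#'   values on the supplied tree instead of re-optimized (used by the
#'   two-stage FEL procedure, or to reuse an M0 estimate for speed).
#' @param pi Codon frequencies to use; `NULL` means F3x4 from the data.
#' @param seed Integer seed for the restart jitter; `NULL` derives one from
#'   the input fingerprint so results are reproducible without bookkeeping.
#' @param max_iter Iteration cap per optimizer run.
#' @param tol Parameter-change convergence tolerance passed to the optimizer.
#' @param rel_tol Relative log-likelihood convergence tolerance.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(kappa_init = 2, omega_init = 1, ncat_beta = 10L,
                        restarts = 3L, fix_branch_lengths = FALSE,
                        pi = NULL, seed = NULL, max_iter = 500L,
                        tol = 5e-7, rel_tol = 1e-10) {
  structure(list(kappa_init = kappa_init, omega_init = omega_init,
                 ncat_beta = as.integer(ncat_beta), restarts = as.integer(restarts),
                 fix_branch_lengths = fix_branch_lengths, pi = pi,
                 seed = seed, max_iter = as.integer(max_iter), tol = tol,
                 rel_tol = rel_tol),
            class = "fit_options")
}

#' Maximum-likelihood fit of a codon selection model
#'
#' Fits one of the implemented codon substitution models to a cleaned
#' alignment and tree by bounded quasi-Newton optimization of the pruning
#' likelihood over kappa, the model's omega/mixture parameters and (by
#' default) all branch lengths. Site models: `M0` (single omega), `M1a`
#' (nearly neutral), `M2a` (positive selection), `M7` (beta), `M8`
#' (beta plus omega > 1 class). Branch models (`branch-null`/`branch-alt`)
#' and branch-site models (`branch-site-null`/`branch-site-alt`) require a
#' `labelled_topology` marking the foreground branch; the null fixes the
#' foreground omega (branch model) or omega2 (branch-site) at 1.
#'
#' Nested alternatives can be warm-started at their null's optimum via
#' `warm_from`, which guarantees `lnL(alt) >= lnL(null)`.
#'
#' @param tree A `phylo` or [parse_newick()] result (site models) or a
#'   `labelled_topology` from [enumerate_foreground_topologies()].
#' @param alignment A cleaned [codon_alignment()].
#' @param model Model name (see above).
#' @param options A [fit_options()] list.
#' @param warm_from Optional `model_fit` of the nested null model.
#' @param code A [genetic_code()].
#' @return An object of class `model_fit`: list with `model`, `lnL`, `mle`
#'   (list `kappa`, `model_pars`, `branch_lengths`), `npar`,
#'   `per_site_class_loglik` (site x class matrix), `proportions`,
#'   `omega_background`, `omega_foreground`, `tree` (with estimated branch
#'   lengths), `pi`, `foreground`, `convergence` and `fingerprint`.
#' @export
fit_model <- function(tree, alignment, model, options = fit_options(),
                      warm_from = NULL, code = genetic_code()) {
  model <- match.arg(model, MODEL_NAMES)
  fg_edge <- NULL
  foreground <- NULL
  if (inherits(tree, "labelled_topology")) {
    fg_edge <- seq_len(nrow(tree$tree$edge)) == tree$foreground_edge
    foreground <- tree$foreground
    tree <- tree$tree
  } else {
    tree <- as_phylo(tree)
    if (model %in% NEEDS_TOPOLOGY)
      stop("model '", model, "' needs a labelled_topology marking the foreground branch")
    tree <- unroot_keep_order(tree)
  }
  prep <- prepare_likelihood_data(tree, alignment, code, fg_edge, options$pi)
  E <- nrow(prep$edge)

  pinfo <- model_parinfo(model, options)
  bl0 <- if (!is.null(tree$edge.length)) pmin(pmax(tree$edge.length, 1e-4), 50)
         else rep(0.1, E)
  free_bl <- !options$fix_branch_lengths
  if (!free_bl && is.null(tree$edge.length))
    stop("fix_branch_lengths = TRUE requires branch lengths on the tree")

  start <- c(kappa = options$kappa_init, pinfo$start)
  names(start) <- c("kappa", pinfo$names)
  alt_start <- NULL
  if (!is.null(warm_from)) {
    emb <- embed_null_start(model, warm_from)
    if (!is.null(emb)) {
      # primary start: the null optimum embedded in the alternative (exact
      # nesting from the first evaluation); secondary: a generic interior
      # start, which rescues fits the boundary start leaves stuck
      alt_start <- start
      alt_start[1] <- unname(warm_from$mle$kappa)
      start <- c(kappa = unname(warm_from$mle$kappa), emb)
      bl0 <- if (free_bl) warm_from$mle$branch_lengths else bl0
    }
  }
  lower <- c(0.01, pinfo$lower)
  upper <- c(100, pinfo$upper)
  if (free_bl) {
    start <- c(start, bl0)
    lower <- c(lower, rep(0, E))
    upper <- c(upper, rep(50, E))
  }
  npp <- 1L + length(pinfo$names)  # kappa + model parameters

  cache <- new.env(parent = emptyenv())
  decode <- function(par) {
    mp <- as.list(par[2:npp])
    names(mp) <- pinfo$names
    list(kappa = par[1], mp = mp,
         tvec = if (free_bl) par[(npp + 1):length(par)] else bl0)
  }
  kparts <- function(kappa) {
    pkey <- sprintf("parts|%.15g", kappa)
    parts <- cache[[pkey]]
    if (is.null(parts)) {
      parts <- rate_matrix_parts(kappa, prep$pi, code)
      cache[[pkey]] <- parts
    }
    parts
  }
  eval_ll <- function(par, want_matrix = FALSE) {
    d <- decode(par)
    mix <- model_mixture(model, d$mp, options$ncat_beta)
    w_fg <- if (is.null(mix$w_fg)) mix$w_bg else mix$w_fg
    parts <- kparts(d$kappa)
    tryCatch(
      mixture_loglik_cpp(prep$edge, prep$ntip, prep$patterns, prep$weights,
                         parts$Qs, parts$Qn, parts$mean_syn, parts$mean_non,
                         mix$w_bg, w_fg, mix$props, prep$fg_edge, d$tvec,
                         prep$pi, want_matrix),
      error = function(e) NULL)
  }
  negll <- function(par) {
    res <- eval_ll(par)
    if (is.null(res) || !is.finite(res$lnL)) return(1e10)
    -res$lnL
  }

  fp_data <- object_md5(list(alignment$codons, alignment$taxa,
                             ape::write.tree(tree), foreground))
  fp <- object_md5(list(fp_data, model))
  seed <- if (is.null(options$seed)) seed_from_fingerprint(fp) else options$seed

  starts <- list(start)
  if (!is.null(alt_start))
    starts <- c(starts, list(c(alt_start, if (free_bl) bl0)))
  if (options$restarts > 0L) {
    jit <- with_local_seed(seed, lapply(seq_len(options$restarts), function(i) {
      s <- start * exp(stats::runif(length(start), -0.5, 0.5))
      pmin(pmax(s, lower + 1e-9 * (upper - lower)), upper - 1e-9 * (upper - lower))
    }))
    starts <- c(starts, jit)
  }

  best <- NULL
  conv <- NA_integer_
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, negll, lower = lower, upper = upper,
                    control = list(iter.max = options$max_iter,
                                   eval.max = 4L * options$max_iter,
                                   rel.tol = options$rel_tol,
                                   x.tol = options$tol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    better <- is.null(best) ||
      fit$objective < best$objective - 1e-9 ||
      (abs(fit$objective - best$objective) <= 1e-9 &&
         isTRUE(vector_less(fit$par, best$par)))
    if (better) { best <- fit; conv <- fit$convergence }
  }
  if (is.null(best))
    stop("optimization failed for model '", model, "' after all restarts")
  if (best$objective >= 1e10)
    warning("model '", model, "' did not reach a finite likelihood")

  d <- decode(best$par)
  mix <- model_mixture(model, d$mp, options$ncat_beta)
  final <- eval_ll(best$par, want_matrix = TRUE)
  if (is.null(final)) stop("likelihood evaluation failed at the optimum")
  ll <- final$ll
  lnL <- final$lnL
  fitted_tree <- prep$tree
  fitted_tree$edge.length <- d$tvec
  structure(list(
    model = model,
    lnL = lnL,
    mle = list(kappa = unname(d$kappa),
               model_pars = unlist(d$mp),
               branch_lengths = unname(d$tvec)),
    npar = npp + if (free_bl) E else 0L,
    per_site_class_loglik = ll[prep$site_index, , drop = FALSE],
    proportions = mix$props,
    omega_background = mix$w_bg,
    omega_foreground = if (is.null(mix$w_fg)) mix$w_bg else mix$w_fg,
    tree = fitted_tree,
    pi = prep$pi,
    foreground = foreground,
    ncat_beta = options$ncat_beta,
    alignment = alignment,
    code = code,
    reference_codons = alignment$codons[1, ],
    convergence = conv,
    fingerprint = fp,
    data_fingerprint = fp_data),
    class = "model_fit")
}

vector_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)
  if (!length(i)) FALSE else d[i[1]] < 0
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model %s: lnL = %.4f (%d free parameters)\n", x$model, x$lnL, x$npar))
  cat("  kappa =", format(x$mle$kappa, digits = 4), "\n")
  if (length(x$mle$model_pars))
    cat("  ", paste(names(x$mle$model_pars),
                    format(x$mle$model_pars, digits = 4), sep = " = ",
                    collapse = ", "), "\n")
  if (!is.null(x$foreground)) cat("  foreground:", x$foreground, "\n")
  invisible(x)
}

#' @export
logLik.model_fit <- function(object, ...) {
  structure(object$lnL, df = object$npar, class = "logLik")
}

#' Fit a nested null/alternative model pair
#'
#' Convenience wrapper fitting a null model and then its alternative
#' warm-started at the null optimum, which enforces
#' `lnL(alt) >= lnL(null)`.
#'
#' @param tree Tree or `labelled_topology` as in [fit_model()].
#' @param alignment A cleaned [codon_alignment()].
#' @param pair One of `"M1a/M2a"`, `"M7/M8"`, `"branch"`, `"branch-site"`.
#' @param options A [fit_options()].
#' @param code A [genetic_code()].
#' @return List with elements `null` and `alt` (both `model_fit`).
#' @export
fit_model_pair <- function(tree, alignment, pair = c("M1a/M2a", "M7/M8", "branch", "branch-site"),
                           options = fit_options(), code = genetic_code()) {
  pair <- match.arg(pair)
  nm <- switch(pair,
               "M1a/M2a" = c("M1a", "M2a"),
               "M7/M8" = c("M7", "M8"),
               "branch" = c("branch-null", "branch-alt"),
               "branch-site" = c("branch-site-null", "branch-site-alt"))
  null <- fit_model(tree, alignment, nm[1], options = options, code = code)
  alt <- fit_model(tree, alignment, nm[2], options = options,
                   warm_from = null, code = code)
  list(null = null, alt = alt)
}
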