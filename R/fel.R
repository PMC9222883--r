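# Fixed-effects likelihood (FEL) per-site scan: a two-stage procedure that
# freezes a global baseline (kappa, branch lengths, codon frequencies from
# an M0 fit) and then, site by site, maximizes the likelihood over a
# synonymous rate alpha and a nonsynonymous rate beta, testing alpha = beta
# by a df-1 LRT. Unlike the site-class mixtures this detects negative
# (beta < alpha) as well as positive (beta > alpha) selection.

#' Fit the global FEL baseline
#'
#' Stage one of the FEL scan: an M0 fit whose kappa, branch lengths and
#' codon frequencies are held fixed during the per-site stage.
#'
#' @param tree A `phylo` (or [parse_newick()] result).
#' @param alignment A cleaned [codon_alignment()].
#' @param options A [fit_options()].
#' @param code A [genetic_code()].
#' @return A `fel_baseline` object: the M0 `model_fit` plus the site-rate
#'   decomposition of the rate matrix used by the site stage.
#' @export
fit_global_baseline <- function(tree, alignment, options = fit_options(),
                                code = genetic_code()) {
  fit <- fit_model(tree, alignment, "M0", options = options, code = code)
  structure(list(fit = fit, code = code), class = "fel_baseline")
}

# Synonymous / nonsynonymous parts of the rate matrix at the baseline's
# kappa and pi, scaled like the baseline M0 matrix so (alpha, beta) are on
# the same scale as the baseline branch lengths: Q(a, b) = a*Qs + b*Qn with
# Q(1, omega_hat) equal to the baseline generator.
fel_rate_parts <- function(baseline) {
  fit <- baseline$fit
  parts <- rate_matrix_parts(fit$mle$kappa, fit$pi, baseline$code)
  omega0 <- unname(fit$mle$model_pars["omega"])
  scale <- parts$mean_syn + omega0 * parts$mean_non
  list(Qs = parts$Qs / scale, Qn = parts$Qn / scale, pi = fit$pi, omega0 = omega0)
}

fel_site_loglik <- function(parts, prep, alpha, beta, tvec, cache) {
  key <- sprintf("%.15g|%.15g", alpha, beta)
  cube <- cache[[key]]
  if (is.null(cube)) {
    Q <- alpha * parts$Qs + beta * parts$Qn
    es <- eigen_system_cpp(Q, parts$pi)
    cube <- pcube_cpp(es$A, es$C, es$lambda, tvec)
    cache_account(cache, 8 * length(cube))
    cache[[key]] <- cube
  }
  ll <- prune_loglik_cubes_cpp(prep$edge, prep$ntip, prep$patterns,
                               list(cube), parts$pi)
  ll[, 1]
}

#' Per-site FEL test
#'
#' Stage two for one codon column: maximize the likelihood over
#' `(alpha, beta)` (bounded to [0, 100]) with branch lengths and kappa
#' frozen at the baseline, refit under the constraint `alpha = beta`, and
#' compare by a chi-squared LRT with 1 degree of freedom. The direction is
#' the sign of `beta - alpha` when the test is significant at `s`.
#'
#' @param site_column Codon index into the alignment the baseline was fit
#'   to, or a 1-column codon matrix with the alignment's taxa.
#' @param baseline A [fit_global_baseline()] result.
#' @param s Significance level (default 0.05).
#' @return A one-row data frame (`fel_site_result`): `codon_index`,
#'   `alpha`, `beta`, `lnL_free`, `lnL_constrained`, `statistic`,
#'   `p_value`, `direction`.
#' @export
fel_site_test <- function(site_column, baseline, s = 0.05) {
  stopifnot(inherits(baseline, "fel_baseline"))
  fit <- baseline$fit
  if (is.numeric(site_column) && length(site_column) == 1L) {
    idx <- as.integer(site_column)
    aln <- codon_alignment(fit$alignment$codons[, idx, drop = FALSE],
                           fit$alignment$taxa)
  } else {
    idx <- NA_integer_
    aln <- codon_alignment(site_column, rownames(site_column))
  }
  res <- fel_site_core(aln, baseline, s)
  res$codon_index <- idx
  res[, c("codon_index", setdiff(names(res), "codon_index"))]
}

fel_site_core <- function(aln1, baseline, s, prep = NULL, cache = NULL) {
  fit <- baseline$fit
  parts <- fel_rate_parts(baseline)
  if (is.null(prep))
    prep <- prepare_likelihood_data(fit$tree, aln1, baseline$code, pi = fit$pi)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  tvec <- fit$tree$edge.length
  w <- prep$weights  # single site: weight 1

  nll_free <- function(par) {
    ll <- fel_site_loglik(parts, prep, par[1], par[2], tvec, cache)
    v <- -sum(w * ll)
    if (!is.finite(v)) 1e10 else v
  }
  nll_con <- function(par) nll_free(c(par, par))

  st <- c(1, parts$omega0)
  free <- stats::nlminb(st, nll_free, lower = c(0, 0), upper = c(100, 100),
                        control = list(rel.tol = 1e-10))
  free2 <- stats::nlminb(c(1, 1), nll_free, lower = c(0, 0), upper = c(100, 100),
                         control = list(rel.tol = 1e-10))
  if (free2$objective < free$objective) free <- free2
  con <- stats::nlminb(mean(free$par), nll_con, lower = 0, upper = 100,
                       control = list(rel.tol = 1e-10))
  con2 <- stats::nlminb(1, nll_con, lower = 0, upper = 100,
                        control = list(rel.tol = 1e-10))
  if (con2$objective < con$objective) con <- con2

  lnL_free <- -free$objective
  lnL_con <- -con$objective
  if (lnL_free < lnL_con) {  # free fit can only improve; polish from the null
    free3 <- stats::nlminb(rep(con$par, 2), nll_free, lower = c(0, 0),
                           upper = c(100, 100),
                           control = list(rel.tol = 1e-10))
    if (-free3$objective >= lnL_free) { free <- free3; lnL_free <- -free3$objective }
    lnL_free <- max(lnL_free, lnL_con)
  }
  stat <- max(0, 2 * (lnL_free - lnL_con))
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  alpha <- free$par[1]; beta <- free$par[2]
  direction <- if (p <= s && beta > alpha) "positive"
               else if (p <= s && beta < alpha) "negative"
               else "none"
  data.frame(alpha = alpha, beta = beta,
             lnL_free = lnL_free, lnL_constrained = lnL_con,
             statistic = stat, p_value = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' FEL scan over all codons
#'
#' Runs the per-site FEL test on every codon column of the alignment,
#' fitting the global baseline first if one is not supplied.
#'
#' @param tree A `phylo` with or without branch lengths.
#' @param alignment A cleaned [codon_alignment()].
#' @param s Significance level for direction calls (default 0.05).
#' @param baseline Optional precomputed [fit_global_baseline()].
#' @param options [fit_options()] for the baseline fit.
#' @param code A [genetic_code()].
#' @return A data frame of class `fel_scan_result`, one row per codon, with
#'   the columns of [fel_site_test()]; attributes `n_positive`,
#'   `n_negative` count significant sites and `baseline` stores the stage-
#'   one fit.
#' @export
fel_scan <- function(tree, alignment, s = 0.05, baseline = NULL,
                     options = fit_options(), code = genetic_code()) {
  if (is.null(baseline))
    baseline <- fit_global_baseline(tree, alignment, options = options, code = code)
  fit <- baseline$fit
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(ncol(alignment$codons)), function(j) {
    aln1 <- codon_alignment(alignment$codons[, j, drop = FALSE], alignment$taxa)
    prep <- prepare_likelihood_data(fit$tree, aln1, code, pi = fit$pi)
    r <- fel_site_core(aln1, baseline, s, prep = prep, cache = cache)
    r$codon_index <- j
    r
  })
  out <- do.call(rbind, rows)
  out <- out[, c("codon_index", "alpha", "beta", "lnL_free", "lnL_constrained",
                 "statistic", "p_value", "direction")]
  attr(out, "n_positive") <- sum(out$direction == "positive")
  attr(out, "n_negative") <- sum(out$direction == "negative")
  attr(out, "baseline") <- baseline
  attr(out, "s") <- s
  class(out) <- c("fel_scan_result", "data.frame")
  out
}

#' @export
print.fel_scan_result <- function(x, ...) {
  cat(sprintf("FEL scan: %d codons, %d positively and %d negatively selected (p <= %g)\n",
              nrow(x), attr(x, "n_positive"), attr(x, "n_negative"), attr(x, "s")))
  NextMethod()
}
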