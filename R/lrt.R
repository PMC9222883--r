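# Likelihood-ratio tests between nested codon models and empirical-Bayes
# identification of positively selected sites.

#' Likelihood-ratio test with chi-squared p-value
#'
#' Computes `2 * (lnL_alt - lnL_null)`, clamped at zero (a negative
#' difference can only arise from optimizer noise in nested models and is
#' reported as statistic 0 with a warning), and the upper-tail chi-squared
#' probability with the given degrees of freedom.
#'
#' @param lnL_null,lnL_alt Maximized log-likelihoods of the nested pair.
#' @param df Degrees of freedom (difference in free parameters, >= 1).
#' @return Object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`, `lnL_null`, `lnL_alt`.
#' @export
lrt_pvalue <- function(lnL_null, lnL_alt, df) {
  if (!is.finite(lnL_null) || !is.finite(lnL_alt)) stop("log-likelihoods must be finite")
  if (df < 1) stop("'df' must be >= 1")
  delta <- 2 * (lnL_alt - lnL_null)
  if (delta < -1e-6)
    warning(sprintf("lnL(alt) < lnL(null) by %.3g: statistic clamped to 0 (optimizer noise)",
                    -delta / 2))
  stat <- max(0, delta)
  structure(list(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 lnL_null = lnL_null, lnL_alt = lnL_alt),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (!is.null(x$pair)) paste0("  [", x$pair, "]") else ""))
  invisible(x)
}

# degrees of freedom of the standard comparisons
comparison_df <- c("M1a/M2a" = 2L, "M7/M8" = 2L, "branch" = 1L, "branch-site" = 1L)

#' Compare a nested model pair by LRT
#'
#' Runs the likelihood-ratio test for one of the standard comparisons with
#' its conventional degrees of freedom: `M1a/M2a` (df 2), `M7/M8` (df 2),
#' `branch` (foreground omega fixed at 1 vs free, df 1) and `branch-site`
#' (omega2 fixed at 1 vs free, df 1; the null places omega2 on its
#' boundary, so the chi-squared reference is the conventional, slightly
#' conservative choice). Both fits must come from the same alignment, tree
#' and foreground branch.
#'
#' @param pair Comparison name (above).
#' @param fits List with elements `null` and `alt` (from
#'   [fit_model_pair()]), or the null fit when `alt` is given separately.
#' @param alt Optional alternative `model_fit`.
#' @return An `lrt_result` with the fits attached (`null_fit`, `alt_fit`,
#'   `pair`, `foreground`).
#' @export
model_comparison <- function(pair, fits, alt = NULL) {
  pair <- match.arg(pair, names(comparison_df))
  if (!is.null(alt)) fits <- list(null = fits, alt = alt)
  null <- fits$null; altf <- fits$alt
  stopifnot(inherits(null, "model_fit"), inherits(altf, "model_fit"))
  expected <- switch(pair,
                     "M1a/M2a" = c("M1a", "M2a"),
                     "M7/M8" = c("M7", "M8"),
                     "branch" = c("branch-null", "branch-alt"),
                     "branch-site" = c("branch-site-null", "branch-site-alt"))
  if (!identical(c(null$model, altf$model), expected))
    stop("fits do not match comparison '", pair, "': got ",
         null$model, " vs ", altf$model)
  if (!identical(null$data_fingerprint, altf$data_fingerprint))
    stop("null and alternative fits were computed on different data")
  res <- lrt_pvalue(null$lnL, altf$lnL, comparison_df[[pair]])
  res$pair <- pair
  res$foreground <- altf$foreground
  res$null_fit <- null
  res$alt_fit <- altf
  res
}

#' Empirical-Bayes posteriors for positively selected sites
#'
#' Identifies the sites driving a significant positive-selection LRT.
#' `NEB` (naive empirical Bayes) computes the posterior probability that
#' each codon belongs to a class with omega > 1, plugging in the MLEs.
#' `BEB` (Bayes empirical Bayes) additionally averages over uncertainty in
#' the mixture parameters on a uniform 10-point grid per parameter
#' (proportions on their simplex; omega0 on (0,1); the positive-selection
#' omega on (1,11); for M8, beta shape parameters on (0,2)), weighting grid
#' points by their marginal likelihood. BEB is available for M2a and M8.
#'
#' Following standard practice, site lists are only meaningful when the
#' companion LRT is significant: if `lrt` is supplied and not significant
#' at `s`, an empty record set is returned.
#'
#' @param fit A `model_fit` of M2a, M8 or branch-site-alt.
#' @param method `"NEB"` or `"BEB"`.
#' @param lrt Optional `lrt_result` of the companion comparison.
#' @param s Significance level (default 0.05); a site is flagged when its
#'   posterior is >= 1 - s.
#' @return A data frame of site records: `codon_index` (1-based, cleaned
#'   alignment), `reference_codon`, `test`, `method`, `posterior`,
#'   `direction` (`"positive"`), `significant`. Zero rows when the fit has
#'   no omega > 1 class or the LRT is not significant.
#' @export
site_posteriors <- function(fit, method = c("NEB", "BEB"), lrt = NULL, s = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "model_fit"))
  if (!fit$model %in% c("M2a", "M8", "branch-site-alt"))
    stop("site posteriors are defined for M2a, M8 and branch-site-alt fits, not ", fit$model)
  empty <- data.frame(codon_index = integer(), reference_codon = character(),
                      test = character(), method = character(),
                      posterior = numeric(), direction = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!is.null(lrt) && lrt$p_value > s) return(empty)
  pos_class <- which(fit$omega_foreground > 1)
  if (!length(pos_class)) return(empty)

  if (method == "NEB") {
    post <- class_posteriors(fit$per_site_class_loglik, fit$proportions)
    prob <- rowSums(post[, pos_class, drop = FALSE])
  } else {
    if (!fit$model %in% c("M2a", "M8"))
      stop("BEB is implemented for M2a and M8 fits")
    prob <- beb_positive_posterior(fit)
  }
  ref <- fit$reference_codons
  data.frame(codon_index = seq_along(prob),
             reference_codon = ref,
             test = fit$model, method = method,
             posterior = prob, direction = "positive",
             significant = prob >= 1 - s,
             stringsAsFactors = FALSE)
}

# per-site class posteriors from a log-likelihood matrix and proportions
class_posteriors <- function(ll, props) {
  M <- sweep(ll, 2, log(props), "+")
  m <- apply(M, 1, max)
  W <- exp(M - m)
  W / rowSums(W)
}

# BEB: average the positive-class posterior over a discrete prior grid on
# the mixture parameters, weighting each grid point by its marginal
# likelihood. Grid resolution: 10 points per parameter.
beb_positive_posterior <- function(fit, ngrid = 10L) {
  mid <- (seq_len(ngrid) - 0.5) / ngrid
  # site log-likelihood under a single omega, at the MLE kappa and branch
  # lengths -- recomputed by pruning for each omega needed by the grid
  prep <- prepare_likelihood_data(fit$tree, fit$alignment, fit$code,
                                  fg_edge = NULL, pi = fit$pi)
  cache <- new.env(parent = emptyenv())
  # class likelihoods are evaluated on the time scale of the MLE fit:
  # branch lengths stay in mixture-average substitutions per codon
  mle_scale <- mixture_scale(cached_parts(cache, fit$mle$kappa, prep$pi, fit$code),
                             list(props = fit$proportions,
                                  w_bg = fit$omega_background))
  site_ll <- function(omega) {
    ll <- pattern_class_loglik(prep, fit$mle$kappa,
                               list(props = 1, w_bg = omega),
                               fit$tree$edge.length, cache, scale = mle_scale)
    ll[prep$site_index, , drop = FALSE]
  }
  nsite <- prep$nsite

  if (fit$model == "M2a") {
    w0g <- mid                 # omega0 ~ U(0,1)
    w2g <- 1 + 10 * mid        # omega2 ~ U(1,11)
    L0 <- vapply(w0g, site_ll, numeric(nsite))   # nsite x 10
    L1 <- site_ll(1)[, 1]
    L2 <- vapply(w2g, site_ll, numeric(nsite))
    # proportions on the simplex via stick-breaking midpoints f1, f2 with
    # Jacobian weight (1 - f1) making (p0, p1) uniform on the triangle
    acc_num <- rep(0, nsite); acc_den <- rep(0, nsite); logw <- c()
    combos <- list()
    for (f1 in mid) for (f2 in mid) {
      p0 <- f1; p1 <- (1 - f1) * f2; p2 <- (1 - f1) * (1 - f2)
      for (i0 in seq_len(ngrid)) for (i2 in seq_len(ngrid)) {
        combos[[length(combos) + 1L]] <- c(p0, p1, p2, i0, i2, 1 - f1)
      }
    }
    cm <- do.call(rbind, combos)
    site_mix <- function(row) {
      p0 <- row[1]; p1 <- row[2]; p2 <- row[3]
      cbind(L0[, row[4]] + log(p0), L1 + log(p1), L2[, row[5]] + log(p2))
    }
    lse <- function(M) { m <- apply(M, 1, max); m + log(rowSums(exp(M - m))) }
    logml <- numeric(nrow(cm)); pos_post <- matrix(0, nsite, nrow(cm))
    for (g in seq_len(nrow(cm))) {
      M <- site_mix(cm[g, ])
      sl <- lse(M)
      logml[g] <- sum(sl) + log(cm[g, 6])
      pos_post[, g] <- exp(M[, 3] - sl)
    }
    wts <- exp(logml - max(logml)); wts <- wts / sum(wts)
    return(as.numeric(pos_post %*% wts))
  }

  # M8: p0 ~ U(0,1), beta p, q ~ U(0,2), omega_s ~ U(1,11)
  p0g <- mid
  pg <- 2 * mid
  qg <- 2 * mid
  wsg <- 1 + 10 * mid
  K <- fit$ncat_beta
  Lws <- vapply(wsg, site_ll, numeric(nsite))
  # per (p,q): log of the beta-mixture site likelihood (equal-weight classes)
  Lbeta <- matrix(0, nsite, ngrid * ngrid)
  idx <- 0L
  for (p in pg) for (q in qg) {
    idx <- idx + 1L
    d <- discretize_beta(p, q, K)
    Lc <- vapply(d$omega, site_ll, numeric(nsite))
    m <- apply(Lc, 1, max)
    Lbeta[, idx] <- m + log(rowMeans(exp(Lc - m)))
  }
  logml <- numeric(0); pos_post <- NULL
  G <- length(p0g) * ncol(Lbeta) * length(wsg)
  pos_post <- matrix(0, nsite, G)
  logml <- numeric(G)
  g <- 0L
  for (ip in seq_len(ncol(Lbeta))) for (p0 in p0g) for (iw in seq_along(wsg)) {
    g <- g + 1L
    a <- Lbeta[, ip] + log(p0)
    b <- Lws[, iw] + log(1 - p0)
    m <- pmax(a, b)
    sl <- m + log(exp(a - m) + exp(b - m))
    logml[g] <- sum(sl)
    pos_post[, g] <- exp(b - sl)
  }
  wts <- exp(logml - max(logml)); wts <- wts / sum(wts)
  as.numeric(pos_post %*% wts)
}
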