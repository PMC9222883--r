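# package-level cache for code-dependent structure tables
.omegascan_env <- new.env(parent = emptyenv())

# For a genetic code, precompute which ordered sense-codon pairs differ at a
# single nucleotide position, whether the change is a transition, and
# whether it is synonymous. Returned as index/flag vectors over the 61x61
# grid; memoized per code id.
codon_pair_structure <- function(code = genetic_code()) {
  key <- paste0("pairs_", code$id)
  if (!is.null(.omegascan_env[[key]]) && code$id != "custom")
    return(.omegascan_env[[key]])
  sense <- code$sense_codons
  n <- length(sense)
  m1 <- matrix(substr(sense, 1, 1), n, n)
  m2 <- matrix(substr(sense, 2, 2), n, n)
  m3 <- matrix(substr(sense, 3, 3), n, n)
  d1 <- m1 != t(m1); d2 <- m2 != t(m2); d3 <- m3 != t(m3)
  ndiff <- d1 + d2 + d3
  single <- ndiff == 1L
  # the differing nucleotides of each single-change pair
  from <- matrix("", n, n); to <- matrix("", n, n)
  from[d1 & single] <- t(m1)[d1 & single]; to[d1 & single] <- m1[d1 & single]
  from[d2 & single] <- t(m2)[d2 & single]; to[d2 & single] <- m2[d2 & single]
  from[d3 & single] <- t(m3)[d3 & single]; to[d3 & single] <- m3[d3 & single]
  purine <- c(A = TRUE, G = TRUE, T = FALSE, C = FALSE)
  transition <- matrix(FALSE, n, n)
  transition[single] <- purine[from[single]] == purine[to[single]]
  aa <- code$table[sense]
  synonymous <- matrix(aa, n, n) == matrix(aa, n, n, byrow = TRUE)
  res <- list(single = single, transition = transition, synonymous = synonymous,
              sense = sense)
  if (code$id != "custom") .omegascan_env[[key]] <- res
  res
}

#' Codon substitution rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of the reversible
#' Goldman-Yang-style codon model: substitutions changing more than one
#' nucleotide have rate 0; a single-nucleotide change from codon i to codon
#' j has rate proportional to `pi[j]`, multiplied by `kappa` when the
#' nucleotide change is a transition and by `omega` when the codon change is
#' nonsynonymous. The matrix is scaled so the expected substitution rate at
#' stationarity is 1, making branch lengths expected substitutions per
#' codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi A [codon_frequencies()] vector over the sense codons.
#' @param code A [genetic_code()].
#' @return Object of class `codon_rate_matrix`: list with `Q` (61 x 61,
#'   rows summing to zero), `kappa`, `omega`, `pi` and `scale` (the raw
#'   mean rate divided out).
#' @export
build_rate_matrix <- function(kappa, omega, pi, code = genetic_code()) {
  if (!is.numeric(kappa) || kappa <= 0) stop("'kappa' must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("'omega' must be >= 0")
  st <- codon_pair_structure(code)
  pi <- normalize_pi(pi, st$sense)
  parts <- rate_matrix_parts(kappa, pi, code)
  scale <- parts$mean_syn + omega * parts$mean_non
  if (scale <= 0) stop("degenerate rate matrix: zero mean rate")
  Q <- (parts$Qs + omega * parts$Qn) / scale
  dimnames(Q) <- list(st$sense, st$sense)
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi, scale = scale),
            class = "codon_rate_matrix")
}

# Unscaled synonymous / nonsynonymous generator parts for fixed (kappa, pi):
# Q(omega) = Qs + omega * Qn up to the mean-rate normalization, which is
# itself linear in omega. Lets mixture models build per-class matrices with
# one axpy instead of re-deriving the structure.
rate_matrix_parts <- function(kappa, pi, code = genetic_code()) {
  st <- codon_pair_structure(code)
  n <- length(st$sense)
  fac <- matrix(0, n, n)
  fac[st$single] <- 1
  fac[st$single & st$transition] <- kappa
  base <- fac * matrix(pi, n, n, byrow = TRUE)
  Qs <- base; Qs[!st$synonymous] <- 0
  Qn <- base; Qn[st$synonymous] <- 0
  diag(Qs) <- -rowSums(Qs)
  diag(Qn) <- -rowSums(Qn)
  list(Qs = Qs, Qn = Qn,
       mean_syn = -sum(pi * diag(Qs)), mean_non = -sum(pi * diag(Qn)))
}

# floor tiny/zero frequencies so the reversible symmetrization is defined,
# then renormalize
normalize_pi <- function(pi, sense) {
  if (inherits(pi, "codon_frequencies") || !is.null(names(pi))) {
    if (!setequal(names(pi), sense)) stop("'pi' must be named by the sense codons")
    pi <- as.numeric(pi[sense])
  } else {
    if (length(pi) != length(sense)) stop("'pi' has wrong length")
    pi <- as.numeric(pi)
  }
  if (any(pi < 0)) stop("'pi' must be non-negative")
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

#' @export
print.codon_rate_matrix <- function(x, ...) {
  cat(sprintf("Codon rate matrix: kappa = %.4g, omega = %.4g, %d states, mean rate 1\n",
              x$kappa, x$omega, nrow(x$Q)))
  invisible(x)
}

# eigen-system of a codon_rate_matrix (or of Q with explicit pi)
eigen_system <- function(Q, pi = NULL) {
  if (inherits(Q, "codon_rate_matrix")) {
    pi <- Q$pi
    Q <- Q$Q
  }
  es <- eigen_system_cpp(Q, pi)
  es$pi <- pi
  es
}

#' Transition probability matrix
#'
#' Computes `P(t) = exp(Q t)` for a codon rate matrix via the symmetric
#' eigendecomposition available for reversible models. Rows sum to 1;
#' `P(0)` is the identity.
#'
#' @param Q A [build_rate_matrix()] result.
#' @param t Branch length (expected substitutions per codon, >= 0).
#' @return A stochastic matrix with the dimnames of `Q$Q`.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(inherits(Q, "codon_rate_matrix"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop("'t' must be a single value >= 0")
  es <- eigen_system(Q)
  P <- pmat_cpp(es$A, es$C, es$lambda, t)
  dimnames(P) <- dimnames(Q$Q)
  P
}

#' Discretize a beta distribution of omega into equal-probability classes
#'
#' The beta site models (M7, M8) represent among-site variation in omega on
#' (0, 1) by a beta(p, q) density, discretized into K classes of equal
#' probability 1/K whose omega value is the mean of the density within each
#' quantile bin (computed in closed form from incomplete-beta identities).
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of categories (default 10, the conventional choice).
#' @return List with `omega` (K category means, increasing) and
#'   `proportion` (rep(1/K, K)).
#' @export
discretize_beta <- function(p, q, K = 10L) {
  if (p <= 0 || q <= 0) stop("beta parameters must be > 0")
  if (K < 1L) stop("'K' must be >= 1")
  br <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = K + 1L), p, q))
  # mean of beta(p,q) restricted to (a,b): (p/(p+q)) * dIb(p+1,q) / dIb(p,q)
  num <- diff(stats::pbeta(br, p + 1, q))
  den <- diff(stats::pbeta(br, p, q))
  m <- ifelse(den > 0, (p / (p + q)) * num / den, (br[-(K + 1)] + br[-1]) / 2)
  list(omega = pmin(pmax(m, 1e-9), 1 - 1e-9), proportion = rep(1 / K, K))
}
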