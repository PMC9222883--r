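// Likelihood core: eigen-system of a reversible codon rate matrix,
// transition matrices P(t) = exp(Qt), and Felsenstein pruning over site
// patterns for a mixture of site classes (with optional foreground /
// background rate matrices per class, as used by branch-site models).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Eigen-system of a reversible Q via symmetrization:
//   B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric;  B = U L U'
//   P(t) = diag(1/sqrt(pi)) U exp(L t) U' diag(sqrt(pi)) = A exp(L t) C
static void reversible_eigen(const arma::mat& Q, const arma::vec& pi,
                             arma::mat& A, arma::mat& C, arma::vec& lam) {
  arma::vec s = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= s;        // diag(s) * Q
  S.each_row() /= s.t();    // ... * diag(1/s)
  S = 0.5 * (S + S.t());    // symmetrize against round-off
  arma::mat U;
  if (!arma::eig_sym(lam, U, S, "dc"))
    stop("eigendecomposition of rate matrix failed");
  A = U;
  A.each_col() /= s;        // diag(1/s) * U
  C = U.t();
  C.each_row() %= s.t();    // U' * diag(s)
}

// [[Rcpp::export]]
List eigen_system_cpp(const arma::mat& Q, const arma::vec& pi) {
  arma::mat A, C;
  arma::vec lam;
  reversible_eigen(Q, pi, A, C, lam);
  return List::create(_["A"] = A, _["C"] = C, _["lambda"] = lam);
}

static arma::mat pmat_from_es(const arma::mat& A, const arma::mat& C,
                              const arma::vec& lam, double t) {
  arma::mat E = C;
  E.each_col() %= arma::exp(lam * t);
  arma::mat P = A * E;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export]]
arma::mat pmat_cpp(const arma::mat& A, const arma::mat& C,
                   const arma::vec& lam, double t) {
  return pmat_from_es(A, C, lam, t);
}

// P(t_e) for every edge, as one cube (cached at the R level per omega)
// [[Rcpp::export]]
arma::cube pcube_cpp(const arma::mat& A, const arma::mat& C,
                     const arma::vec& lam, const arma::vec& tvec) {
  const int E = tvec.n_elem;
  arma::cube P(A.n_rows, A.n_cols, E);
  for (int e = 0; e < E; ++e)
    P.slice(e) = pmat_from_es(A, C, lam, tvec(e));
  return P;
}

// Pruning from precomputed per-class transition cubes (61 x 61 x E each).
// [[Rcpp::export]]
arma::mat prune_loglik_cubes_cpp(const arma::imat& edge, int nTip,
                                 const arma::imat& tipStates,
                                 const List& cubes, const arma::vec& pi) {
  const int E = edge.n_rows;
  const int nPat = tipStates.n_cols;
  const int K = cubes.size();
  const int nStates = pi.n_elem;
  int maxNode = nTip;
  for (int e = 0; e < E; ++e)
    maxNode = std::max(maxNode, std::max(edge(e, 0), edge(e, 1)));
  const int root = edge(0, 0) - 1;

  arma::mat out(nPat, K);
  for (int k = 0; k < K; ++k) {
    arma::cube P = cubes[k];
    std::vector<arma::mat> partial(maxNode);
    std::vector<bool> filled(maxNode, false);
    arma::mat logsc(maxNode, nPat, arma::fill::zeros);

    for (int e = E - 1; e >= 0; --e) {
      const int p = edge(e, 0) - 1;
      const int c = edge(e, 1) - 1;
      arma::mat M(nStates, nPat);
      arma::rowvec ls(nPat, arma::fill::zeros);
      if (c < nTip) {
        for (int j = 0; j < nPat; ++j)
          M.col(j) = P.slice(e).col(tipStates(c, j) - 1);
      } else {
        M = P.slice(e) * partial[c];
        ls = logsc.row(c);
      }
      if (!filled[p]) {
        partial[p] = M;
        filled[p] = true;
        logsc.row(p) = ls;
      } else {
        partial[p] %= M;
        logsc.row(p) += ls;
      }
      arma::rowvec m = arma::max(partial[p], 0);
      for (int j = 0; j < nPat; ++j) {
        if (m(j) > 0 && m(j) < 1e-200) {
          partial[p].col(j) /= m(j);
          logsc(p, j) += std::log(m(j));
        }
      }
    }
    for (int j = 0; j < nPat; ++j) {
      double L = arma::dot(pi, partial[root].col(j));
      out(j, k) = (L > 0 ? std::log(L) : -arma::datum::inf) + logsc(root, j);
    }
  }
  return out;
}


// Fused mixture log-likelihood used by the optimizer hot loop: builds the
// per-class rate matrices from the synonymous / nonsynonymous generator
// parts at a shared kappa, eigendecomposes each distinct omega once,
// prunes all classes and returns the weighted mixture total (and the
// per-pattern matrix when requested).
//   Q(omega) = (Qs + omega * Qn) / (meanSyn + omega * meanNon)
// [[Rcpp::export]]
List mixture_loglik_cpp(const arma::imat& edge, int nTip,
                        const arma::imat& tipStates,
                        const arma::vec& weights,
                        const arma::mat& Qs, const arma::mat& Qn,
                        double meanSyn, double meanNon,
                        const arma::vec& wBg, const arma::vec& wFg,
                        const arma::vec& props,
                        const LogicalVector& fgEdge,
                        const arma::vec& tvec, const arma::vec& pi,
                        bool wantMatrix) {
  const int E = edge.n_rows;
  const int nPat = tipStates.n_cols;
  const int K = props.n_elem;
  const int nStates = pi.n_elem;
  int maxNode = nTip;
  for (int e = 0; e < E; ++e)
    maxNode = std::max(maxNode, std::max(edge(e, 0), edge(e, 1)));
  const int root = edge(0, 0) - 1;
  bool anyFg = false;
  for (int e = 0; e < E; ++e) if (fgEdge[e]) anyFg = true;

  // distinct omegas over background and (if used) foreground assignments
  std::vector<double> uo;
  auto omega_index = [&](double w) {
    for (size_t i = 0; i < uo.size(); ++i)
      if (uo[i] == w) return (int)i;
    uo.push_back(w);
    return (int)uo.size() - 1;
  };
  std::vector<int> mapBg(K), mapFg(K);
  for (int k = 0; k < K; ++k) {
    mapBg[k] = omega_index(wBg(k));
    mapFg[k] = anyFg ? omega_index(wFg(k)) : mapBg[k];
  }

  // shared scaling: one expected substitution per codon per unit time
  // averaged over the site-class mixture (so omega > 1 classes evolve
  // faster than omega < 1 classes on the same branch)
  double wbar = arma::dot(props, wBg);
  double scale = meanSyn + wbar * meanNon;

  std::vector<arma::cube> cubes(uo.size());
  for (size_t i = 0; i < uo.size(); ++i) {
    double w = uo[i];
    arma::mat Q = (Qs + w * Qn) / scale;
    arma::mat A, C;
    arma::vec lam;
    reversible_eigen(Q, pi, A, C, lam);
    cubes[i].set_size(nStates, nStates, E);
    for (int e = 0; e < E; ++e)
      cubes[i].slice(e) = pmat_from_es(A, C, lam, tvec(e));
  }

  arma::mat ll(nPat, K);
  for (int k = 0; k < K; ++k) {
    std::vector<arma::mat> partial(maxNode);
    std::vector<bool> filled(maxNode, false);
    arma::mat logsc(maxNode, nPat, arma::fill::zeros);
    for (int e = E - 1; e >= 0; --e) {
      const int p = edge(e, 0) - 1;
      const int c = edge(e, 1) - 1;
      const arma::mat& P = fgEdge[e] ? cubes[mapFg[k]].slice(e)
                                     : cubes[mapBg[k]].slice(e);
      arma::mat M(nStates, nPat);
      arma::rowvec ls(nPat, arma::fill::zeros);
      if (c < nTip) {
        for (int j = 0; j < nPat; ++j)
          M.col(j) = P.col(tipStates(c, j) - 1);
      } else {
        M = P * partial[c];
        ls = logsc.row(c);
      }
      if (!filled[p]) {
        partial[p] = M;
        filled[p] = true;
        logsc.row(p) = ls;
      } else {
        partial[p] %= M;
        logsc.row(p) += ls;
      }
      arma::rowvec m = arma::max(partial[p], 0);
      for (int j = 0; j < nPat; ++j) {
        if (m(j) > 0 && m(j) < 1e-200) {
          partial[p].col(j) /= m(j);
          logsc(p, j) += std::log(m(j));
        }
      }
    }
    for (int j = 0; j < nPat; ++j) {
      double L = arma::dot(pi, partial[root].col(j));
      ll(j, k) = (L > 0 ? std::log(L) : -arma::datum::inf) + logsc(root, j);
    }
  }

  // weighted log-sum-exp over classes
  arma::vec lp = arma::log(props);
  double total = 0.0;
  bool finite = true;
  for (int j = 0; j < nPat; ++j) {
    double m = -arma::datum::inf;
    for (int k = 0; k < K; ++k)
      m = std::max(m, ll(j, k) + lp(k));
    if (!std::isfinite(m)) { finite = false; break; }
    double sum = 0.0;
    for (int k = 0; k < K; ++k)
      sum += std::exp(ll(j, k) + lp(k) - m);
    total += weights(j) * (m + std::log(sum));
  }
  if (!finite) total = -arma::datum::inf;
  if (wantMatrix)
    return List::create(_["lnL"] = total, _["ll"] = ll);
  return List::create(_["lnL"] = total);
}
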