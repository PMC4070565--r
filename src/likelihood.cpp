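// Felsenstein pruning log-likelihood for one partition.
//
// Reversible Q is diagonalized through the symmetrizing similarity
// transform (D^{1/2} Q D^{-1/2} is symmetric), giving real eigenvalues
// and a stable P(t) = U exp(L r t) U^{-1}. Underflow is handled by
// per-node rescaling with log accumulators, so exact lnL is returned
// for alignments of arbitrary depth.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void build_eigen(const arma::vec& r6, const arma::vec& pi,
                        arma::vec& eval, arma::mat& U, arma::mat& Uinv) {
  arma::mat Q(4, 4, arma::fill::zeros);
  const int pr[6] = {0, 0, 0, 1, 1, 2};
  const int pc[6] = {1, 2, 3, 2, 3, 3};
  for (int k = 0; k < 6; ++k) {
    Q(pr[k], pc[k]) = r6[k] * pi[pc[k]];
    Q(pc[k], pr[k]) = r6[k] * pi[pr[k]];
  }
  for (int i = 0; i < 4; ++i) {
    double s = 0;
    for (int j = 0; j < 4; ++j) if (j != i) s += Q(i, j);
    Q(i, i) = -s;
  }
  double mu = 0;
  for (int i = 0; i < 4; ++i) mu -= pi[i] * Q(i, i);
  Q /= mu;
  arma::vec d = arma::sqrt(pi);
  arma::mat S = Q;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) S(i, j) *= d[i] / d[j];
  S = (S + S.t()) / 2.0;
  arma::mat V;
  arma::eig_sym(eval, V, S);
  U = V;
  Uinv = V.t();
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) { U(i, j) /= d[i]; Uinv(i, j) *= d[j]; }
}

// Core pruning evaluation over one partition given a precomputed eigen
// system of Q.
static double prune_partition(const IntegerMatrix& leafMasks,
                              const NumericVector& weights,
                              const IntegerMatrix& edge,
                              const NumericVector& edgeLen,
                              const arma::vec& eval, const arma::mat& U,
                              const arma::mat& Uinv, const arma::vec& pi,
                              const NumericVector& catRates,
                              double multiplier) {
  const int ntax = leafMasks.nrow();
  const int npat = leafMasks.ncol();
  const int nedge = edge.nrow();
  const int ncat = catRates.size();
  const int nnode = ntax + (nedge / 2) + 2;  // generous upper bound

  // P matrices: [edge][cat], flat 16 doubles each, row-major
  std::vector<double> P((size_t)nedge * ncat * 16);
  for (int e = 0; e < nedge; ++e) {
    double t = edgeLen[e] * multiplier;
    for (int c = 0; c < ncat; ++c) {
      double ex[4];
      for (int i = 0; i < 4; ++i) ex[i] = std::exp(eval[i] * catRates[c] * t);
      double* M = &P[((size_t)e * ncat + c) * 16];
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double v = 0;
          for (int l = 0; l < 4; ++l) v += U(i, l) * ex[l] * Uinv(l, j);
          M[i * 4 + j] = v > 0 ? v : 0;
        }
    }
  }

  const int root = edge(nedge - 1, 0) - 1;
  // per-pattern, per-category log site likelihoods; mixed by logsumexp
  // at the end so per-node rescaling never has to be re-expanded.
  arma::mat lsite(npat, ncat);

  // partials: [node][pat*4], per category; scale logs shared across
  // categories would be wrong, so keep per-category accumulators.
  std::vector<double> partial((size_t)nnode * npat * 4);
  std::vector<double> scalelog(npat);

  for (int c = 0; c < ncat; ++c) {
    std::fill(partial.begin(), partial.end(), 0.0);
    std::fill(scalelog.begin(), scalelog.end(), 0.0);
    std::vector<char> seen(nnode, 0);
    // init internal partials to 1 lazily via 'seen'
    for (int e = 0; e < nedge; ++e) {
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const double* M = &P[((size_t)e * ncat + c) * 16];
      if (!seen[par]) {
        for (int s = 0; s < npat; ++s)
          for (int i = 0; i < 4; ++i)
            partial[((size_t)par * npat + s) * 4 + i] = 1.0;
        seen[par] = 1;
      }
      if (ch < ntax) {
        for (int s = 0; s < npat; ++s) {
          int mask = leafMasks(ch, s);
          double* pp = &partial[((size_t)par * npat + s) * 4];
          for (int i = 0; i < 4; ++i) {
            double v = 0;
            for (int j = 0; j < 4; ++j)
              if (mask & (1 << j)) v += M[i * 4 + j];
            pp[i] *= v;
          }
        }
      } else {
        for (int s = 0; s < npat; ++s) {
          const double* cp = &partial[((size_t)ch * npat + s) * 4];
          double* pp = &partial[((size_t)par * npat + s) * 4];
          double mx = 0;
          double tmp[4];
          for (int i = 0; i < 4; ++i) {
            double v = 0;
            for (int j = 0; j < 4; ++j) v += M[i * 4 + j] * cp[j];
            tmp[i] = v;
          }
          for (int i = 0; i < 4; ++i) {
            pp[i] *= tmp[i];
            if (pp[i] > mx) mx = pp[i];
          }
          if (mx > 0 && mx < 1e-100) {
            for (int i = 0; i < 4; ++i) pp[i] /= mx;
            scalelog[s] += std::log(mx);
          }
        }
      }
    }
    for (int s = 0; s < npat; ++s) {
      double v = 0;
      const double* rp = &partial[((size_t)root * npat + s) * 4];
      for (int i = 0; i < 4; ++i) v += pi[i] * rp[i];
      lsite(s, c) = (v > 0) ? std::log(v) + scalelog[s] : R_NegInf;
    }
  }

  double lnL = 0;
  for (int s = 0; s < npat; ++s) {
    double mx = lsite.row(s).max();
    if (!std::isfinite(mx)) return R_NegInf;
    double acc = 0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(lsite(s, c) - mx);
    lnL += weights[s] * (mx + std::log(acc / ncat));
  }
  return lnL;
}

// edge: 2-column matrix (parent, child), 1-based node ids, postorder;
// tips are 1..ntax, internal nodes ntax+1..; root = edge(last, 0).
// leafMasks: ntax x npat integers, 4-bit state masks over (A,C,G,T).
// [[Rcpp::export(name = ".pruningLnL")]]
double pruningLnL(IntegerMatrix leafMasks, NumericVector weights,
                  IntegerMatrix edge, NumericVector edgeLen,
                  NumericVector rates6, NumericVector freqs4,
                  NumericVector catRates, double multiplier) {
  arma::vec eval, pi(4), r6(6);
  arma::mat U, Uinv;
  for (int i = 0; i < 4; ++i) pi[i] = freqs4[i];
  for (int i = 0; i < 6; ++i) r6[i] = rates6[i];
  build_eigen(r6, pi, eval, U, Uinv);
  return prune_partition(leafMasks, weights, edge, edgeLen, eval, U, Uinv,
                         pi, catRates, multiplier);
}

// All (or a subset of) partitions in one call, sharing the tree.
// patterns: list of list(masks, weights); ratesMat k x 6; freqsMat k x 4;
// catRates: list of k numeric vectors; which: 1-based partition indices.
// Returns lnL per requested partition (full-length vector, NA elsewhere).
// [[Rcpp::export(name = ".pruningLnLMulti")]]
NumericVector pruningLnLMulti(List patterns, IntegerMatrix edge,
                              NumericVector edgeLen, NumericMatrix ratesMat,
                              NumericMatrix freqsMat, List catRates,
                              NumericVector multipliers,
                              IntegerVector which) {
  const int k = patterns.size();
  NumericVector out(k, NA_REAL);
  for (int w = 0; w < which.size(); ++w) {
    int p = which[w] - 1;
    List pat = patterns[p];
    IntegerMatrix masks = pat["masks"];
    NumericVector wts = pat["weights"];
    arma::vec eval, pi(4), r6(6);
    arma::mat U, Uinv;
    for (int i = 0; i < 4; ++i) pi[i] = freqsMat(p, i);
    for (int i = 0; i < 6; ++i) r6[i] = ratesMat(p, i);
    build_eigen(r6, pi, eval, U, Uinv);
    NumericVector cr = catRates[p];
    out[p] = prune_partition(masks, wts, edge, edgeLen, eval, U, Uinv,
                             pi, cr, multipliers[p]);
  }
  return out;
}
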