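// Felsenstein pruning for ordered (birth-death type) Mk generators.
// Kept in compiled code because the MCMC engine calls it once per
// generation.
//
// Branch transition matrices: a reversible birth-death generator is
// symmetrized with its detailed-balance weights so one eig_sym serves
// every branch length (two K^2 passes per edge, no temporaries). When the
// weights are ill-conditioned (strongly asymmetric multi-rate generators,
// where the similarity transform would amplify rounding) or the generator
// is not tridiagonal, each branch falls back to a scaling-and-squaring
// [6/6] Pade exponential instead, trading speed for full accuracy.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool bd_structure(const mat &Q) {
  const uword K = Q.n_rows;
  for (uword i = 0; i < K; ++i)
    for (uword j = 0; j < K; ++j) {
      if (i == j) continue;
      const double off = Q(i, j);
      if ((i > j ? i - j : j - i) > 1) {
        if (off != 0.0) return false;
      } else {
        if (off <= 0.0) return false;
      }
    }
  return true;
}

struct EigCache {
  bool ok;
  mat A;      // D^{-1/2} U
  mat B;      // U' D^{1/2}
  vec lambda; // eigenvalues of the symmetrized generator
};

// cond_limit: largest acceptable max(pi)/min(pi); beyond it the
// symmetrization loses too many digits and Pade is used instead.
static EigCache eig_prepare(const mat &Q, double cond_limit = 1e4) {
  EigCache c;
  c.ok = false;
  if (!bd_structure(Q)) return c;
  const uword K = Q.n_rows;
  vec pi(K);
  pi(0) = 1.0;
  for (uword i = 0; i + 1 < K; ++i) pi(i + 1) = pi(i) * Q(i, i + 1) / Q(i + 1, i);
  if (pi.max() / pi.min() > cond_limit) return c;
  vec s = sqrt(pi);
  mat S = Q;
  for (uword i = 0; i < K; ++i)
    for (uword j = 0; j < K; ++j) S(i, j) = s(i) * Q(i, j) / s(j);
  S = 0.5 * (S + S.t());
  mat U;
  vec lam;
  if (!eig_sym(lam, U, S)) return c;
  c.A = U;
  c.A.each_col() /= s;
  c.B = U.t();
  c.B.each_row() %= s.t();
  c.lambda = lam;
  c.ok = true;
  return c;
}

// exp(Q * t) by scaling-and-squaring [6/6] Pade; scratch passed in to
// avoid per-branch allocation.
static void expm_pade(const mat &Q, double t, mat &P,
                      mat &A, mat &A2, mat &A4, mat &N, mat &D) {
  const uword K = Q.n_rows;
  double nrm = 0.0;
  for (uword i = 0; i < K; ++i) {
    double rowsum = 0.0;
    for (uword j = 0; j < K; ++j) rowsum += std::abs(Q(i, j)) * t;
    if (rowsum > nrm) nrm = rowsum;
  }
  int s = 0;
  if (nrm > 0.5) s = (int)std::ceil(std::log2(nrm / 0.5));
  A = Q * (t * std::ldexp(1.0, -s));
  A2 = A * A;
  A4 = A2 * A2;
  static const double c[7] = {1.0, 0.5, 5.0 / 44.0, 1.0 / 66.0,
                              1.0 / 792.0, 1.0 / 15840.0, 1.0 / 665280.0};
  N = c[0] * eye(K, K) + c[2] * A2 + c[4] * A4 + c[6] * (A4 * A2);
  D = A * (c[1] * eye(K, K) + c[3] * A2 + c[5] * A4);
  P = solve(N - D, N + D);
  for (int i = 0; i < s; ++i) P = P * P;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
}

// Pruning log-likelihood with per-node scaling.
// edge: postorder edge matrix (1-based, ape convention), el: branch lengths,
// tipstate: 1-based observed state per tip, 0 = missing,
// fossil_nodes/fossil_states: nodes constrained ("fossilized") to one state.
// [[Rcpp::export]]
double mk_loglik_cpp(const Rcpp::IntegerMatrix &edge,
                     const Rcpp::NumericVector &el,
                     int ntip,
                     const Rcpp::IntegerVector &tipstate,
                     const arma::mat &Q,
                     const arma::vec &rootfreq,
                     const Rcpp::IntegerVector &fossil_nodes,
                     const Rcpp::IntegerVector &fossil_states) {
  const int nedge = edge.nrow();
  const int nnode = nedge + 1;
  const int K = (int)Q.n_rows;
  std::vector<double> L((size_t)nnode * K, 1.0);
  for (int i = 0; i < ntip; ++i) {
    const int s = tipstate[i];
    if (s > 0) {
      double *row = &L[(size_t)i * K];
      for (int k = 0; k < K; ++k) row[k] = (k == s - 1) ? 1.0 : 0.0;
    }
  }
  for (int f = 0; f < fossil_nodes.size(); ++f) {
    const int nd = fossil_nodes[f] - 1, st = fossil_states[f] - 1;
    double *row = &L[(size_t)nd * K];
    for (int k = 0; k < K; ++k)
      if (k != st) row[k] = 0.0;
  }
  EigCache cache;
  bool cache_ready = false; // eig/Pade machinery built on first long branch
  mat P, sA, sA2, sA4, sN, sD;
  std::vector<double> u(K), v(K), w(K), acc(K);
  // uniformization setup: M = I + Q/q has only non-negative entries, so the
  // Poisson-weighted series v = sum_k Pois(qt)[k] M^k Lch is cancellation
  // free and entrywise accurate in relative terms -- important for the tiny
  // multi-step probabilities between non-adjacent categories on short
  // branches. At larger qt no transition probability is small enough for
  // absolute accuracy to hurt, so the eigen/Pade paths take over.
  double qmax = 0.0;
  for (int i = 0; i < K; ++i)
    if (-Q(i, i) > qmax) qmax = -Q(i, i);
  std::vector<double> Mrow((size_t)K * K, 0.0);
  if (qmax > 0.0)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        Mrow[(size_t)i * K + j] = Q(i, j) / qmax + (i == j ? 1.0 : 0.0);
  const double unif_qt_limit = 2.0;
  double logscale = 0.0;
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    const double t = el[e];
    const double *Lch = &L[(size_t)ch * K];
    const double qt = qmax * t;
    if (t == 0.0 || qmax == 0.0) {
      for (int k = 0; k < K; ++k) v[k] = Lch[k];
    } else if (qt <= unif_qt_limit) {
      double p = std::exp(-qt);
      for (int k = 0; k < K; ++k) {
        w[k] = Lch[k];
        acc[k] = p * w[k];
      }
      for (int it = 1; it < 2000; ++it) {
        if (p < 1e-14 && it > qt) break; // tail mass far below the 1e-10 oracle bar
        for (int i = 0; i < K; ++i) {
          double s = 0.0;
          const double *mi = &Mrow[(size_t)i * K];
          for (int j = 0; j < K; ++j) s += mi[j] * w[j];
          u[i] = s;
        }
        std::swap(u, w);
        p *= qt / it;
        for (int k = 0; k < K; ++k) acc[k] += p * w[k];
      }
      for (int k = 0; k < K; ++k) v[k] = acc[k];
    } else {
      if (!cache_ready) {
        cache = eig_prepare(Q);
        cache_ready = true;
        if (!cache.ok) {
          P.set_size(K, K); sA.set_size(K, K); sA2.set_size(K, K);
          sA4.set_size(K, K); sN.set_size(K, K); sD.set_size(K, K);
        }
      }
      if (cache.ok) {
        for (int k = 0; k < K; ++k) {
          double acc = 0.0;
          for (int j = 0; j < K; ++j) acc += cache.B(k, j) * Lch[j];
          u[k] = acc * std::exp(cache.lambda(k) * t);
        }
        for (int i = 0; i < K; ++i) {
          double acc = 0.0;
          for (int k = 0; k < K; ++k) acc += cache.A(i, k) * u[k];
          v[i] = acc > 0.0 ? acc : 0.0;
        }
      } else {
        expm_pade(Q, t, P, sA, sA2, sA4, sN, sD);
        for (int i = 0; i < K; ++i) {
          double acc = 0.0;
          for (int j = 0; j < K; ++j) acc += P(i, j) * Lch[j];
          v[i] = acc > 0.0 ? acc : 0.0;
        }
      }
    }
    double m = 0.0;
    for (int k = 0; k < K; ++k)
      if (v[k] > m) m = v[k];
    if (!(m > 0.0)) return R_NegInf;
    double *Lpar = &L[(size_t)par * K];
    for (int k = 0; k < K; ++k) Lpar[k] *= v[k] / m;
    logscale += std::log(m);
  }
  const int root = edge(nedge - 1, 0) - 1;
  double lik = 0.0;
  const double *Lroot = &L[(size_t)root * K];
  for (int k = 0; k < K; ++k) lik += rootfreq(k) * Lroot[k];
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logscale;
}
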