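#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Felsenstein/contrast pruning for Brownian motion with a fixed root mean.
// edge rows must be in postorder (every edge into an internal node appears
// after all edges of that node's subtree); node indices are 1-based ape
// indices (tips 1..ntip, root ntip+1).  `len` are branch lengths already
// carrying sigma2, branch scalars and any lambda transform.
// [[Rcpp::export]]
double bm_prune_cpp(IntegerMatrix edge, NumericVector len, int ntip,
                    NumericVector x, double root_mean, bool use_root) {
  int ntot = ntip + (max(edge(_, 0)) - ntip);
  std::vector<double> m(ntot + 1, 0.0), v(ntot + 1, 0.0);
  std::vector<bool> seen(ntot + 1, false);
  for (int i = 0; i < ntip; ++i) { m[i + 1] = x[i]; seen[i + 1] = true; }
  double ll = 0.0;
  int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    double vc = v[c] + len[e];
    if (!seen[p]) { m[p] = m[c]; v[p] = vc; seen[p] = true; }
    else {
      double vt = v[p] + vc;
      if (vt <= 0.0) {
        if (m[p] != m[c]) return R_NegInf;
      } else {
        double d = m[p] - m[c];
        ll += -0.5 * (LOG2PI + std::log(vt) + d * d / vt);
        m[p] = (m[p] * vc + m[c] * v[p]) / vt;
        v[p] = v[p] * vc / vt;
      }
    }
  }
  int root = ntip + 1;
  if (use_root) {
    if (v[root] <= 0.0) {
      if (m[root] != root_mean) return R_NegInf;
    } else {
      double d = m[root] - root_mean;
      ll += -0.5 * (LOG2PI + std::log(v[root]) + d * d / v[root]);
    }
  }
  return ll;
}

// One-off spectral decomposition of Q so per-edge transition matrices are
// two small matrix products instead of a full expmat; falls back to
// scaling-and-squaring when Q is defective/ill-conditioned.
struct QExp {
  arma::cx_mat evec, inv;
  arma::cx_vec eval;
  arma::mat Q;
  bool use_eig;
  // tref: the longest branch to be evaluated -- eigen error grows with t,
  // so the decomposition is validated against expmat at that horizon
  QExp(const arma::mat &Qin, double tref) : Q(Qin) {
    use_eig = arma::eig_gen(eval, evec, Qin) && arma::inv(inv, evec);
    if (use_eig) {
      if (tref <= 0.0) tref = 1.0;
      arma::mat test = P(tref);
      arma::mat ref = arma::expmat(Qin * tref);
      if (arma::abs(test - ref).max() > 1e-9) use_eig = false;
    }
  }
  arma::mat P(double t) const {
    if (use_eig) {
      arma::mat out = arma::real(evec * arma::diagmat(arma::exp(eval * t)) * inv);
      out.clamp(0.0, arma::datum::inf);
      return out;
    }
    return arma::expmat(Q * t);
  }
};

// Pruning likelihood for a k-state CTMC on a rooted tree.
// tiplik: ntip x k partial likelihoods at the tips (ambiguity vectors).
// rootp: root state distribution.  Returns log likelihood.
// [[Rcpp::export]]
double ctmc_prune_cpp(IntegerMatrix edge, NumericVector len, int ntip,
                      arma::mat tiplik, arma::mat Q, arma::vec rootp) {
  int k = Q.n_rows;
  QExp qe(Q, max(len));
  int nnode = max(edge(_, 0)) - ntip;
  int ntot = ntip + nnode;
  arma::mat part(ntot + 1, k, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) part.row(i + 1) = tiplik.row(i);
  double logscale = 0.0;
  int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    arma::mat P = qe.P(len[e]);
    arma::rowvec msg = (P * part.row(c).t()).t();
    part.row(p) %= msg;
    double s = arma::accu(part.row(p));
    if (s <= 0.0) return R_NegInf;
    if (s < 1e-40) { part.row(p) /= s; logscale += std::log(s); }
  }
  double lik = arma::dot(rootp, part.row(ntip + 1).t());
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// Marginal ancestral state probabilities for every node (tips included)
// by the standard down (postorder) / up (preorder) message passing.
// Returns (ntot x k) matrix of marginals, rows indexed by ape node id.
// [[Rcpp::export]]
arma::mat ctmc_marginals_cpp(IntegerMatrix edge, NumericVector len, int ntip,
                             arma::mat tiplik, arma::mat Q, arma::vec rootp) {
  int k = Q.n_rows;
  int nnode = max(edge(_, 0)) - ntip;
  int ntot = ntip + nnode;
  int ne = edge.nrow();
  QExp qe(Q, max(len));
  arma::mat down(ntot + 1, k, arma::fill::ones);     // data below node
  arma::mat msg(ne, k);                              // parent-side message per edge
  arma::cube Pmats(k, k, ne);
  for (int i = 0; i < ntip; ++i) down.row(i + 1) = tiplik.row(i);
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    arma::mat P = qe.P(len[e]);
    Pmats.slice(e) = P;
    arma::rowvec m = (P * down.row(c).t()).t();
    msg.row(e) = m;
    down.row(p) %= m;
    double s = arma::accu(down.row(p));
    if (s > 0.0) down.row(p) /= s;                   // scale; marginals renormalized anyway
  }
  arma::mat up(ntot + 1, k, arma::fill::ones);
  up.row(ntip + 1) = rootp.t();
  // preorder: reverse of postorder edge order
  for (int e = ne - 1; e >= 0; --e) {
    int p = edge(e, 0), c = edge(e, 1);
    arma::rowvec above = up.row(p) % down.row(p);
    for (int j = 0; j < k; ++j) {
      double b = msg(e, j);
      above[j] = (b > 0.0) ? above[j] / b : 0.0;     // remove child's own message
    }
    up.row(c) = (Pmats.slice(e).t() * above.t()).t();
    double s = arma::accu(up.row(c));
    if (s > 0.0) up.row(c) /= s;
  }
  arma::mat marg(ntot, k);
  for (int n = 1; n <= ntot; ++n) {
    arma::rowvec mrow = down.row(n) % up.row(n);
    double s = arma::accu(mrow);
    marg.row(n - 1) = (s > 0.0) ? mrow / s : mrow;
  }
  return marg;
}
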