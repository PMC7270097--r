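// Fast single-site likelihood under the branch-mixture codon model used by
// the episodic scan. The reversible generator is passed in symmetrized form
// Q(a, b) = D^{-1/2} (a*SA + b*SB) D^{1/2}, so each evaluation needs two
// symmetric eigendecompositions plus one pruning pass.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void trans_mats(const arma::mat& SA, const arma::mat& SB,
                       const arma::vec& sqrt_pi, double a, double b,
                       const arma::vec& elen, std::vector<arma::mat>& out) {
  arma::mat Sy = a * SA + b * SB;
  arma::vec lam;
  arma::mat U;
  arma::eig_sym(lam, U, Sy);
  arma::mat left = U.each_col() / sqrt_pi;   // D^{-1/2} U
  arma::mat right = U.each_col() % sqrt_pi;  // (U^T D^{1/2})^T
  for (size_t e = 0; e < out.size(); ++e) {
    arma::vec ex = arma::exp(lam * elen[e]);
    out[e] = left * arma::diagmat(ex) * right.t();
    out[e].transform([](double v) { return v < 0 ? 0.0 : v; });
  }
}

// states: 1-based codon state per tip (postorder tip numbering), NA = missing
// edge: postorder edge matrix (parent, child), 1-based node ids
// [[Rcpp::export(name = ".mix_site_loglik_cpp")]]
double mix_site_loglik_cpp(IntegerVector states, IntegerMatrix edge,
                           NumericVector elen, arma::vec pi,
                           arma::mat SA, arma::mat SB,
                           double alpha, double beta_minus, double beta_plus,
                           double q) {
  int m = pi.n_elem;
  int ntip = states.size();
  int nedge = edge.nrow();
  int nnode = ntip + nedge / 2 + 1; // binary-ish upper bound
  // find max node id to size storage
  for (int e = 0; e < nedge; ++e) {
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  }
  arma::vec sqrt_pi = arma::sqrt(pi);
  arma::vec el(elen.begin(), elen.size());
  std::vector<arma::mat> Pm(nedge), Pp;
  trans_mats(SA, SB, sqrt_pi, alpha, beta_minus, el, Pm);
  bool mix = (q > 0.0) && std::abs(beta_plus - beta_minus) > 1e-12;
  if (mix) {
    Pp.resize(nedge);
    trans_mats(SA, SB, sqrt_pi, alpha, beta_plus, el, Pp);
  }
  std::vector<arma::vec> partial(nnode + 1);
  std::vector<bool> seen(nnode + 1, false);
  double logscale = 0.0;
  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    arma::vec cp;
    if (child <= ntip) {
      cp.zeros(m);
      if (states[child - 1] == NA_INTEGER) cp.ones(m);
      else cp[states[child - 1] - 1] = 1.0;
    } else {
      cp = partial[child];
    }
    arma::vec contrib = mix ? arma::vec((1.0 - q) * (Pm[e] * cp) + q * (Pp[e] * cp))
                            : arma::vec(Pm[e] * cp);
    if (!seen[parent]) {
      partial[parent] = contrib;
      seen[parent] = true;
    } else {
      partial[parent] %= contrib;
      double mx = partial[parent].max();
      if (mx > 0 && mx < 1e-200) { partial[parent] /= mx; logscale += std::log(mx); }
    }
  }
  int root = edge(nedge - 1, 0);
  double lik = arma::dot(pi, partial[root]);
  return std::log(lik) + logscale;
}
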