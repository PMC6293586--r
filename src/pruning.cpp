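#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-category per-site log-likelihoods by Felsenstein pruning.
//
// edge          E x 2 integer matrix (parent, child), 1-based ape node ids,
//               rows already in postorder (children before parents).
// el            edge lengths, substitutions/site at rate 1.
// tip_states    n_tip x n_sites integer matrix; 1..n_states, 0 = missing
//               (gap/'X': partial likelihood 1 for every state).
// A, B, lambda  spectral factors of the reversible generator:
//               P(t) = A diag(exp(lambda * t)) B.
// rates         relative rate of each discrete-gamma category (mean 1).
// freq          stationary frequencies (root distribution).
//
// Returns a k x n_sites matrix: log-likelihood of each site under each
// rate category, scaled partials accumulated into per-site log scalers so
// long trees do not underflow.
// [[Rcpp::export]]
NumericMatrix cat_site_loglik(IntegerMatrix edge, NumericVector el,
                              IntegerMatrix tip_states,
                              NumericMatrix A, NumericMatrix B,
                              NumericVector lambda, NumericVector rates,
                              NumericVector freq) {
  const int ns = freq.size();
  const int n_tip = tip_states.nrow();
  const int n_sites = tip_states.ncol();
  const int n_edge = edge.nrow();
  const int k = rates.size();
  int n_nodes = n_tip;
  for (int e = 0; e < n_edge; ++e) {
    if (edge(e, 0) > n_nodes) n_nodes = edge(e, 0);
    if (edge(e, 1) > n_nodes) n_nodes = edge(e, 1);
  }

  NumericMatrix out(k, n_sites);
  std::vector<double> P(ns * ns);
  std::vector<double> expl(ns);
  // partials: only interior nodes carry one (tips are consumed directly)
  std::vector< std::vector<double> > partial(n_nodes + 1);
  std::vector<char> touched(n_nodes + 1);
  std::vector<double> v(ns);

  for (int c = 0; c < k; ++c) {
    double r = rates[c];
    std::vector<double> logscale(n_sites, 0.0);
    for (int i = n_tip + 1; i <= n_nodes; ++i) touched[i] = 0;

    for (int e = 0; e < n_edge; ++e) {
      int par = edge(e, 0), chd = edge(e, 1);
      double t = el[e] * r;
      // P(t) = A diag(exp(lambda t)) B, clamped at 0 against round-off
      for (int s = 0; s < ns; ++s) expl[s] = std::exp(lambda[s] * t);
      for (int i = 0; i < ns; ++i) {
        for (int j = 0; j < ns; ++j) {
          double acc = 0.0;
          for (int s = 0; s < ns; ++s) acc += A(i, s) * expl[s] * B(s, j);
          P[i * ns + j] = acc > 0.0 ? acc : 0.0;
        }
      }

      std::vector<double> &pp = partial[par];
      if (!touched[par]) { pp.assign((size_t)ns * n_sites, 1.0); touched[par] = 1; }

      if (chd <= n_tip) {
        // tip child: column gather, no matrix product needed
        for (int site = 0; site < n_sites; ++site) {
          int st = tip_states(chd - 1, site);
          double *dst = &pp[(size_t)site * ns];
          if (st == 0) continue;             // missing: factor 1
          int j = st - 1;
          for (int i = 0; i < ns; ++i) dst[i] *= P[i * ns + j];
        }
      } else {
        std::vector<double> &cp = partial[chd];
        for (int site = 0; site < n_sites; ++site) {
          const double *src = &cp[(size_t)site * ns];
          double *dst = &pp[(size_t)site * ns];
          double mx = 0.0;
          for (int i = 0; i < ns; ++i) {
            double acc = 0.0;
            for (int j = 0; j < ns; ++j) acc += P[i * ns + j] * src[j];
            v[i] = acc;
            if (acc > mx) mx = acc;
          }
          if (mx <= 0.0) {
            for (int i = 0; i < ns; ++i) dst[i] = 0.0;
          } else {
            for (int i = 0; i < ns; ++i) dst[i] *= v[i] / mx;
            logscale[site] += std::log(mx);
          }
        }
        cp.clear();
        touched[chd] = 0;
      }
      // re-scale parent partial to keep magnitudes bounded
      if (e == n_edge - 1 || edge(e + 1, 0) != par) {
        for (int site = 0; site < n_sites; ++site) {
          double *dst = &pp[(size_t)site * ns];
          double mx = 0.0;
          for (int i = 0; i < ns; ++i) if (dst[i] > mx) mx = dst[i];
          if (mx > 0.0 && (mx < 1e-100 || mx > 1e100)) {
            for (int i = 0; i < ns; ++i) dst[i] /= mx;
            logscale[site] += std::log(mx);
          }
        }
      }
    }

    int root = edge(n_edge - 1, 0);
    std::vector<double> &rp = partial[root];
    for (int site = 0; site < n_sites; ++site) {
      const double *src = &rp[(size_t)site * ns];
      double acc = 0.0;
      for (int i = 0; i < ns; ++i) acc += freq[i] * src[i];
      out(c, site) = acc > 0.0 ? std::log(acc) + logscale[site] : R_NegInf;
    }
    rp.clear();
  }
  return out;
}
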