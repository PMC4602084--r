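// Gibbs sampler for a pairwise (Potts-like) model over codon states.
// Sequences are independent chains: each is equilibrated for `sweeps`
// full passes over the L sites and its final configuration is the sample.
// Fields and couplings are exponentiated once up front, so a single-site
// update is a product of table lookups.  Energies are assumed bounded
// (couplings of order a few kT), so the unnormalised weights cannot
// overflow.  Uses R's RNG for reproducibility under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(const NumericMatrix& h,      // K x L fields
                               const IntegerMatrix& edges,  // E x 2, 0-based sites
                               const List& emats,           // E energy matrices K x K
                               IntegerMatrix states,        // M x L init, 0-based
                               int sweeps) {
  const int K = h.nrow();
  const int L = h.ncol();
  const int M = states.nrow();
  const int E = edges.nrow();

  // adjacency: for each site, incident edges and whether the site is the row
  std::vector<std::vector<std::pair<int, bool> > > adj(L);
  for (int e = 0; e < E; ++e) {
    adj[edges(e, 0)].push_back(std::make_pair(e, true));
    adj[edges(e, 1)].push_back(std::make_pair(e, false));
  }
  // exponentiated fields (K x L, column-major) and couplings (both
  // orientations, so partner lookup is always a column scan)
  std::vector<double> eh((size_t) K * L);
  for (int i = 0; i < L; ++i)
    for (int k = 0; k < K; ++k) eh[(size_t) i * K + k] = std::exp(h(k, i));
  std::vector<std::vector<double> > Wrow(E), Wcol(E);
  for (int e = 0; e < E; ++e) {
    NumericMatrix Em = as<NumericMatrix>(emats[e]);
    Wrow[e].resize((size_t) K * K);
    Wcol[e].resize((size_t) K * K);
    for (int b = 0; b < K; ++b)
      for (int a = 0; a < K; ++a) {
        const double w = std::exp(Em(a, b));
        Wrow[e][(size_t) b * K + a] = w;  // fixed partner state b, scan a
        Wcol[e][(size_t) a * K + b] = w;  // fixed partner state a, scan b
      }
  }

  std::vector<double> prob(K);
  for (int s = 0; s < M; ++s) {
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int i = 0; i < L; ++i) {
        const double* ehi = &eh[(size_t) i * K];
        double z = 0.0;
        if (adj[i].empty()) {
          for (int k = 0; k < K; ++k) { prob[k] = ehi[k]; z += ehi[k]; }
        } else {
          for (int k = 0; k < K; ++k) prob[k] = ehi[k];
          for (size_t a = 0; a < adj[i].size(); ++a) {
            const int e = adj[i][a].first;
            const bool isRow = adj[i][a].second;
            const int partner = isRow ? edges(e, 1) : edges(e, 0);
            const int t = states(s, partner);
            const double* w = isRow ? &Wrow[e][(size_t) t * K]
                                    : &Wcol[e][(size_t) t * K];
            for (int k = 0; k < K; ++k) prob[k] *= w[k];
          }
          for (int k = 0; k < K; ++k) z += prob[k];
        }
        double u = unif_rand() * z, c = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) { c += prob[k]; if (u <= c) { pick = k; break; } }
        states(s, i) = pick;
      }
    }
  }
  return states;
}
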