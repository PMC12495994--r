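#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// CSR adjacency: adj holds 0-based neighbor ids (sorted within each node),
// ptr has length n+1 with ptr[v]..ptr[v+1]-1 indexing v's neighbors.

static inline bool has_edge(const IntegerVector& adj, const IntegerVector& ptr,
                            int u, int v) {
  const int* begin = adj.begin() + ptr[u];
  const int* end   = adj.begin() + ptr[u + 1];
  return std::binary_search(begin, end, v);
}

// Biased second-order random walks (return parameter p, in-out parameter q).
// Weight 1/p to step back to the previous node, 1 to a common neighbor of the
// previous node, 1/q otherwise; first step is uniform.
// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector adj, IntegerVector ptr,
                        double p, double q,
                        int walk_length, int walks_per_node, int seed) {
  const int n = ptr.size() - 1;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 1u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  List walks(static_cast<R_xlen_t>(n) * walks_per_node);
  R_xlen_t w_idx = 0;
  std::vector<double> wts;

  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1, curr = start;
      while ((int)walk.size() < walk_length) {
        int deg = ptr[curr + 1] - ptr[curr];
        if (deg == 0) break;  // dead end: shorter walk
        int next;
        if (prev < 0) {
          next = adj[ptr[curr] + (int)(unif(rng) * deg) % deg];
        } else {
          wts.resize(deg);
          double tot = 0.0;
          for (int k = 0; k < deg; ++k) {
            int c = adj[ptr[curr] + k];
            double w;
            if (c == prev) w = 1.0 / p;
            else if (has_edge(adj, ptr, prev, c)) w = 1.0;
            else w = 1.0 / q;
            tot += w;
            wts[k] = tot;
          }
          double r = unif(rng) * tot;
          int k = (int)(std::lower_bound(wts.begin(), wts.end(), r) - wts.begin());
          if (k >= deg) k = deg - 1;
          next = adj[ptr[curr] + k];
        }
        walk.push_back(next);
        prev = curr;
        curr = next;
      }
      walks[w_idx++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return walks;
}

// Single biased transition step probabilities, for cross-checking against the
// R-level implementation (same arithmetic as the walker).
// [[Rcpp::export]]
NumericVector cpp_transition_probs(IntegerVector adj, IntegerVector ptr,
                                   int prev, int curr, double p, double q) {
  int deg = ptr[curr + 1] - ptr[curr];
  NumericVector out(deg);
  double tot = 0.0;
  for (int k = 0; k < deg; ++k) {
    int c = adj[ptr[curr] + k];
    double w;
    if (prev < 0) w = 1.0;
    else if (c == prev) w = 1.0 / p;
    else if (has_edge(adj, ptr, prev, c)) w = 1.0;
    else w = 1.0 / q;
    out[k] = w;
    tot += w;
  }
  for (int k = 0; k < deg; ++k) out[k] /= tot;
  return out;
}
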