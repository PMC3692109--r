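#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving edge switching on a simple undirected graph.
// edges: m x 2 integer matrix of 1-based endpoint indices (no loops, no
// duplicates). Picks two distinct edges uniformly, orients the second one
// uniformly, and rewires (u,v),(x,y) -> (u,y),(x,v) unless that creates a
// self-loop or multi-edge. Stops after n_swaps accepted swaps or
// max_attempts attempts, whichever comes first. Uses R's RNG stream.
// [[Rcpp::export]]
IntegerMatrix edge_switch_cpp(IntegerMatrix edges, int n_nodes,
                              double n_swaps, double max_attempts) {
  const int m = edges.nrow();
  std::vector<int> a(m), b(m);
  std::unordered_set<long long> present;
  const long long base = (long long)n_nodes + 1;
  auto key = [base](int u, int v) {
    if (u > v) std::swap(u, v);
    return (long long)u * base + v;
  };
  for (int i = 0; i < m; ++i) {
    a[i] = edges(i, 0);
    b[i] = edges(i, 1);
    present.insert(key(a[i], b[i]));
  }
  double done = 0, tries = 0;
  while (m >= 2 && done < n_swaps && tries < max_attempts) {
    ++tries;
    int e1 = (int)(unif_rand() * m); if (e1 == m) --e1;
    int e2 = (int)(unif_rand() * m); if (e2 == m) --e2;
    if (e1 == e2) continue;
    int u = a[e1], v = b[e1], x = a[e2], y = b[e2];
    if (unif_rand() < 0.5) std::swap(x, y);  // undirected: orientation uniform
    if (u == y || x == v) continue;          // self-loop
    long long k1 = key(u, y), k2 = key(x, v);
    if (k1 == k2) continue;                  // both new edges identical
    if (present.count(k1) || present.count(k2)) continue;  // multi-edge
    present.erase(key(u, v));
    present.erase(key(x, y));
    present.insert(k1);
    present.insert(k2);
    a[e1] = u; b[e1] = y;
    a[e2] = x; b[e2] = v;
    ++done;
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = a[i];
    out(i, 1) = b[i];
  }
  return out;
}
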