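#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// BottleNeck scores over all BFS shortest-path trees of an undirected graph.
//
// adj: 0-based adjacency list; vertices must be supplied in the order used
// for tie-breaking (lexicographic by name) and each neighbour vector sorted
// ascending, so that "smallest index" == "lexicographically smallest name".
// For every root r a BFS tree is built with parent(v) = smallest-index
// neighbour one step closer to r; v is a bottleneck for r when the number
// of nodes routing through it (its subtree size minus itself) is at least
// n_r / 4, n_r being the number of nodes of the tree. The score of v is the
// number of roots for which it is a bottleneck.
// [[Rcpp::export(name = ".bnScoresCpp")]]
IntegerVector bnScoresCpp(List adj) {
  const int n = adj.size();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
  }
  IntegerVector bn(n);
  std::vector<int> dist(n), parent(n), order;
  order.reserve(n);
  std::vector<long long> size(n);

  for (int r = 0; r < n; ++r) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(parent.begin(), parent.end(), -1);
    order.clear();
    std::queue<int> q;
    dist[r] = 0;
    q.push(r);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (int w : nb[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    const long long n_r = (long long) order.size();
    if (n_r < 2) continue;
    // lexicographic parent: smallest-index neighbour at dist - 1
    for (int v : order) {
      if (v == r) continue;
      for (int w : nb[v]) {
        if (dist[w] == dist[v] - 1) { parent[v] = w; break; }
      }
    }
    for (int v : order) size[v] = 1;
    // accumulate child subtree sizes bottom-up (reverse BFS order)
    for (int i = (int) order.size() - 1; i >= 0; --i) {
      int v = order[i];
      if (parent[v] >= 0) size[parent[v]] += size[v];
    }
    for (int v : order) {
      if (v == r) continue;
      if (4 * (size[v] - 1) >= n_r) bn[v] += 1;
    }
  }
  return bn;
}
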