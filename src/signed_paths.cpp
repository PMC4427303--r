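// Exact signed simple-path and simple-cycle search on small directed
// graphs (<= ~40 nodes). Path semantics are required: the sign of a walk
// through a negative cycle differs from any simple path's sign, so plain
// matrix reachability cannot replace the depth-first enumeration here.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Adj {
  std::vector<std::vector<int>> to;
  std::vector<std::vector<int>> sgn;
  Adj(int n, const IntegerVector& from, const IntegerVector& tov,
      const IntegerVector& sign)
      : to(n), sgn(n) {
    for (int e = 0; e < from.size(); ++e) {
      to[from[e] - 1].push_back(tov[e] - 1);
      sgn[from[e] - 1].push_back(sign[e]);
    }
  }
};

void cycle_dfs(const Adj& adj, int root, int v, int sign,
               std::vector<char>& visited, std::vector<int>& path,
               std::vector<char>& on_neg) {
  visited[v] = 1;
  path.push_back(v);
  const auto& nb = adj.to[v];
  const auto& ns = adj.sgn[v];
  for (size_t k = 0; k < nb.size(); ++k) {
    int w = nb[k];
    int s2 = sign * ns[k];
    if (w == root) {
      if (s2 < 0)
        for (int u : path) on_neg[u] = 1;
    } else if (w > root && !visited[w]) {
      cycle_dfs(adj, root, w, s2, visited, path, on_neg);
    }
  }
  visited[v] = 0;
  path.pop_back();
}

void path_dfs(const Adj& adj, int v, int sign, bool touched,
              const std::vector<char>& nfb, std::vector<char>& visited,
              std::vector<char>& pos, std::vector<char>& neg,
              std::vector<char>& via) {
  visited[v] = 1;
  const auto& nb = adj.to[v];
  const auto& ns = adj.sgn[v];
  for (size_t k = 0; k < nb.size(); ++k) {
    int w = nb[k];
    if (visited[w]) continue;
    int s2 = sign * ns[k];
    bool t2 = touched || nfb[w];
    if (s2 > 0) pos[w] = 1; else neg[w] = 1;
    if (t2) via[w] = 1;
    path_dfs(adj, w, s2, t2, nfb, visited, pos, neg, via);
  }
  visited[v] = 0;
}

}  // namespace

// Nodes lying on at least one simple directed cycle with negative
// edge-sign product. Each cycle is rooted at its minimum-index node.
// [[Rcpp::export(name = ".neg_cycle_nodes_cpp")]]
LogicalVector neg_cycle_nodes_cpp(int n, IntegerVector from,
                                  IntegerVector to, IntegerVector sign) {
  Adj adj(n, from, to, sign);
  std::vector<char> on_neg(n, 0), visited(n, 0);
  std::vector<int> path;
  for (int root = 0; root < n; ++root)
    cycle_dfs(adj, root, root, 1, visited, path, on_neg);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = on_neg[i] != 0;
  return out;
}

// For one source node: per target, whether a positive / negative simple
// path exists and whether any simple path touches a node of `nfb`
// (endpoints count). Returns a 3 x n logical matrix (pos, neg, via_nfb).
// [[Rcpp::export(name = ".path_profile_cpp")]]
LogicalMatrix path_profile_cpp(int n, IntegerVector from, IntegerVector to,
                               IntegerVector sign, int src,
                               LogicalVector nfb) {
  Adj adj(n, from, to, sign);
  std::vector<char> nfbv(n, 0);
  for (int i = 0; i < n; ++i) nfbv[i] = nfb[i] ? 1 : 0;
  std::vector<char> visited(n, 0), pos(n, 0), neg(n, 0), via(n, 0);
  path_dfs(adj, src - 1, 1, nfbv[src - 1], nfbv, visited, pos, neg, via);
  LogicalMatrix out(3, n);
  for (int i = 0; i < n; ++i) {
    out(0, i) = pos[i] != 0;
    out(1, i) = neg[i] != 0;
    out(2, i) = via[i] != 0;
  }
  return out;
}
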