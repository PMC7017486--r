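#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Side graph of a bidirected sequence graph: vertices are node sides
// (1-based; left = 2*id-1, right = 2*id), connected by node-traversal edges
// (s <-> opposite(s)) and by the adjacency edges passed in `adj`.
//
// Separability of a side pair {x, y}: remove ALL edges (node and adjacency)
// incident to x' and y' (the opposite sides of x and y); the pair is
// separable iff the component X containing x also contains y and every side
// of X other than x and y keeps at least one incident adjacency edge, i.e.
// the only ways in or out of X are through x and y.

static inline int opp(int s) { return (s % 2 == 1) ? s + 1 : s - 1; }

// Returns the component X (1-based side ids) when {x,y} is separable,
// otherwise an empty vector.
static std::vector<int> separable_component(const std::vector<std::vector<int>> &adj,
                                            int nsides, int x, int y) {
  std::vector<int> comp;
  if (x == y || ((x + 1) / 2) == ((y + 1) / 2)) return comp; // same node
  int xo = opp(x), yo = opp(y);
  std::vector<char> seen(nsides + 1, 0);
  std::vector<int> stack;
  stack.push_back(x);
  seen[x] = 1;
  bool ok = true;
  while (!stack.empty()) {
    int s = stack.back();
    stack.pop_back();
    comp.push_back(s);
    // node-traversal edge s -- opp(s), unless incident to xo or yo
    int t = opp(s);
    if (s != xo && s != yo && t != xo && t != yo && !seen[t]) {
      seen[t] = 1;
      stack.push_back(t);
    }
    // adjacency edges
    bool has_adj = false;
    for (int u : adj[s]) {
      if (s == xo || s == yo || u == xo || u == yo) continue;
      has_adj = true;
      if (!seen[u]) {
        seen[u] = 1;
        stack.push_back(u);
      }
    }
    if (!has_adj && s != x && s != y) ok = false; // internal tip: X leaks
  }
  if (!ok || !seen[y]) comp.clear();
  return comp;
}

static std::vector<std::vector<int>> build_adj(int nsides, const IntegerMatrix &edges) {
  std::vector<std::vector<int>> adj(nsides + 1);
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0), b = edges(i, 1);
    adj[a].push_back(b);
    if (b != a) adj[b].push_back(a);
  }
  return adj;
}

// [[Rcpp::export]]
IntegerVector cpp_separable(int nsides, IntegerMatrix edges, int x, int y) {
  auto adj = build_adj(nsides, edges);
  std::vector<int> comp = separable_component(adj, nsides, x, y);
  return wrap(comp);
}

// Batch separability over a list of candidate pairs.
// [[Rcpp::export]]
LogicalVector cpp_sep_pairs(int nsides, IntegerMatrix edges, IntegerMatrix pairs) {
  auto adj = build_adj(nsides, edges);
  int n = pairs.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = !separable_component(adj, nsides, pairs(i, 0), pairs(i, 1)).empty();
  }
  return out;
}
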