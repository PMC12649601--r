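#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact induced-subgraph census on 2..5 nodes via ESU (Wernicke's
// enumeration of connected induced subgraphs, each exactly once).
// Classification at the leaves is a table lookup: the subgraph's edge
// bitmask over the C(k,2) position pairs (combn order: (1,2),(1,3),...,
// i-major) indexes an R-built lookup vector mapping labeled masks to
// 0-based graphlet class ids.

namespace {

struct EsuState {
  int n, k;
  const std::vector<std::vector<int>>* adj;
  const std::vector<uint8_t>* adjmat;  // n*n, row-major
  const int* lookup;                   // lookup for current k (1-based mask+1 handled in R; here 0-based index = mask)
  std::vector<double>* counts;         // length 30
  std::vector<int> sub;
  std::vector<uint8_t> mark;           // in subgraph or neighborhood
  double enumerated;
  double max_subgraphs;
};

// bit position of pair (a, b), a < b, in combn(k, 2) order
inline int pair_bit(int a, int b, int k) {
  // pairs (0,1),(0,2),...,(0,k-1),(1,2),... ; a, b are 0-based positions
  return a * k - a * (a + 1) / 2 + (b - a - 1);
}

void classify_leaf(EsuState& st) {
  const int k = st.k;
  int mask = 0;
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      if ((*st.adjmat)[(size_t)st.sub[i] * st.n + st.sub[j]]) {
        mask |= 1 << pair_bit(i, j, k);
      }
    }
  }
  int cls = st.lookup[mask];  // class id, or NA handled as negative
  if (cls >= 0) (*st.counts)[cls] += 1.0;
}

void extend(EsuState& st, std::vector<int>& ext, int v_root) {
  if ((int)st.sub.size() == st.k) {
    st.enumerated += 1.0;
    if (st.enumerated > st.max_subgraphs) {
      stop("exact census aborted: more than %.0f connected subgraphs; "
           "use census_sampled() or raise max_subgraphs",
           st.max_subgraphs);
    }
    classify_leaf(st);
    return;
  }
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    // exclusive neighborhood of w w.r.t. current subgraph: unmarked neighbors
    std::vector<int> newly;
    for (int u : (*st.adj)[w]) {
      if (!st.mark[u]) {
        st.mark[u] = 1;
        newly.push_back(u);
      }
    }
    std::vector<int> ext2 = ext;
    for (int u : newly) if (u > v_root) ext2.push_back(u);
    st.sub.push_back(w);
    extend(st, ext2, v_root);
    st.sub.pop_back();
    for (int u : newly) st.mark[u] = 0;
  }
}

}  // namespace

// [[Rcpp::export(name = ".esu_census_cpp")]]
NumericVector esu_census_cpp(int n, IntegerMatrix edges, List lookups,
                             double max_subgraphs) {
  std::vector<std::vector<int>> adj(n);
  std::vector<uint8_t> adjmat((size_t)n * n, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);  // 0-based from R wrapper
    if (a == b || a < 0 || b < 0 || a >= n || b >= n)
      stop("invalid edge (%d, %d)", a + 1, b + 1);
    if (adjmat[(size_t)a * n + b]) stop("duplicate edge (%d, %d)", a + 1, b + 1);
    adjmat[(size_t)a * n + b] = adjmat[(size_t)b * n + a] = 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  std::vector<double> counts(30, 0.0);
  // lookups: list of integer vectors for k = 2..5; value = class id (0-based)
  // or NA for disconnected masks
  std::vector<std::vector<int>> luts;
  for (int k = 2; k <= 5; ++k) {
    IntegerVector lv = lookups[k - 2];
    std::vector<int> lut(lv.size());
    for (int i = 0; i < lv.size(); ++i) {
      lut[i] = (lv[i] == NA_INTEGER) ? -1 : lv[i];
    }
    luts.push_back(std::move(lut));
  }
  for (int k = 2; k <= 5 && k <= n; ++k) {
    EsuState st;
    st.n = n; st.k = k; st.adj = &adj; st.adjmat = &adjmat;
    st.lookup = luts[k - 2].data();
    st.counts = &counts;
    st.enumerated = 0.0;
    st.max_subgraphs = max_subgraphs;
    st.mark.assign(n, 0);
    for (int v = 0; v < n; ++v) {
      st.sub.assign(1, v);
      st.mark[v] = 1;
      std::vector<int> ext;
      std::vector<int> marked;
      for (int u : adj[v]) {
        st.mark[u] = 1;
        marked.push_back(u);
        if (u > v) ext.push_back(u);
      }
      extend(st, ext, v);
      st.mark[v] = 0;
      for (int u : marked) st.mark[u] = 0;
    }
  }
  return NumericVector(counts.begin(), counts.end());
}
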