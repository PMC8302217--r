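#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Graphs on up to 30 vertices are handled as bitmask adjacency lists:
// adj[i] has bit j set iff {i, j} is an edge. Vertex subsets are masks.

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// connected component of `seed` inside subset `verts`
static uint32_t component_of(const std::vector<uint32_t>& adj, uint32_t verts,
                             int seed) {
  uint32_t comp = 1u << seed;
  uint32_t frontier = comp;
  while (frontier) {
    uint32_t next = 0;
    uint32_t f = frontier;
    while (f) {
      int v = __builtin_ctz(f);
      f &= f - 1;
      next |= adj[v] & verts & ~comp;
    }
    comp |= next;
    frontier = next;
  }
  return comp;
}

// cograph test by recursive decomposition: a graph is a cograph iff every
// multi-vertex induced module splits into connected components or complement
// components (no prime module).
static bool cograph_rec(const std::vector<uint32_t>& adj, uint32_t verts,
                        bool complemented) {
  int n = popcount32(verts);
  if (n <= 1) return true;
  int seed = __builtin_ctz(verts);
  uint32_t rest = verts;
  bool split = false;
  // components of G (or of its complement when `complemented`)
  std::vector<uint32_t> cadj;
  const std::vector<uint32_t>* use = &adj;
  if (complemented) {
    cadj.resize(adj.size());
    for (size_t i = 0; i < adj.size(); ++i) {
      cadj[i] = (~adj[i]) & verts & ~(1u << (unsigned)i);
    }
    use = &cadj;
  }
  std::vector<uint32_t> comps;
  while (rest) {
    int s = __builtin_ctz(rest);
    uint32_t c = component_of(*use, rest, s);
    comps.push_back(c);
    rest &= ~c;
  }
  split = comps.size() > 1;
  if (!split) {
    if (complemented) return false; // connected in both G and complement: prime
    return cograph_rec(adj, verts, true);
  }
  for (uint32_t c : comps) {
    if (!cograph_rec(adj, c, false)) return false;
  }
  return true;
  (void)seed;
}

// [[Rcpp::export]]
bool cograph_check_masks(IntegerVector adj) {
  int n = adj.size();
  if (n > 30) stop("mask representation limited to 30 vertices");
  std::vector<uint32_t> a(n);
  for (int i = 0; i < n; ++i) a[i] = (uint32_t)adj[i];
  uint32_t verts = (n == 0) ? 0u : ((n == 32) ? ~0u : ((1u << n) - 1u));
  if (n == 0) return true;
  return cograph_rec(a, verts, false);
}

// induced-P4 search: for every 4-subset, the induced subgraph is a P4 iff it
// has exactly 3 edges with maximum degree 2 and minimum degree 1.
static bool has_induced_p4(const std::vector<uint32_t>& adj, int n) {
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      for (int c = b + 1; c < n; ++c)
        for (int d = c + 1; d < n; ++d) {
          uint32_t set = (1u << a) | (1u << b) | (1u << c) | (1u << d);
          int deg[4];
          int idx[4] = {a, b, c, d};
          int edges = 0;
          for (int k = 0; k < 4; ++k) {
            deg[k] = popcount32(adj[idx[k]] & set);
            edges += deg[k];
          }
          edges /= 2;
          if (edges != 3) continue;
          int mx = 0, mn = 4;
          for (int k = 0; k < 4; ++k) {
            if (deg[k] > mx) mx = deg[k];
            if (deg[k] < mn) mn = deg[k];
          }
          if (mx == 2 && mn == 1) return true;
        }
  return false;
}

// [[Rcpp::export]]
bool p4_free_masks(IntegerVector adj) {
  int n = adj.size();
  if (n > 30) stop("mask representation limited to 30 vertices");
  std::vector<uint32_t> a(n);
  for (int i = 0; i < n; ++i) a[i] = (uint32_t)adj[i];
  return !has_induced_p4(a, n);
}

// Exhaustive sweep over every labeled graph on n vertices comparing the
// decomposition-based cograph test with the induced-P4 oracle.
// Returns c(graphs, agreements, cographs_by_decomposition, p4_free_graphs).
// [[Rcpp::export]]
NumericVector sweep_cograph_agreement(int n) {
  if (n < 1 || n > 7) stop("sweep supported for 1 <= n <= 7");
  int m = n * (n - 1) / 2;
  uint64_t total = 1ull << m;
  // bit k of the graph code is edge (pair_i[k], pair_j[k])
  std::vector<int> pi(m), pj(m);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) { pi[k] = i; pj[k] = j; ++k; }
  uint64_t agree = 0, ncog = 0, nfree = 0;
  std::vector<uint32_t> adj(n);
  uint32_t verts = (1u << n) - 1u;
  for (uint64_t code = 0; code < total; ++code) {
    std::fill(adj.begin(), adj.end(), 0u);
    uint64_t c = code;
    for (int e = 0; e < m; ++e) {
      if (c & 1ull) {
        adj[pi[e]] |= 1u << pj[e];
        adj[pj[e]] |= 1u << pi[e];
      }
      c >>= 1;
    }
    bool dec = cograph_rec(adj, verts, false);
    bool free4 = !has_induced_p4(adj, n);
    if (dec == free4) ++agree;
    if (dec) ++ncog;
    if (free4) ++nfree;
  }
  return NumericVector::create((double)total, (double)agree,
                               (double)ncog, (double)nfree);
}
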