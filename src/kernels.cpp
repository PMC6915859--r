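#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <set>
#include <queue>

using namespace Rcpp;

// Edge matrices are m x 2 integer matrices of 1-based node ids
// (column 1 = parent, column 2 = child).  Node ids may contain gaps;
// a node is "active" iff it appears in an edge.  `taxon` is indexed by
// node id (0 = unlabelled).

static void adjacency(const IntegerMatrix& E, int maxid,
                      std::vector<std::vector<int> >& ch,
                      std::vector<std::vector<int> >& pa,
                      std::vector<char>& active) {
  ch.assign(maxid + 1, std::vector<int>());
  pa.assign(maxid + 1, std::vector<int>());
  active.assign(maxid + 1, 0);
  int m = E.nrow();
  for (int i = 0; i < m; ++i) {
    int u = E(i, 0), v = E(i, 1);
    ch[u].push_back(v);
    pa[v].push_back(u);
    active[u] = active[v] = 1;
  }
}

// Reflexive reachability: out(u, v) is TRUE iff there is a directed
// path (possibly empty) from u to v.
// [[Rcpp::export(name = ".reach_matrix_cpp")]]
LogicalMatrix reach_matrix_cpp(IntegerMatrix E, int maxid) {
  std::vector<std::vector<int> > ch, pa;
  std::vector<char> active;
  adjacency(E, maxid, ch, pa, active);
  LogicalMatrix out(maxid, maxid);
  std::vector<int> stack;
  for (int u = 1; u <= maxid; ++u) {
    if (!active[u]) continue;
    stack.clear();
    stack.push_back(u);
    out(u - 1, u - 1) = TRUE;
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      for (size_t j = 0; j < ch[x].size(); ++j) {
        int y = ch[x][j];
        if (!out(u - 1, y - 1)) {
          out(u - 1, y - 1) = TRUE;
          stack.push_back(y);
        }
      }
    }
  }
  return out;
}

static bool path_counts_core(const IntegerMatrix& E,
                             const IntegerVector& taxon, int ntaxa,
                             std::vector<std::vector<long long> >& P,
                             std::vector<char>& active) {
  int maxid = taxon.size();
  std::vector<std::vector<int> > ch, pa;
  adjacency(E, maxid, ch, pa, active);
  P.assign(maxid + 1, std::vector<long long>(ntaxa, 0));
  std::vector<int> pending(maxid + 1, 0);
  std::queue<int> q;
  int nactive = 0;
  for (int v = 1; v <= maxid; ++v) {
    if (!active[v]) continue;
    ++nactive;
    pending[v] = (int) ch[v].size();
    if (pending[v] == 0) {
      int t = taxon[v - 1];
      if (t >= 1 && t <= ntaxa) P[v][t - 1] = 1;
      q.push(v);
    }
  }
  int done = 0;
  while (!q.empty()) {
    int v = q.front();
    q.pop();
    ++done;
    for (size_t j = 0; j < pa[v].size(); ++j) {
      int p = pa[v][j];
      for (int t = 0; t < ntaxa; ++t) P[p][t] += P[v][t];
      if (--pending[p] == 0) q.push(p);
    }
  }
  return done == nactive;  // false iff the digraph has a cycle
}

// Per-node counts of directed paths to each labelled leaf.
// [[Rcpp::export(name = ".path_counts_cpp")]]
IntegerMatrix path_counts_cpp(IntegerMatrix E, IntegerVector taxon, int ntaxa) {
  std::vector<std::vector<long long> > P;
  std::vector<char> active;
  if (!path_counts_core(E, taxon, ntaxa, P, active))
    stop("path counts undefined: the digraph contains a directed cycle");
  int maxid = taxon.size();
  IntegerMatrix out(maxid, ntaxa);
  for (int v = 1; v <= maxid; ++v)
    for (int t = 0; t < ntaxa; ++t)
      out(v - 1, t) = (int) P[v][t];
  return out;
}

static std::string vec_key(const std::vector<long long>& x) {
  std::string s;
  s.reserve(x.size() * 3);
  for (size_t i = 0; i < x.size(); ++i) {
    if (i) s.push_back(',');
    s += std::to_string(x[i]);
  }
  return s;
}

// Canonical code: the sorted multiset of per-node path-count vectors,
// concatenated with the sorted multiset of per-edge (parent, child)
// path-count vector pairs.  Invariant under any leaf-label-preserving
// isomorphism by construction.
// [[Rcpp::export(name = ".canon_code_cpp")]]
String canon_code_cpp(IntegerMatrix E, IntegerVector taxon, int ntaxa) {
  std::vector<std::vector<long long> > P;
  std::vector<char> active;
  if (!path_counts_core(E, taxon, ntaxa, P, active))
    stop("canonical code undefined: the digraph contains a directed cycle");
  int maxid = taxon.size();
  std::vector<std::string> nodekeys;
  for (int v = 1; v <= maxid; ++v)
    if (active[v]) nodekeys.push_back(vec_key(P[v]));
  std::sort(nodekeys.begin(), nodekeys.end());
  std::vector<std::string> edgekeys;
  int m = E.nrow();
  for (int i = 0; i < m; ++i) {
    std::string s = vec_key(P[E(i, 0)]);
    s.push_back('>');
    s += vec_key(P[E(i, 1)]);
    edgekeys.push_back(s);
  }
  std::sort(edgekeys.begin(), edgekeys.end());
  std::string out;
  for (size_t i = 0; i < nodekeys.size(); ++i) {
    if (i) out.push_back(';');
    out += nodekeys[i];
  }
  out.push_back('|');
  for (size_t i = 0; i < edgekeys.size(); ++i) {
    if (i) out.push_back(';');
    out += edgekeys[i];
  }
  return String(out);
}

struct IsoCtx {
  std::vector<std::vector<int> > ch1, pa1, ch2, pa2;
  std::vector<char> act1, act2;
  std::set<long long> e2;
  int maxid2;
  std::vector<int> map12, map21;
  std::vector<int> order;  // unmapped nodes of N1, BFS from root

  bool edge2(int a, int b) const {
    return e2.count((long long) a * (maxid2 + 1) + b) > 0;
  }

  bool consistent(int x, int c) {
    // x in N1 tentatively mapped to c; check all edges at x whose other
    // endpoint is already mapped.
    for (size_t j = 0; j < ch1[x].size(); ++j) {
      int y = map12[ch1[x][j]];
      if (y && !edge2(c, y)) return false;
    }
    for (size_t j = 0; j < pa1[x].size(); ++j) {
      int y = map12[pa1[x][j]];
      if (y && !edge2(y, c)) return false;
    }
    return true;
  }

  bool backtrack(size_t idx) {
    if (idx == order.size()) return true;
    int x = order[idx];
    int in1 = (int) pa1[x].size(), out1 = (int) ch1[x].size();
    for (int c = 1; c <= maxid2; ++c) {
      if (!act2[c] || map21[c]) continue;
      if ((int) pa2[c].size() != in1 || (int) ch2[c].size() != out1) continue;
      if (!consistent(x, c)) continue;
      map12[x] = c;
      map21[c] = x;
      if (backtrack(idx + 1)) return true;
      map12[x] = 0;
      map21[c] = 0;
    }
    return false;
  }
};

// Leaf-label-preserving isomorphism by backtracking, seeded by the
// forced leaf correspondence and the root.  Independent of the
// canonical code (degree signatures only are used for pruning).
// [[Rcpp::export(name = ".iso_cpp")]]
bool iso_cpp(IntegerMatrix E1, IntegerVector tax1,
             IntegerMatrix E2, IntegerVector tax2) {
  if (E1.nrow() != E2.nrow()) return false;
  int maxid1 = tax1.size(), maxid2 = tax2.size();
  IsoCtx cx;
  adjacency(E1, maxid1, cx.ch1, cx.pa1, cx.act1);
  adjacency(E2, maxid2, cx.ch2, cx.pa2, cx.act2);
  cx.maxid2 = maxid2;
  int n1 = 0, n2 = 0, root1 = 0, root2 = 0;
  std::vector<int> leaf2_of_taxon;  // taxon -> node in N2
  int maxtax = 0;
  for (int v = 1; v <= maxid1; ++v)
    if (cx.act1[v] && tax1[v - 1] > maxtax) maxtax = tax1[v - 1];
  for (int v = 1; v <= maxid2; ++v)
    if (cx.act2[v] && tax2[v - 1] > maxtax) maxtax = tax2[v - 1];
  leaf2_of_taxon.assign(maxtax + 1, 0);
  for (int v = 1; v <= maxid1; ++v) {
    if (!cx.act1[v]) continue;
    ++n1;
    if (cx.pa1[v].empty()) {
      if (root1) return false;
      root1 = v;
    }
  }
  for (int v = 1; v <= maxid2; ++v) {
    if (!cx.act2[v]) continue;
    ++n2;
    if (cx.pa2[v].empty()) {
      if (root2) return false;
      root2 = v;
    }
  }
  if (n1 != n2 || !root1 || !root2) return false;
  for (int i = 0; i < E2.nrow(); ++i)
    cx.e2.insert((long long) E2(i, 0) * (maxid2 + 1) + E2(i, 1));
  cx.map12.assign(maxid1 + 1, 0);
  cx.map21.assign(maxid2 + 1, 0);
  // forced: leaves by label, root to root
  for (int v = 1; v <= maxid2; ++v)
    if (cx.act2[v] && tax2[v - 1] > 0) {
      if (leaf2_of_taxon[tax2[v - 1]]) return false;  // duplicate label
      leaf2_of_taxon[tax2[v - 1]] = v;
    }
  for (int v = 1; v <= maxid1; ++v) {
    if (!cx.act1[v] || tax1[v - 1] == 0) continue;
    int w = leaf2_of_taxon[tax1[v - 1]];
    if (!w) return false;
    cx.map12[v] = w;
    cx.map21[w] = v;
  }
  if (cx.map12[root1] == 0) {
    cx.map12[root1] = root2;
    cx.map21[root2] = root1;
  } else if (cx.map12[root1] != root2) {
    return false;
  }
  // BFS order over remaining nodes of N1 for strong propagation
  std::vector<char> seen(maxid1 + 1, 0);
  std::queue<int> q;
  q.push(root1);
  seen[root1] = 1;
  while (!q.empty()) {
    int x = q.front();
    q.pop();
    if (!cx.map12[x]) cx.order.push_back(x);
    for (size_t j = 0; j < cx.ch1[x].size(); ++j) {
      int y = cx.ch1[x][j];
      if (!seen[y]) {
        seen[y] = 1;
        q.push(y);
      }
    }
  }
  // verify forced assignments are themselves consistent
  for (int v = 1; v <= maxid1; ++v)
    if (cx.act1[v] && cx.map12[v] && !cx.consistent(v, cx.map12[v]))
      return false;
  return cx.backtrack(0);
}
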