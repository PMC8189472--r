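// Core parsimony kernel: Fitch scoring on unrooted binary trees,
// stepwise-addition starting trees, NNI/SPR/TBR hill climbing with
// hold-k retention, and a suboptimal-retention pool used for Bremer
// (decay) support.  Trees cross the R boundary as ape-style rooted
// edge matrices (tips 1..n, root n+1); internally everything is an
// unrooted adjacency structure.  State sets are integer bitmasks;
// missing cells must already be expanded to the full per-character
// alphabet mask on the R side.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- UTree

struct UTree {
  int nTip;
  // 3 adjacency slots per node; -1 = unused.  Leaves 0..nTip-1 use one
  // slot, internal nodes nTip..2*nTip-3 use three.
  std::vector<int> adj;
  explicit UTree(int n) : nTip(n), adj(3 * (2 * n - 2), -1) {}
  int nNode() const { return 2 * nTip - 2; }
};

static inline void slot_add(UTree &t, int a, int b) {
  for (int s = 0; s < 3; ++s)
    if (t.adj[3 * a + s] == -1) { t.adj[3 * a + s] = b; return; }
  stop("internal error: node has no free adjacency slot");
}
static inline void add_edge(UTree &t, int a, int b) {
  slot_add(t, a, b); slot_add(t, b, a);
}
static inline void slot_del(UTree &t, int a, int b) {
  for (int s = 0; s < 3; ++s)
    if (t.adj[3 * a + s] == b) { t.adj[3 * a + s] = -1; return; }
  stop("internal error: edge to delete not found");
}
static inline void del_edge(UTree &t, int a, int b) {
  slot_del(t, a, b); slot_del(t, b, a);
}
static inline int first_neighbor(const UTree &t, int a) {
  for (int s = 0; s < 3; ++s)
    if (t.adj[3 * a + s] != -1) return t.adj[3 * a + s];
  return -1;
}

// Deterministic edge list: scan nodes ascending, slots ascending, emit
// (a, b) once with the orientation met first.
static std::vector<std::pair<int,int>> edge_list(const UTree &t) {
  std::vector<std::pair<int,int>> e;
  int n = t.nNode();
  for (int a = 0; a < n; ++a)
    for (int s = 0; s < 3; ++s) {
      int b = t.adj[3 * a + s];
      if (b > a) e.push_back({a, b});
    }
  return e;
}

// ---------------------------------------------------------- Fitch score

// Weighted Fitch length of the unrooted tree, scored by rooting at the
// pendant edge of `anchor` (a leaf present in the tree).  If ub >= 0
// and perChar == nullptr, aborts early once the running total exceeds
// ub and returns a value > ub.
static long fitch_score(const UTree &t, int anchor, const IntegerMatrix &tips,
                        const IntegerVector &w, long ub,
                        std::vector<int> &S, std::vector<int> &po,
                        std::vector<int> &par, IntegerVector *perChar) {
  const int nChar = tips.ncol();
  const int nN = t.nNode();
  if ((int)S.size() < nN * nChar) S.resize((size_t)nN * nChar);
  po.clear();
  if ((int)par.size() < nN) par.resize(nN);

  int r = first_neighbor(t, anchor);
  if (r < 0) stop("anchor leaf is not attached");

  // iterative DFS establishing postorder over all nodes except anchor
  std::vector<int> stack; stack.push_back(r); par[r] = anchor;
  std::vector<int> pre; pre.reserve(nN);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    pre.push_back(v);
    for (int s = 0; s < 3; ++s) {
      int u = t.adj[3 * v + s];
      if (u != -1 && u != par[v]) { par[u] = v; stack.push_back(u); }
    }
  }
  po.assign(pre.rbegin(), pre.rend());

  long steps = 0;
  for (size_t i = 0; i < po.size(); ++i) {
    int v = po[i];
    if (v < t.nTip) {
      for (int k = 0; k < nChar; ++k) S[(size_t)v * nChar + k] = tips(v, k);
      continue;
    }
    // internal: exactly two children (neighbors != parent)
    int c1 = -1, c2 = -1;
    for (int s = 0; s < 3; ++s) {
      int u = t.adj[3 * v + s];
      if (u != -1 && u != par[v]) { if (c1 == -1) c1 = u; else c2 = u; }
    }
    const int *A = &S[(size_t)c1 * nChar];
    const int *B = &S[(size_t)c2 * nChar];
    int *V = &S[(size_t)v * nChar];
    if (perChar) {
      for (int k = 0; k < nChar; ++k) {
        int x = A[k] & B[k];
        if (x == 0) { x = A[k] | B[k]; (*perChar)[k] += w[k]; steps += w[k]; }
        V[k] = x;
      }
    } else {
      for (int k = 0; k < nChar; ++k) {
        int x = A[k] & B[k];
        if (x == 0) { x = A[k] | B[k]; steps += w[k]; }
        V[k] = x;
      }
      if (ub >= 0 && steps > ub) return steps;
    }
  }
  // close the root edge against the anchor leaf
  const int *A = &S[(size_t)r * nChar];
  for (int k = 0; k < nChar; ++k) {
    if ((A[k] & tips(anchor, k)) == 0) {
      steps += w[k];
      if (perChar) (*perChar)[k] += w[k];
    }
  }
  return steps;
}

// ------------------------------------------------------- canonical key

typedef std::vector<uint64_t> SplitKey;

// Key = sorted list of internal-edge splits, each split encoded as the
// leaf bitmask of the side NOT containing leaf `ref` (ref = smallest
// leaf present).
static SplitKey splits_key(const UTree &t, std::vector<int> &par) {
  int ref = -1;
  for (int i = 0; i < t.nTip; ++i)
    if (first_neighbor(t, i) != -1) { ref = i; break; }
  const int words = (t.nTip + 63) / 64;
  const int nN = t.nNode();
  if ((int)par.size() < nN) par.resize(nN);
  std::vector<uint64_t> mask((size_t)nN * words, 0);
  int r = first_neighbor(t, ref);
  std::vector<int> stack; stack.push_back(r); par[r] = ref;
  std::vector<int> pre;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back(); pre.push_back(v);
    for (int s = 0; s < 3; ++s) {
      int u = t.adj[3 * v + s];
      if (u != -1 && u != par[v]) { par[u] = v; stack.push_back(u); }
    }
  }
  std::vector<SplitKey> parts;
  for (auto it = pre.rbegin(); it != pre.rend(); ++it) {
    int v = *it;
    if (v < t.nTip) {
      mask[(size_t)v * words + v / 64] |= (uint64_t)1 << (v % 64);
    } else {
      for (int s = 0; s < 3; ++s) {
        int u = t.adj[3 * v + s];
        if (u != -1 && u != par[v])
          for (int wd = 0; wd < words; ++wd)
            mask[(size_t)v * words + wd] |= mask[(size_t)u * words + wd];
      }
    }
    if (v >= t.nTip && par[v] >= t.nTip) {  // internal edge (par[v], v)
      SplitKey k(mask.begin() + (size_t)v * words,
                 mask.begin() + (size_t)v * words + words);
      parts.push_back(k);
    }
  }
  std::sort(parts.begin(), parts.end());
  SplitKey key;
  for (auto &p : parts) key.insert(key.end(), p.begin(), p.end());
  return key;
}

// ------------------------------------------------- R <-> C++ conversion

// Build a UTree from an ape-style rooted edge matrix (1-based; tips
// 1..nTip).  A binary root (degree 2) is suppressed.
static UTree from_ape(const IntegerMatrix &edge, int nTip) {
  int maxId = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    maxId = std::max(maxId, std::max(edge(i, 0), edge(i, 1)));
  std::vector<int> map(maxId + 1, -1);
  for (int i = 1; i <= nTip; ++i) map[i] = i - 1;
  int nextInternal = nTip;
  UTree t(nTip);
  std::vector<int> deg(maxId + 1, 0);
  for (int i = 0; i < edge.nrow(); ++i) { deg[edge(i, 0)]++; deg[edge(i, 1)]++; }
  int root = nTip + 1;  // ape convention
  bool suppress = (root <= maxId && deg[root] == 2);
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0), b = edge(i, 1);
    for (int id : {a, b})
      if (map[id] == -1) {
        if (suppress && id == root) continue;
        map[id] = nextInternal++;
      }
  }
  if (suppress) {
    int c1 = -1, c2 = -1;
    std::vector<std::pair<int,int>> kept;
    for (int i = 0; i < edge.nrow(); ++i) {
      int a = edge(i, 0), b = edge(i, 1);
      if (a == root) { (c1 == -1 ? c1 : c2) = map[b]; continue; }
      kept.push_back({map[a], map[b]});
    }
    for (auto &e : kept) add_edge(t, e.first, e.second);
    add_edge(t, c1, c2);
  } else {
    for (int i = 0; i < edge.nrow(); ++i)
      add_edge(t, map[edge(i, 0)], map[edge(i, 1)]);
  }
  return t;
}

// Emit an ape-style rooted edge matrix, rooting on the pendant edge of
// leaf `og` (0-based): root children are og and the rest of the tree.
// Preorder ("cladewise") edge ordering.
static IntegerMatrix to_ape(const UTree &t, int og) {
  int nTip = t.nTip;
  int nEdge = 2 * nTip - 2;  // rooted binary with degree-2 root
  IntegerMatrix edge(nEdge, 2);
  int r = first_neighbor(t, og);
  int rootId = nTip + 1;
  int nextId = nTip + 2;
  int row = 0;
  edge(row, 0) = rootId; edge(row, 1) = og + 1; ++row;
  // DFS preorder from r with parent og; edge emitted on visit, so the
  // output is "cladewise" in ape's sense
  struct Frame { int v, p, parentId; };
  std::vector<Frame> stack;
  stack.push_back({r, og, rootId});
  while (!stack.empty()) {
    Frame fr = stack.back(); stack.pop_back();
    int myId = (fr.v < nTip) ? fr.v + 1 : nextId++;
    edge(row, 0) = fr.parentId; edge(row, 1) = myId; ++row;
    std::vector<int> kids;
    for (int s = 0; s < 3; ++s) {
      int u = t.adj[3 * fr.v + s];
      if (u != -1 && u != fr.p) kids.push_back(u);
    }
    for (auto it = kids.rbegin(); it != kids.rend(); ++it)
      stack.push_back({*it, fr.v, myId});
  }
  return edge;
}

// ------------------------------------------------- neighbor enumeration

// Visit every neighbor of t under the given swap mode (0 = NNI,
// 1 = SPR, 2 = TBR).  The visitor sees t temporarily mutated; it must
// not keep references.  Returning false stops the enumeration.
template <typename F>
static void for_neighbors(UTree &t, int mode, F f) {
  std::vector<std::pair<int,int>> edges = edge_list(t);
  bool go = true;

  if (mode == 0) {  // NNI across each internal edge
    for (auto &e : edges) {
      if (!go) return;
      int u = e.first, v = e.second;
      if (u < t.nTip || v < t.nTip) continue;
      int un[2], vn[2], iu = 0, iv = 0;
      for (int s = 0; s < 3; ++s) {
        int x = t.adj[3 * u + s];
        if (x != -1 && x != v) un[iu++] = x;
        int y = t.adj[3 * v + s];
        if (y != -1 && y != u) vn[iv++] = y;
      }
      for (int j = 0; j < 2; ++j) {
        del_edge(t, u, un[0]); del_edge(t, v, vn[j]);
        add_edge(t, u, vn[j]); add_edge(t, v, un[0]);
        go = f(t);
        del_edge(t, u, vn[j]); del_edge(t, v, un[0]);
        add_edge(t, u, un[0]); add_edge(t, v, vn[j]);
        if (!go) return;
      }
    }
    return;
  }

  for (auto &e : edges) {
    if (!go) return;
    int u = e.first, v = e.second;
    bool uLeaf = u < t.nTip, vLeaf = v < t.nTip;
    if (uLeaf && vLeaf) continue;  // 2-taxon tree: no moves

    if (uLeaf || vLeaf) {
      // leaf regraft (the pendant-edge case of SPR/TBR)
      int leaf = uLeaf ? u : v, hub = uLeaf ? v : u;
      int x = -1, y = -1;
      for (int s = 0; s < 3; ++s) {
        int w2 = t.adj[3 * hub + s];
        if (w2 != -1 && w2 != leaf) { (x == -1 ? x : y) = w2; }
      }
      del_edge(t, leaf, hub); del_edge(t, hub, x); del_edge(t, hub, y);
      add_edge(t, x, y);
      std::vector<std::pair<int,int>> e2 = edge_list(t);
      for (auto &g : e2) {
        if ((g.first == std::min(x, y) && g.second == std::max(x, y)))
          continue;  // would rebuild the original tree
        del_edge(t, g.first, g.second);
        add_edge(t, g.first, hub); add_edge(t, hub, g.second);
        add_edge(t, leaf, hub);
        go = f(t);
        del_edge(t, leaf, hub);
        del_edge(t, g.first, hub); del_edge(t, hub, g.second);
        add_edge(t, g.first, g.second);
        if (!go) break;
      }
      del_edge(t, x, y);
      add_edge(t, hub, x); add_edge(t, hub, y); add_edge(t, leaf, hub);
      if (!go) return;
      continue;
    }

    // internal edge: bisect, suppress endpoints, reconnect across all
    // (TBR) or attachment-preserving (SPR) edge pairs
    int u1 = -1, u2 = -1, v1 = -1, v2 = -1;
    for (int s = 0; s < 3; ++s) {
      int x = t.adj[3 * u + s];
      if (x != -1 && x != v) { (u1 == -1 ? u1 : u2) = x; }
      int y = t.adj[3 * v + s];
      if (y != -1 && y != u) { (v1 == -1 ? v1 : v2) = y; }
    }
    del_edge(t, u, v);
    del_edge(t, u, u1); del_edge(t, u, u2); add_edge(t, u1, u2);
    del_edge(t, v, v1); del_edge(t, v, v2); add_edge(t, v1, v2);

    // collect fragment node sets by DFS
    std::vector<char> inA(t.nNode(), 0);
    { std::vector<int> st; st.push_back(u1); inA[u1] = 1;
      while (!st.empty()) {
        int a = st.back(); st.pop_back();
        for (int s = 0; s < 3; ++s) {
          int b = t.adj[3 * a + s];
          if (b != -1 && !inA[b]) { inA[b] = 1; st.push_back(b); }
        }
      } }
    std::vector<std::pair<int,int>> eA, eB;
    for (auto &g : edge_list(t)) (inA[g.first] ? eA : eB).push_back(g);
    std::pair<int,int> origA{std::min(u1, u2), std::max(u1, u2)};
    std::pair<int,int> origB{std::min(v1, v2), std::max(v1, v2)};

    for (auto &ga : eA) {
      if (!go) break;
      bool aOrig = (ga == origA);
      for (auto &gb : eB) {
        bool bOrig = (gb == origB);
        if (aOrig && bOrig) continue;          // original tree
        if (mode == 1 && !aOrig && !bOrig) continue;  // SPR keeps one side
        del_edge(t, ga.first, ga.second);
        add_edge(t, ga.first, u); add_edge(t, u, ga.second);
        del_edge(t, gb.first, gb.second);
        add_edge(t, gb.first, v); add_edge(t, v, gb.second);
        add_edge(t, u, v);
        go = f(t);
        del_edge(t, u, v);
        del_edge(t, ga.first, u); del_edge(t, u, ga.second);
        add_edge(t, ga.first, ga.second);
        del_edge(t, gb.first, v); del_edge(t, v, gb.second);
        add_edge(t, gb.first, gb.second);
        if (!go) break;
      }
    }
    del_edge(t, u1, u2); del_edge(t, v1, v2);
    add_edge(t, u, u1); add_edge(t, u, u2);
    add_edge(t, v, v1); add_edge(t, v, v2);
    add_edge(t, u, v);
    if (!go) return;
  }
}

// ------------------------------------------------------- hill climbing

struct Workspace {
  std::vector<int> S, po, par;
};

struct TreePool {
  std::map<SplitKey, std::pair<UTree, long>> trees;
  size_t cap;
  explicit TreePool(size_t c) : cap(c) {}
  bool add(const UTree &t, long len, std::vector<int> &par) {
    if (trees.size() >= cap) return false;
    SplitKey k = splits_key(t, par);
    auto it = trees.find(k);
    if (it == trees.end()) { trees.emplace(k, std::make_pair(t, len)); return true; }
    if (len < it->second.second) it->second.second = len;
    return false;
  }
};

// Hill-climb t to a local optimum (first-improvement, deterministic
// order), then gather up to holdK equally short trees by plateau BFS.
// If pool != nullptr, every evaluated tree within poolThresh is
// recorded.  Returns the local optimum length; `held` receives the
// retained trees.
static long hill_climb(UTree &t, const IntegerMatrix &tips,
                       const IntegerVector &w, int mode, int holdK,
                       Workspace &ws,
                       std::map<SplitKey, UTree> &held,
                       TreePool *pool, long poolThresh) {
  int anchor = 0;
  while (first_neighbor(t, anchor) == -1) ++anchor;
  long L = fitch_score(t, anchor, tips, w, -1, ws.S, ws.po, ws.par, nullptr);

  // NB: the visitor's argument aliases the tree being swapped, and the
  // enumerator reverts each move after the visit, so an accepted
  // neighbor must be copied out before returning
  bool improved = true;
  UTree cand = t;
  while (improved) {
    improved = false;
    long ub = pool ? std::max(L, poolThresh) : L;
    for_neighbors(t, mode, [&](UTree &nb) -> bool {
      long s = fitch_score(nb, anchor, tips, w, ub, ws.S, ws.po, ws.par, nullptr);
      if (pool && s <= poolThresh) pool->add(nb, s, ws.par);
      if (s < L) { cand = nb; L = s; improved = true; return false; }
      return true;
    });
    if (improved) t = cand;
  }

  // plateau exploration at the optimum length
  held.clear();
  std::vector<UTree> queue;
  held.emplace(splits_key(t, ws.par), t);
  queue.push_back(t);
  bool restart = false;
  while (!queue.empty() && (int)held.size() < holdK) {
    UTree cur = queue.back(); queue.pop_back();
    for_neighbors(cur, mode, [&](UTree &nb) -> bool {
      long s = fitch_score(nb, anchor, tips, w,
                           pool ? std::max(L, poolThresh) : L,
                           ws.S, ws.po, ws.par, nullptr);
      if (pool && s <= poolThresh) pool->add(nb, s, ws.par);
      if (s < L) { cand = nb; restart = true; return false; }
      if (s == L && (int)held.size() < holdK) {
        SplitKey k = splits_key(nb, ws.par);
        if (held.find(k) == held.end()) {
          held.emplace(k, nb);
          queue.push_back(nb);
        }
      }
      return (int)held.size() < holdK;
    });
    if (restart) {
      t = cand;
      return hill_climb(t, tips, w, mode, holdK, ws, held, pool, poolThresh);
    }
  }
  return L;
}

// ---------------------------------------------------- stepwise addition

static UTree addition_tree(const IntegerMatrix &tips, const IntegerVector &w,
                           const std::vector<int> &order, Workspace &ws) {
  int nTip = tips.nrow();
  if (nTip < 3) stop("stepwise addition needs at least 3 taxa");
  UTree t(nTip);
  int hub = nTip;  // first internal node
  add_edge(t, order[0], hub); add_edge(t, order[1], hub); add_edge(t, order[2], hub);
  int anchor = order[0];
  int nextInternal = nTip + 1;
  for (int k = 3; k < nTip; ++k) {
    int x = order[k];
    int m = nextInternal++;
    std::vector<std::pair<int,int>> edges = edge_list(t);
    long best = -1; int bestIdx = -1;
    for (size_t i = 0; i < edges.size(); ++i) {
      int a = edges[i].first, b = edges[i].second;
      del_edge(t, a, b);
      add_edge(t, a, m); add_edge(t, m, b); add_edge(t, m, x);
      long s = fitch_score(t, anchor, tips, w, best, ws.S, ws.po, ws.par, nullptr);
      del_edge(t, m, x); del_edge(t, a, m); del_edge(t, m, b);
      add_edge(t, a, b);
      if (best < 0 || s < best) { best = s; bestIdx = (int)i; }
    }
    int a = edges[bestIdx].first, b = edges[bestIdx].second;
    del_edge(t, a, b);
    add_edge(t, a, m); add_edge(t, m, b); add_edge(t, m, x);
  }
  return t;
}

// ------------------------------------------------------------- exports

// [[Rcpp::export]]
List fitch_counts_cpp(IntegerMatrix edge, int nTip, IntegerMatrix tips,
                      IntegerVector weights) {
  if (nTip < 2) stop("need at least 2 tips");
  if (nTip == 2) {
    IntegerVector pc(tips.ncol());
    long tot = 0;
    for (int k = 0; k < tips.ncol(); ++k)
      if ((tips(0, k) & tips(1, k)) == 0) { pc[k] = weights[k]; tot += weights[k]; }
    return List::create(_["perChar"] = pc, _["total"] = (double)tot);
  }
  UTree t = from_ape(edge, nTip);
  Workspace ws;
  IntegerVector pc(tips.ncol());
  int anchor = 0;
  while (first_neighbor(t, anchor) == -1) ++anchor;
  long tot = fitch_score(t, anchor, tips, weights, -1, ws.S, ws.po, ws.par, &pc);
  return List::create(_["perChar"] = pc, _["total"] = (double)tot);
}

// [[Rcpp::export]]
IntegerMatrix addition_tree_cpp(IntegerMatrix tips, IntegerVector weights,
                                IntegerVector order, int og) {
  int nTip = tips.nrow();
  std::vector<int> ord(order.begin(), order.end());
  for (auto &x : ord) --x;
  Workspace ws;
  UTree t = addition_tree(tips, weights, ord, ws);
  return to_ape(t, og - 1);
}

static List pack_results(std::map<SplitKey, UTree> &pool, long bestLen, int og,
                         IntegerVector repBest) {
  List trees(pool.size());
  int i = 0;
  for (auto &kv : pool) trees[i++] = to_ape(kv.second, og - 1);
  return List::create(_["trees"] = trees, _["bestLength"] = (double)bestLen,
                      _["replicateBest"] = repBest);
}

// [[Rcpp::export]]
List search_cpp(IntegerMatrix tips, IntegerVector weights, IntegerMatrix orders,
                int mode, int holdK, int maxPool, int og) {
  int nTip = tips.nrow();
  int nRep = orders.nrow();
  Workspace ws;
  std::map<SplitKey, UTree> best;  // pooled across replicates
  long bestLen = -1;
  IntegerVector repBest(nRep);
  for (int r = 0; r < nRep; ++r) {
    std::vector<int> ord(nTip);
    for (int i = 0; i < nTip; ++i) ord[i] = orders(r, i) - 1;
    UTree t = addition_tree(tips, weights, ord, ws);
    std::map<SplitKey, UTree> held;
    long L = hill_climb(t, tips, weights, mode, holdK, ws, held, nullptr, -1);
    repBest[r] = (int)L;
    if (bestLen < 0 || L < bestLen) { bestLen = L; best.clear(); }
    if (L == bestLen)
      for (auto &kv : held) {
        if ((int)best.size() >= maxPool) break;
        best.emplace(kv.first, kv.second);
      }
    Rcpp::checkUserInterrupt();
  }
  return pack_results(best, bestLen, og, repBest);
}

// [[Rcpp::export]]
List swap_from_cpp(IntegerMatrix edge, int nTip, IntegerMatrix tips,
                   IntegerVector weights, int mode, int holdK, int og) {
  UTree t = from_ape(edge, nTip);
  Workspace ws;
  std::map<SplitKey, UTree> held;
  long L = hill_climb(t, tips, weights, mode, holdK, ws, held, nullptr, -1);
  IntegerVector repBest(1); repBest[0] = (int)L;
  return pack_results(held, L, og, repBest);
}

// Breadth-limited suboptimal-retention search: starting from the given
// trees (assumed optimal or near-optimal), repeatedly expand pooled
// trees by TBR, retaining every distinct topology whose length is at
// most bestLen + maxExtra.  Used for Bremer support.
// [[Rcpp::export]]
List retain_pool_cpp(List startEdges, int nTip, IntegerMatrix tips,
                     IntegerVector weights, int maxExtra, int maxPool,
                     int maxExpand, int og) {
  Workspace ws;
  TreePool pool((size_t)maxPool);
  int anchor = 0;
  long bestLen = -1;
  std::vector<SplitKey> order;  // expansion frontier, insertion order
  for (int i = 0; i < startEdges.size(); ++i) {
    UTree t = from_ape(as<IntegerMatrix>(startEdges[i]), nTip);
    long L = fitch_score(t, anchor, tips, weights, -1, ws.S, ws.po, ws.par, nullptr);
    if (bestLen < 0 || L < bestLen) bestLen = L;
    if (pool.add(t, L, ws.par)) order.push_back(splits_key(t, ws.par));
  }
  long thresh = bestLen + maxExtra;
  std::map<SplitKey, char> expanded;
  int nExpanded = 0;
  size_t cursor = 0;
  while (cursor < order.size() && nExpanded < maxExpand &&
         pool.trees.size() < (size_t)maxPool) {
    SplitKey k = order[cursor++];
    if (expanded.count(k)) continue;
    expanded[k] = 1;
    ++nExpanded;
    auto it = pool.trees.find(k);
    if (it == pool.trees.end()) continue;
    UTree cur = it->second.first;
    for_neighbors(cur, 2, [&](UTree &nb) -> bool {
      long s = fitch_score(nb, anchor, tips, weights, thresh, ws.S, ws.po,
                           ws.par, nullptr);
      if (s <= thresh) {
        SplitKey nk = splits_key(nb, ws.par);
        if (pool.trees.find(nk) == pool.trees.end() &&
            pool.trees.size() < (size_t)maxPool) {
          pool.trees.emplace(nk, std::make_pair(nb, s));
          order.push_back(nk);
        }
      }
      return pool.trees.size() < (size_t)maxPool;
    });
    Rcpp::checkUserInterrupt();
  }
  List trees(pool.trees.size());
  NumericVector lens(pool.trees.size());
  int i = 0;
  for (auto &kv : pool.trees) {
    trees[i] = to_ape(kv.second.first, og - 1);
    lens[i] = (double)kv.second.second;
    ++i;
  }
  return List::create(_["trees"] = trees, _["lengths"] = lens,
                      _["bestLength"] = (double)bestLen);
}
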