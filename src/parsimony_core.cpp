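// Parsimony scoring and tree-search kernels.
//
// Character data are passed as an n_char x n_tip integer matrix of 10-bit
// state masks (bit s set <=> state s allowed in that cell).  Missing and
// inapplicable cells are encoded upstream as the full mask, polymorphic
// cells as the union of their member states, so every mask is non-zero.
//
// Unordered characters are scored with Hartigan's generalisation of the
// Fitch pass, which is exact on arbitrary (multifurcating) trees; ordered
// characters with a Sankoff pass under linear (|i-j|) costs.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const int NSTATE = 10;
static const int BIG = 1 << 24;
static const double TIE_TOL = 1e-9;

typedef std::vector<std::vector<int> > Adj;

// ---------------------------------------------------------------------------
// traversal

// Postorder over the component containing `root`; parent[root] = root.
static void postorder_from(const Adj& adj, int root,
                           std::vector<int>& order, std::vector<int>& parent) {
  const int n = (int)adj.size();
  order.clear();
  parent.assign(n, -1);
  std::vector<int> stack;
  stack.push_back(root);
  parent[root] = root;
  std::vector<int> pre;
  pre.reserve(n);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    pre.push_back(v);
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (parent[w] == -1) {
        parent[w] = v;
        stack.push_back(w);
      }
    }
  }
  order.assign(pre.rbegin(), pre.rend());
}

// ---------------------------------------------------------------------------
// per-character scoring

static int steps_unordered_char(const std::vector<int>& order,
                                const std::vector<int>& parent,
                                const Adj& adj, int ntip,
                                const int* col,  // mask per tip index
                                std::vector<uint16_t>& S) {
  int steps = 0;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int v = order[oi];
    if (v < ntip) {
      S[v] = (uint16_t)col[v];
      continue;
    }
    int cnt[NSTATE] = {0};
    int k = 0;
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (w == parent[v]) continue;
      ++k;
      uint16_t m = S[w];
      while (m) {
        cnt[__builtin_ctz(m)]++;
        m &= (uint16_t)(m - 1);
      }
    }
    int maxc = 0;
    for (int s = 0; s < NSTATE; ++s)
      if (cnt[s] > maxc) maxc = cnt[s];
    uint16_t set = 0;
    for (int s = 0; s < NSTATE; ++s)
      if (cnt[s] == maxc) set |= (uint16_t)(1 << s);
    S[v] = set;
    steps += k - maxc;
  }
  return steps;
}

// min-plus transform under linear cost: e[i] = min_j d[j] + |i-j|
static inline void linear_minplus(const int* d, int* e) {
  e[0] = d[0];
  for (int i = 1; i < NSTATE; ++i) e[i] = std::min(d[i], e[i - 1] + 1);
  for (int i = NSTATE - 2; i >= 0; --i) e[i] = std::min(e[i], e[i + 1] + 1);
}

static int steps_ordered_char(const std::vector<int>& order,
                              const std::vector<int>& parent,
                              const Adj& adj, int ntip,
                              const int* col,
                              std::vector<int>& C /* n_nodes * NSTATE */) {
  int root = order.back();
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int v = order[oi];
    int* cv = &C[v * NSTATE];
    if (v < ntip) {
      int mask = col[v];
      for (int s = 0; s < NSTATE; ++s) cv[s] = (mask >> s) & 1 ? 0 : BIG;
      continue;
    }
    for (int s = 0; s < NSTATE; ++s) cv[s] = 0;
    int e[NSTATE];
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (w == parent[v]) continue;
      linear_minplus(&C[w * NSTATE], e);
      for (int s = 0; s < NSTATE; ++s) {
        cv[s] += e[s];
        if (cv[s] > BIG) cv[s] = BIG;
      }
    }
  }
  int best = BIG;
  const int* cr = &C[root * NSTATE];
  for (int s = 0; s < NSTATE; ++s)
    if (cr[s] < best) best = cr[s];
  return best;
}

struct CharData {
  const IntegerMatrix* X;  // n_char x n_tip masks
  const LogicalVector* ordered;
  const NumericVector* w;
  const IntegerVector* mmin;  // per-char minimum conceivable steps
  bool implied;
  double k;
  int nchar() const { return X->nrow(); }
};

// Scores the component containing internal node `root`; characters with
// weight 0 are skipped (steps reported as 0).
static void score_component(const Adj& adj, int root, int ntip,
                            const CharData& cd, std::vector<int>& steps) {
  std::vector<int> order, parent;
  postorder_from(adj, root, order, parent);
  const int n = (int)adj.size();
  std::vector<uint16_t> S(n);
  std::vector<int> C;
  const int nc = cd.nchar();
  steps.assign(nc, 0);
  std::vector<int> col(ntip);
  for (int i = 0; i < nc; ++i) {
    if ((*cd.w)[i] == 0.0) continue;
    for (int t = 0; t < ntip; ++t) col[t] = (*cd.X)(i, t);
    if ((*cd.ordered)[i]) {
      if (C.empty()) C.assign((size_t)n * NSTATE, 0);
      steps[i] = steps_ordered_char(order, parent, adj, ntip, col.data(), C);
    } else {
      steps[i] = steps_unordered_char(order, parent, adj, ntip, col.data(), S);
    }
  }
}

static double objective_of(const std::vector<int>& steps, const CharData& cd) {
  double tot = 0.0;
  const int nc = cd.nchar();
  for (int i = 0; i < nc; ++i) {
    double wi = (*cd.w)[i];
    if (wi == 0.0) continue;
    if (cd.implied) {
      double h = steps[i] - (*cd.mmin)[i];
      if (h < 0) h = 0;
      tot += wi * h / (cd.k + h);
    } else {
      tot += wi * steps[i];
    }
  }
  return tot;
}

// ---------------------------------------------------------------------------
// tree plumbing

static void adj_remove(std::vector<int>& a, int x) {
  a.erase(std::find(a.begin(), a.end(), x));
}

// deterministic edge list (parent, child) from a DFS rooted at `root`
static void collect_edges(const Adj& adj, int root,
                          std::vector<std::pair<int, int> >& edges) {
  std::vector<int> order, parent;
  postorder_from(adj, root, order, parent);
  edges.clear();
  for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
    int v = order[oi];
    if (v != root) edges.push_back(std::make_pair(parent[v], v));
  }
}

// insert tip t on edge (u,v) using internal node w
static void insert_tip(Adj& adj, int u, int v, int t, int w) {
  adj_remove(adj[u], v);
  adj_remove(adj[v], u);
  adj[u].push_back(w);
  adj[v].push_back(w);
  adj[w].clear();
  adj[w].push_back(u);
  adj[w].push_back(v);
  adj[w].push_back(t);
  adj[t].clear();
  adj[t].push_back(w);
}

static void remove_tip(Adj& adj, int t) {
  int w = adj[t][0];
  int u = -1, v = -1;
  for (size_t i = 0; i < adj[w].size(); ++i) {
    int x = adj[w][i];
    if (x == t) continue;
    if (u < 0) u = x; else v = x;
  }
  adj_remove(adj[u], w);
  adj_remove(adj[v], w);
  adj[u].push_back(v);
  adj[v].push_back(u);
  adj[w].clear();
  adj[t].clear();
}

// Convert adjacency (tips 0..ntip-1) into an ape-style 1-based edge matrix,
// rooted at the internal node adjacent to the lowest-index tip present.
static IntegerMatrix adj_to_edge(const Adj& adj, int ntip) {
  int start_tip = -1;
  for (int t = 0; t < ntip; ++t)
    if (!adj[t].empty()) { start_tip = t; break; }
  int root = adj[start_tip][0];
  std::vector<int> order, parent;
  postorder_from(adj, root, order, parent);
  int n_nodes = (int)order.size();
  int n_tips_present = 0;
  for (size_t i = 0; i < order.size(); ++i)
    if (order[i] < ntip) n_tips_present++;
  // ape numbering: tips 1..ntip (by tip index), internals ntip+1.. in preorder
  std::vector<int> lab(adj.size(), 0);
  int next_int = n_tips_present + 1;
  int next_tip = 1;
  std::vector<int> tipmap(ntip, 0);
  for (int t = 0; t < ntip; ++t)
    if (!adj[t].empty()) tipmap[t] = next_tip++;
  for (int oi = n_nodes - 1; oi >= 0; --oi) {  // preorder
    int v = order[oi];
    lab[v] = (v < ntip) ? tipmap[v] : next_int++;
  }
  IntegerMatrix edge(n_nodes - 1, 2);
  int r = 0;
  for (int oi = n_nodes - 1; oi >= 0; --oi) {
    int v = order[oi];
    if (v == root) continue;
    edge(r, 0) = lab[parent[v]];
    edge(r, 1) = lab[v];
    ++r;
  }
  return edge;
}

// ---------------------------------------------------------------------------
// optimum pool

struct Pool {
  double best;
  std::vector<Adj> trees;
  int max_hold;
  Pool(int mh) : best(R_PosInf), max_hold(mh) {}
  void offer(const Adj& t, double obj) {
    if (obj < best - TIE_TOL) {
      best = obj;
      trees.clear();
      trees.push_back(t);
    } else if (obj <= best + TIE_TOL) {
      if ((int)trees.size() < max_hold) trees.push_back(t);
    }
  }
};

// ---------------------------------------------------------------------------
// Wagner addition

static double wagner_build(Adj& adj, const std::vector<int>& ord, int ntip,
                           const CharData& cd, long& n_rearr) {
  const int n_nodes = 2 * ntip - 2;
  adj.assign(n_nodes, std::vector<int>());
  int next_internal = ntip;
  int i0 = ntip;  // first internal node
  adj[i0].push_back(ord[0]);
  adj[i0].push_back(ord[1]);
  adj[i0].push_back(ord[2]);
  adj[ord[0]].push_back(i0);
  adj[ord[1]].push_back(i0);
  adj[ord[2]].push_back(i0);
  ++next_internal;
  std::vector<int> steps;
  std::vector<std::pair<int, int> > edges;
  double obj = 0.0;
  for (size_t ti = 3; ti < ord.size(); ++ti) {
    int t = ord[ti];
    int w = next_internal++;
    collect_edges(adj, i0, edges);
    double best_obj = R_PosInf;
    int best_edge = -1;
    for (size_t ei = 0; ei < edges.size(); ++ei) {
      insert_tip(adj, edges[ei].first, edges[ei].second, t, w);
      score_component(adj, i0, ntip, cd, steps);
      double o = objective_of(steps, cd);
      ++n_rearr;
      remove_tip(adj, t);
      if (o < best_obj - TIE_TOL) {
        best_obj = o;
        best_edge = (int)ei;
      }
    }
    insert_tip(adj, edges[best_edge].first, edges[best_edge].second, t, w);
    obj = best_obj;
  }
  if (ord.size() == 3) {
    score_component(adj, i0, ntip, cd, steps);
    obj = objective_of(steps, cd);
  }
  return obj;
}

// ---------------------------------------------------------------------------
// branch swapping (generic bisection-reconnection; SPR and NNI are
// restrictions of the reconnection pairs)

struct Recon {  // a candidate reconnection applied to the bisected tree
  int pa, qa;   // side-A attachment edge (or pa==qa==tip for a lone tip)
  int pb, qb;
  bool a_tip, b_tip;
};

static void apply_recon(Adj& adj, const Recon& rc, int u, int v) {
  int au, bv;
  if (rc.a_tip) {
    au = rc.pa;
  } else {
    adj_remove(adj[rc.pa], rc.qa);
    adj_remove(adj[rc.qa], rc.pa);
    adj[u].clear();
    adj[u].push_back(rc.pa);
    adj[u].push_back(rc.qa);
    adj[rc.pa].push_back(u);
    adj[rc.qa].push_back(u);
    au = u;
  }
  if (rc.b_tip) {
    bv = rc.pb;
  } else {
    adj_remove(adj[rc.pb], rc.qb);
    adj_remove(adj[rc.qb], rc.pb);
    adj[v].clear();
    adj[v].push_back(rc.pb);
    adj[v].push_back(rc.qb);
    adj[rc.pb].push_back(v);
    adj[rc.qb].push_back(v);
    bv = v;
  }
  adj[au].push_back(bv);
  adj[bv].push_back(au);
}

static void undo_recon(Adj& adj, const Recon& rc, int u, int v) {
  int au = rc.a_tip ? rc.pa : u;
  int bv = rc.b_tip ? rc.pb : v;
  adj_remove(adj[au], bv);
  adj_remove(adj[bv], au);
  if (!rc.a_tip) {
    adj_remove(adj[rc.pa], u);
    adj_remove(adj[rc.qa], u);
    adj[u].clear();
    adj[rc.pa].push_back(rc.qa);
    adj[rc.qa].push_back(rc.pa);
  }
  if (!rc.b_tip) {
    adj_remove(adj[rc.pb], v);
    adj_remove(adj[rc.qb], v);
    adj[v].clear();
    adj[rc.pb].push_back(rc.qb);
    adj[rc.qb].push_back(rc.pb);
  }
}

static bool edges_adjacent(const std::pair<int, int>& a,
                           const std::pair<int, int>& b) {
  return a.first == b.first || a.first == b.second || a.second == b.first ||
         a.second == b.second;
}

// --- fast reconnection evaluation for unordered characters ----------------
//
// For a bisected component, directional Fitch/Hartigan state sets are
// computed for every edge: `down` (the subtree hanging below the edge),
// `up` (the rest of the component seen across the edge), and their
// combination `fset` (the state set of the component rooted on that edge).
// Joining side A at edge ea to side B at edge eb then costs, per character,
//   internalA(ea) + sB + penalty(downA, upA, fsetB)
// where the penalty counts how many of the three subtree sets the join
// node's state must fall outside (Hartigan's rule on three independent
// subtrees); this is exact for unordered parsimony, so each candidate is
// O(characters) instead of a full rescore.

struct SideTables {
  bool lone_tip;
  int tip;
  std::vector<std::pair<int, int> > edges;  // (parent, child)
  std::vector<uint16_t> down, up, fset;     // [edge * nchar + char]
  std::vector<int> internal_steps;          // [edge * nchar + char]
  std::vector<int> s_char;                  // per char, whole component
};

static inline uint16_t hartigan_set(const std::vector<uint16_t>& sets,
                                    int& penalty) {
  int cnt[NSTATE] = {0};
  for (size_t i = 0; i < sets.size(); ++i) {
    uint16_t m = sets[i];
    while (m) {
      cnt[__builtin_ctz(m)]++;
      m &= (uint16_t)(m - 1);
    }
  }
  int maxc = 0;
  for (int s = 0; s < NSTATE; ++s)
    if (cnt[s] > maxc) maxc = cnt[s];
  uint16_t set = 0;
  for (int s = 0; s < NSTATE; ++s)
    if (cnt[s] == maxc) set |= (uint16_t)(1 << s);
  penalty = (int)sets.size() - maxc;
  return set;
}

// component containing `start` (which must not be a lone tip)
static void build_side_tables(const Adj& adj, int start, int ntip,
                              const CharData& cd, SideTables& st) {
  st.lone_tip = false;
  const int nc = cd.nchar();
  // locate an internal node of the component
  std::vector<int> order, parent;
  int root = -1;
  {
    std::vector<int> comp, stck;
    std::vector<char> seen(adj.size(), 0);
    stck.push_back(start);
    seen[start] = 1;
    while (!stck.empty()) {
      int v = stck.back();
      stck.pop_back();
      comp.push_back(v);
      if (v >= ntip && root < 0) root = v;
      for (size_t i = 0; i < adj[v].size(); ++i)
        if (!seen[adj[v][i]]) { seen[adj[v][i]] = 1; stck.push_back(adj[v][i]); }
    }
    if (root < 0) {
      // two-tip component: a single edge
      int a = comp[0], b = comp[1];
      st.edges.assign(1, std::make_pair(a, b));
      st.down.assign(nc, 0);
      st.up.assign(nc, 0);
      st.fset.assign(nc, 0);
      st.internal_steps.assign(nc, 0);
      st.s_char.assign(nc, 0);
      for (int c = 0; c < nc; ++c) {
        if ((*cd.w)[c] == 0.0) continue;
        uint16_t ma = (uint16_t)(*cd.X)(c, a), mb = (uint16_t)(*cd.X)(c, b);
        st.down[c] = mb;
        st.up[c] = ma;
        st.fset[c] = (ma & mb) ? (uint16_t)(ma & mb) : (uint16_t)(ma | mb);
        st.s_char[c] = (ma & mb) ? 0 : 1;
        st.internal_steps[c] = 0;
      }
      return;
    }
  }
  postorder_from(adj, root, order, parent);
  const int n_nodes_all = (int)adj.size();
  st.edges.clear();
  for (int oi = (int)order.size() - 1; oi >= 0; --oi)
    if (order[oi] != root)
      st.edges.push_back(std::make_pair(parent[order[oi]], order[oi]));
  const int ne = (int)st.edges.size();
  st.down.assign((size_t)ne * nc, 0);
  st.up.assign((size_t)ne * nc, 0);
  st.fset.assign((size_t)ne * nc, 0);
  st.internal_steps.assign((size_t)ne * nc, 0);
  st.s_char.assign(nc, 0);
  std::vector<int> edge_of_node(n_nodes_all, -1);
  for (int e = 0; e < ne; ++e) edge_of_node[st.edges[e].second] = e;
  std::vector<uint16_t> Dn(n_nodes_all), Up(n_nodes_all);
  std::vector<uint16_t> kid_sets;
  for (int c = 0; c < nc; ++c) {
    if ((*cd.w)[c] == 0.0) continue;
    // down pass
    int steps = 0;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int v = order[oi];
      if (v < ntip) {
        Dn[v] = (uint16_t)(*cd.X)(c, v);
        continue;
      }
      kid_sets.clear();
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int w2 = adj[v][i];
        if (w2 == parent[v]) continue;
        kid_sets.push_back(Dn[w2]);
      }
      int pen;
      Dn[v] = hartigan_set(kid_sets, pen);
      steps += pen;
    }
    st.s_char[c] = steps;
    // up pass (preorder)
    for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
      int v = order[oi];
      if (v == root) continue;
      int u = parent[v];
      kid_sets.clear();
      for (size_t i = 0; i < adj[u].size(); ++i) {
        int w2 = adj[u][i];
        if (w2 == parent[u] || w2 == v) continue;
        kid_sets.push_back(Dn[w2]);
      }
      if (u != root) kid_sets.push_back(Up[u]);
      int pen;
      Up[v] = hartigan_set(kid_sets, pen);
      int e = edge_of_node[v];
      uint16_t d = Dn[v], up = Up[v];
      st.down[(size_t)e * nc + c] = d;
      st.up[(size_t)e * nc + c] = up;
      st.fset[(size_t)e * nc + c] =
          (d & up) ? (uint16_t)(d & up) : (uint16_t)(d | up);
      st.internal_steps[(size_t)e * nc + c] = steps - ((d & up) ? 0 : 1);
    }
  }
}

static inline int pen3(uint16_t a, uint16_t b, uint16_t f) {
  if (a & b & f) return 0;
  if ((a & b) | (a & f) | (b & f)) return 1;
  return 2;
}

// objective of joining side A at edge ea to side B at edge eb
static double join_objective(const SideTables& A, int ea, const SideTables& B,
                             int eb, const CharData& cd) {
  const int nc = cd.nchar();
  double tot = 0.0;
  if (A.lone_tip && B.lone_tip) stop("degenerate bisection");
  for (int c = 0; c < nc; ++c) {
    double wi = (*cd.w)[c];
    if (wi == 0.0) continue;
    int steps;
    if (A.lone_tip) {
      uint16_t t = (uint16_t)(*cd.X)(c, A.tip);
      steps = B.s_char[c] + ((t & B.fset[(size_t)eb * nc + c]) ? 0 : 1);
    } else if (B.lone_tip) {
      uint16_t t = (uint16_t)(*cd.X)(c, B.tip);
      steps = A.s_char[c] + ((t & A.fset[(size_t)ea * nc + c]) ? 0 : 1);
    } else {
      steps = A.internal_steps[(size_t)ea * nc + c] + B.s_char[c] +
              pen3(A.down[(size_t)ea * nc + c], A.up[(size_t)ea * nc + c],
                   B.fset[(size_t)eb * nc + c]);
    }
    if (cd.implied) {
      double h = steps - (*cd.mmin)[c];
      if (h < 0) h = 0;
      tot += wi * h / (cd.k + h);
    } else {
      tot += wi * steps;
    }
  }
  return tot;
}

// One full scan of the swap neighbourhood.  If an improving tree is found it
// is applied to `adj` and the function returns true.  If `pool` is non-null,
// all equal-score candidates are offered to it (used on the final scan).
static bool swap_scan(Adj& adj, int ntip, const CharData& cd, int swap_type,
                      double& cur_obj, long& n_rearr, Pool* pool) {
  int i0 = -1;
  for (size_t i = ntip; i < adj.size(); ++i)
    if (!adj[i].empty()) { i0 = (int)i; break; }
  std::vector<std::pair<int, int> > edges;
  collect_edges(adj, i0, edges);
  std::vector<int> steps;
  for (size_t ei = 0; ei < edges.size(); ++ei) {
    int u = edges[ei].first, v = edges[ei].second;
    Adj tc = adj;  // working copy for this bisection
    adj_remove(tc[u], v);
    adj_remove(tc[v], u);
    // suppress degree-2 endpoints, remembering the closed-up edge
    bool a_tip = (u < ntip);
    bool b_tip = (v < ntip);
    std::pair<int, int> orig_a(-1, -1), orig_b(-1, -1);
    if (!a_tip) {
      int p = tc[u][0], q = tc[u][1];
      adj_remove(tc[p], u);
      adj_remove(tc[q], u);
      tc[p].push_back(q);
      tc[q].push_back(p);
      tc[u].clear();
      orig_a = std::make_pair(p, q);
    }
    if (!b_tip) {
      int p = tc[v][0], q = tc[v][1];
      adj_remove(tc[p], v);
      adj_remove(tc[q], v);
      tc[p].push_back(q);
      tc[q].push_back(p);
      tc[v].clear();
      orig_b = std::make_pair(p, q);
    }
    // enumerate attachment sites on each side
    bool fast = true;
    for (int c = 0; c < cd.nchar(); ++c)
      if ((*cd.w)[c] != 0.0 && (*cd.ordered)[c]) { fast = false; break; }
    std::vector<std::pair<int, int> > ea, eb;
    SideTables TA, TB;
    int ia_orig = -1, ib_orig = -1;
    if (a_tip) {
      TA.lone_tip = true;
      TA.tip = u;
      ea.push_back(std::make_pair(u, u));
      ia_orig = 0;
    } else {
      build_side_tables(tc, orig_a.first, ntip, cd, TA);
      ea = TA.edges;
      for (size_t i = 0; i < ea.size(); ++i) {
        if ((ea[i].first == orig_a.first && ea[i].second == orig_a.second) ||
            (ea[i].first == orig_a.second && ea[i].second == orig_a.first))
          ia_orig = (int)i;
      }
    }
    if (b_tip) {
      TB.lone_tip = true;
      TB.tip = v;
      eb.push_back(std::make_pair(v, v));
      ib_orig = 0;
    } else {
      build_side_tables(tc, orig_b.first, ntip, cd, TB);
      eb = TB.edges;
      for (size_t i = 0; i < eb.size(); ++i) {
        if ((eb[i].first == orig_b.first && eb[i].second == orig_b.second) ||
            (eb[i].first == orig_b.second && eb[i].second == orig_b.first))
          ib_orig = (int)i;
      }
    }
    for (size_t ai = 0; ai < ea.size(); ++ai) {
      for (size_t bi = 0; bi < eb.size(); ++bi) {
        if (swap_type <= 2) {  // nni / spr: one side keeps its original site
          bool a_home = ((int)ai == ia_orig);
          bool b_home = ((int)bi == ib_orig);
          if (!a_home && !b_home) continue;
          if (swap_type == 1) {  // nni: the moving side stays adjacent
            bool near_a = a_home || ia_orig < 0 ||
                          edges_adjacent(ea[ai], ea[ia_orig]);
            bool near_b = b_home || ib_orig < 0 ||
                          edges_adjacent(eb[bi], eb[ib_orig]);
            if (!(near_a && near_b)) continue;
          }
        }
        Recon rc;
        rc.a_tip = a_tip;
        rc.b_tip = b_tip;
        rc.pa = ea[ai].first;
        rc.qa = ea[ai].second;
        rc.pb = eb[bi].first;
        rc.qb = eb[bi].second;
        double o;
        ++n_rearr;
        if (fast) {
          o = join_objective(TA, (int)ai, TB, (int)bi, cd);
          if (o < cur_obj - TIE_TOL) {
            apply_recon(tc, rc, u, v);
            adj = tc;
            cur_obj = o;
            return true;
          }
          if (pool != NULL && o <= pool->best + TIE_TOL) {
            Adj cand = tc;
            apply_recon(cand, rc, u, v);
            pool->offer(cand, o);
          }
        } else {
          apply_recon(tc, rc, u, v);
          int root_now = -1;
          for (size_t i = ntip; i < tc.size(); ++i)
            if (!tc[i].empty()) { root_now = (int)i; break; }
          score_component(tc, root_now, ntip, cd, steps);
          o = objective_of(steps, cd);
          if (o < cur_obj - TIE_TOL) {
            adj = tc;
            cur_obj = o;
            return true;
          }
          if (pool != NULL) pool->offer(tc, o);
          undo_recon(tc, rc, u, v);
        }
      }
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_mp_search(IntegerMatrix X, LogicalVector ordered, NumericVector w,
                   IntegerVector mmin, IntegerMatrix addition_orders,
                   int swap_type, bool implied, double k, int max_hold) {
  const int ntip = X.ncol();
  CharData cd;
  cd.X = &X;
  cd.ordered = &ordered;
  cd.w = &w;
  cd.mmin = &mmin;
  cd.implied = implied;
  cd.k = k;
  long n_rearr = 0;
  Pool pool(max_hold);
  const int n_add = addition_orders.nrow();
  for (int rep = 0; rep < n_add; ++rep) {
    std::vector<int> ord(ntip);
    for (int i = 0; i < ntip; ++i) ord[i] = addition_orders(rep, i);
    Adj adj;
    double obj = wagner_build(adj, ord, ntip, cd, n_rearr);
    if (swap_type > 0 && ntip >= 4) {
      while (swap_scan(adj, ntip, cd, swap_type, obj, n_rearr, NULL)) {
        Rcpp::checkUserInterrupt();
      }
    }
    pool.offer(adj, obj);
    if (obj <= pool.best + TIE_TOL && swap_type > 0 && ntip >= 4) {
      // collect equal-score neighbours of this local optimum
      double o2 = obj;
      swap_scan(adj, ntip, cd, swap_type, o2, n_rearr, &pool);
    }
  }
  // score the pooled optima once more for reporting
  List trees(pool.trees.size());
  List steps_list(pool.trees.size());
  for (size_t i = 0; i < pool.trees.size(); ++i) {
    std::vector<int> steps;
    int i0 = -1;
    for (size_t j = ntip; j < pool.trees[i].size(); ++j)
      if (!pool.trees[i][j].empty()) { i0 = (int)j; break; }
    score_component(pool.trees[i], i0, ntip, cd, steps);
    trees[i] = adj_to_edge(pool.trees[i], ntip);
    steps_list[i] = wrap(steps);
  }
  return List::create(_["best_obj"] = pool.best, _["edges"] = trees,
                      _["steps"] = steps_list,
                      _["n_rearrangements"] = (double)n_rearr);
}

// ---------------------------------------------------------------------------
// exhaustive enumeration (<= 9 tips federates to 135135 topologies)

static void exhaust_rec(Adj& adj, int next_tip, int ntip, int next_internal,
                        const CharData& cd, Pool& pool, double& n_topo) {
  if (next_tip == ntip) {
    std::vector<int> steps;
    score_component(adj, ntip, ntip, cd, steps);
    pool.offer(adj, objective_of(steps, cd));
    n_topo += 1;
    return;
  }
  std::vector<std::pair<int, int> > edges;
  collect_edges(adj, ntip, edges);
  int w = next_internal;
  for (size_t ei = 0; ei < edges.size(); ++ei) {
    insert_tip(adj, edges[ei].first, edges[ei].second, next_tip, w);
    exhaust_rec(adj, next_tip + 1, ntip, next_internal + 1, cd, pool, n_topo);
    remove_tip(adj, next_tip);
  }
}

// [[Rcpp::export]]
List cpp_exhaustive(IntegerMatrix X, LogicalVector ordered, NumericVector w,
                    IntegerVector mmin, bool implied, double k, int max_hold) {
  const int ntip = X.ncol();
  if (ntip > 9) stop("exhaustive search limited to 9 taxa");
  CharData cd;
  cd.X = &X;
  cd.ordered = &ordered;
  cd.w = &w;
  cd.mmin = &mmin;
  cd.implied = implied;
  cd.k = k;
  Pool pool(max_hold);
  double n_topo = 0;
  Adj adj(2 * ntip - 2);
  adj[ntip].push_back(0);
  adj[ntip].push_back(1);
  adj[ntip].push_back(2);
  adj[0].push_back(ntip);
  adj[1].push_back(ntip);
  adj[2].push_back(ntip);
  if (ntip == 3) {
    std::vector<int> steps;
    score_component(adj, ntip, ntip, cd, steps);
    pool.offer(adj, objective_of(steps, cd));
    n_topo = 1;
  } else {
    exhaust_rec(adj, 3, ntip, ntip + 1, cd, pool, n_topo);
  }
  List trees(pool.trees.size());
  List steps_list(pool.trees.size());
  for (size_t i = 0; i < pool.trees.size(); ++i) {
    std::vector<int> steps;
    score_component(pool.trees[i], ntip, ntip, cd, steps);
    trees[i] = adj_to_edge(pool.trees[i], ntip);
    steps_list[i] = wrap(steps);
  }
  return List::create(_["best_obj"] = pool.best, _["edges"] = trees,
                      _["steps"] = steps_list, _["n_topologies"] = n_topo);
}

// ---------------------------------------------------------------------------
// scoring an arbitrary ape edge matrix (rooted or unrooted storage,
// polytomies allowed)

// [[Rcpp::export]]
IntegerVector cpp_tree_steps(IntegerMatrix edge, int ntip, IntegerMatrix X,
                             LogicalVector ordered, NumericVector w) {
  int n_nodes = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    n_nodes = std::max(n_nodes, std::max(edge(i, 0), edge(i, 1)));
  Adj adj(n_nodes);
  std::vector<bool> has_parent(n_nodes + 1, false);
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0) - 1, b = edge(i, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
    has_parent[edge(i, 1)] = true;
  }
  int root = -1;
  for (int v = ntip + 1; v <= n_nodes; ++v)
    if (!has_parent[v]) { root = v - 1; break; }
  if (root < 0) stop("could not locate root node in edge matrix");
  // remap: ape tips 1..ntip are already 0..ntip-1 internally
  CharData cd;
  IntegerVector mmin(X.nrow());
  cd.X = &X;
  cd.ordered = &ordered;
  cd.w = &w;
  cd.mmin = &mmin;
  cd.implied = false;
  cd.k = 3.0;
  std::vector<int> steps;
  score_component(adj, root, ntip, cd, steps);
  return wrap(steps);
}
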