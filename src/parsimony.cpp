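// Core parsimony engine: Wagner (linearly ordered) and Fitch (unordered)
// character scoring, tree enumeration (exhaustive / branch-and-bound),
// random-addition + TBR heuristic search with MULTREES-style tree pools,
// fast stepwise-addition bootstrap, and uniform random topology sampling.
//
// Internal tree representation: leaves 0..n-1, internal nodes n..2n-3,
// unrooted binary trees stored as an edge list.  Scoring roots the tree at
// an arbitrary leaf; for linearly ordered characters the Farris interval
// method gives the exact Wagner length on binary trees, and unordered
// characters use Fitch set operations.  A general Sankoff scorer (linear or
// 0/1 cost, O(states) per transition) handles arbitrary (possibly
// multifurcating, ape-format) trees.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <map>
#include <queue>
#include <random>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

typedef std::vector<std::array<int, 2> > EdgeList;

static const double INF = 1e18;

// ---------------------------------------------------------------------------
// Fast scorer for binary unrooted trees (interval method + Fitch)
// ---------------------------------------------------------------------------

struct Scorer {
  const int *S;          // states, ntaxa x nchar, column-major (R matrix)
  int ntaxa, nchar;
  const int *ord;        // 1 = ordered, 0 = unordered
  const double *w;       // per-character weights (bootstrap resampling)
  int maxNodes;

  std::vector<int> adj;      // 3 slots per node
  std::vector<int> deg;
  std::vector<int> post;     // postorder node list
  std::vector<int> parent;
  std::vector<int> lo, hi;   // per node x char intervals
  std::vector<uint64_t> mask;
  std::vector<int> dfs;      // reusable DFS stack

  Scorer(const int *S_, int ntaxa_, int nchar_, const int *ord_,
         const double *w_)
      : S(S_), ntaxa(ntaxa_), nchar(nchar_), ord(ord_), w(w_) {
    maxNodes = 2 * ntaxa;
    adj.assign(3 * maxNodes, -1);
    deg.assign(maxNodes, 0);
    parent.assign(maxNodes, -1);
    lo.assign((size_t)maxNodes * nchar, 0);
    hi.assign((size_t)maxNodes * nchar, 0);
    mask.assign((size_t)maxNodes * nchar, 0);
  }

  inline int state(int taxon, int c) const { return S[(size_t)c * ntaxa + taxon]; }

  // Exact length of the binary unrooted tree given by `edges`; early-exits
  // with +inf once the accumulated length exceeds `cutoff`.
  double score(const EdgeList &edges, double cutoff) {
    const int ne = (int)edges.size();
    if (ne == 0) return 0.0;
    // reset degrees for touched nodes
    for (int e = 0; e < ne; ++e) {
      deg[edges[e][0]] = 0;
      deg[edges[e][1]] = 0;
    }
    for (int e = 0; e < ne; ++e) {
      int u = edges[e][0], v = edges[e][1];
      adj[3 * u + deg[u]++] = v;
      adj[3 * v + deg[v]++] = u;
    }
    // root at some leaf present in the tree
    int rootLeaf = -1;
    for (int e = 0; e < ne && rootLeaf < 0; ++e) {
      if (edges[e][0] < ntaxa) rootLeaf = edges[e][0];
      else if (edges[e][1] < ntaxa) rootLeaf = edges[e][1];
    }
    // iterative DFS; reversed preorder puts children before parents
    post.clear();
    dfs.clear();
    dfs.push_back(rootLeaf);
    parent[rootLeaf] = -1;
    while (!dfs.empty()) {
      int v = dfs.back();
      dfs.pop_back();
      post.push_back(v);
      for (int k = 0; k < deg[v]; ++k) {
        int u = adj[3 * v + k];
        if (u != parent[v]) {
          parent[u] = v;
          dfs.push_back(u);
        }
      }
    }
    std::reverse(post.begin(), post.end());

    double total = 0.0;
    // process nodes in postorder; combine children into each internal node
    for (size_t pi = 0; pi < post.size(); ++pi) {
      int v = post[pi];
      if (v < ntaxa && v != rootLeaf) {
        for (int c = 0; c < nchar; ++c) {
          size_t off = (size_t)v * nchar + c;
          int s = state(v, c);
          if (ord[c]) {
            if (s < 0) { lo[off] = 0; hi[off] = 1 << 20; }
            else { lo[off] = s; hi[off] = s; }
          } else {
            mask[off] = (s < 0) ? ~0ull : (1ull << s);
          }
        }
        continue;
      }
      // internal node (or the root leaf at the end): combine children
      bool first = true;
      for (int k = 0; k < deg[v]; ++k) {
        int u = adj[3 * v + k];
        if (u == parent[v]) continue;
        size_t offu = (size_t)u * nchar;
        size_t offv = (size_t)v * nchar;
        if (first) {
          for (int c = 0; c < nchar; ++c) {
            lo[offv + c] = lo[offu + c];
            hi[offv + c] = hi[offu + c];
            mask[offv + c] = mask[offu + c];
          }
          first = false;
        } else {
          for (int c = 0; c < nchar; ++c) {
            if (ord[c]) {
              int l1 = lo[offv + c], h1 = hi[offv + c];
              int l2 = lo[offu + c], h2 = hi[offu + c];
              int nl = std::max(l1, l2), nh = std::min(h1, h2);
              if (nl <= nh) {
                lo[offv + c] = nl; hi[offv + c] = nh;
              } else {
                total += w[c] * (nl - nh);
                lo[offv + c] = nh; hi[offv + c] = nl;
              }
            } else {
              uint64_t m1 = mask[offv + c], m2 = mask[offu + c];
              uint64_t in = m1 & m2;
              if (in) mask[offv + c] = in;
              else { mask[offv + c] = m1 | m2; total += w[c]; }
            }
          }
          if (total > cutoff) return INF;
        }
      }
      if (v == rootLeaf) {
        // fold the root leaf's own state in
        size_t offv = (size_t)v * nchar;
        for (int c = 0; c < nchar; ++c) {
          int s = state(v, c);
          if (ord[c]) {
            if (s < 0) continue;
            if (s < lo[offv + c]) total += w[c] * (lo[offv + c] - s);
            else if (s > hi[offv + c]) total += w[c] * (s - hi[offv + c]);
          } else {
            uint64_t m = (s < 0) ? ~0ull : (1ull << s);
            if (!(m & mask[offv + c])) total += w[c];
          }
        }
      }
    }
    return total;
  }
};

// ---------------------------------------------------------------------------
// Canonical newick (children sorted by smallest leaf index) for deduplication
// ---------------------------------------------------------------------------

struct NewickBuilder {
  const EdgeList *edges;
  const std::vector<std::string> *labels;
  std::vector<std::vector<int> > nbr;
  int ntaxa;

  void build_adj(const EdgeList &E, int maxNodes) {
    nbr.assign(maxNodes, std::vector<int>());
    for (size_t e = 0; e < E.size(); ++e) {
      nbr[E[e][0]].push_back(E[e][1]);
      nbr[E[e][1]].push_back(E[e][0]);
    }
  }

  // returns (string, min leaf index)
  std::pair<std::string, int> sub(int v, int par) {
    if (v < ntaxa)
      return std::make_pair((*labels)[v], v);
    std::vector<std::pair<int, std::string> > kids;
    for (size_t k = 0; k < nbr[v].size(); ++k) {
      int u = nbr[v][k];
      if (u == par) continue;
      std::pair<std::string, int> r = sub(u, v);
      kids.push_back(std::make_pair(r.second, r.first));
    }
    std::sort(kids.begin(), kids.end());
    std::string s = "(";
    for (size_t k = 0; k < kids.size(); ++k) {
      if (k) s += ",";
      s += kids[k].second;
    }
    s += ")";
    return std::make_pair(s, kids[0].first);
  }

  // canonical unrooted newick: trichotomy at the neighbor of leaf 0
  std::string canonical(const EdgeList &E, int ntaxa_,
                        const std::vector<std::string> &labs, int maxNodes) {
    ntaxa = ntaxa_;
    labels = &labs;
    build_adj(E, maxNodes);
    if (ntaxa == 2) return "(" + labs[0] + "," + labs[1] + ");";
    int r = nbr[0][0];
    std::vector<std::pair<int, std::string> > kids;
    for (size_t k = 0; k < nbr[r].size(); ++k) {
      int u = nbr[r][k];
      if (u == 0) continue;
      std::pair<std::string, int> rr = sub(u, r);
      kids.push_back(std::make_pair(rr.second, rr.first));
    }
    std::sort(kids.begin(), kids.end());
    std::string s = "(" + labs[0];
    for (size_t k = 0; k < kids.size(); ++k) s += "," + kids[k].second;
    s += ");";
    return s;
  }
};

// ---------------------------------------------------------------------------
// Stepwise addition helpers
// ---------------------------------------------------------------------------

// insert taxon t on edge e; returns undo info (original edge)
static inline std::array<int, 2> insert_taxon(EdgeList &E, int e, int t,
                                              int newNode) {
  std::array<int, 2> old = E[e];
  E[e][1] = newNode;                      // (u, w)
  std::array<int, 2> e1 = {{newNode, old[1]}};
  std::array<int, 2> e2 = {{newNode, t}};
  E.push_back(e1);
  E.push_back(e2);
  return old;
}

static inline void undo_insert(EdgeList &E, int e, const std::array<int, 2> &old) {
  E.pop_back();
  E.pop_back();
  E[e] = old;
}

// greedy stepwise addition under a given taxon order; ties broken by the
// first-encountered edge in a shuffled scan order
static EdgeList stepwise_tree(Scorer &sc, const std::vector<int> &order,
                              std::mt19937 &rng, bool greedy) {
  int n = sc.ntaxa;
  EdgeList E;
  std::array<int, 2> e0 = {{order[0], order[1]}};
  E.push_back(e0);
  int nextNode = n;
  for (int k = 2; k < n; ++k) {
    int t = order[k];
    int ne = (int)E.size();
    int bestE = -1;
    double bestS = INF;
    std::vector<int> scan(ne);
    for (int i = 0; i < ne; ++i) scan[i] = i;
    if (greedy) {
      std::shuffle(scan.begin(), scan.end(), rng);
      for (int i = 0; i < ne; ++i) {
        int e = scan[i];
        std::array<int, 2> old = insert_taxon(E, e, t, nextNode);
        double s = sc.score(E, bestS);
        undo_insert(E, e, old);
        if (s < bestS) { bestS = s; bestE = e; }
      }
    } else {
      std::uniform_int_distribution<int> pick(0, ne - 1);
      bestE = pick(rng);
    }
    insert_taxon(E, bestE, t, nextNode);
    ++nextNode;
  }
  return E;
}

// ---------------------------------------------------------------------------
// Exported search entry points
// ---------------------------------------------------------------------------

// Exhaustive or branch-and-bound enumeration over all unrooted binary
// topologies (taxa added in fixed order 0..n-1, each addition on every edge).
// [[Rcpp::export(name = ".cpp_enumerate")]]
List cpp_enumerate(IntegerMatrix states, LogicalVector ordered,
                   bool use_bound, int max_trees, int seed) {
  int n = states.nrow(), nchar = states.ncol();
  std::vector<int> ord(nchar);
  for (int c = 0; c < nchar; ++c) ord[c] = ordered[c] ? 1 : 0;
  std::vector<double> w(nchar, 1.0);
  Scorer sc(states.begin(), n, nchar, ord.data(), w.data());
  std::mt19937 rng(seed);

  std::vector<std::string> labs(n);
  for (int i = 0; i < n; ++i) labs[i] = "t" + std::to_string(i + 1);
  NewickBuilder nb;

  double best = INF;
  double initial_bound = INF;
  std::set<std::string> pool;
  bool saturated = false;

  if (n == 2) {
    EdgeList E;
    std::array<int, 2> e0 = {{0, 1}};
    E.push_back(e0);
    best = sc.score(E, INF);
    pool.insert(nb.canonical(E, n, labs, 2 * n));
  } else {
    if (use_bound) {
      // stepwise-addition upper bound (admissible initial bound)
      std::vector<int> order(n);
      for (int i = 0; i < n; ++i) order[i] = i;
      EdgeList E0 = stepwise_tree(sc, order, rng, true);
      initial_bound = sc.score(E0, INF);
      best = initial_bound;
      pool.insert(nb.canonical(E0, n, labs, 2 * n));
    }
    EdgeList E;
    std::array<int, 2> e0 = {{0, 1}};
    E.push_back(e0);
    // recursive enumeration (explicit stack of (taxon k, edge index))
    struct Frame { int e; std::array<int, 2> old; };
    std::vector<Frame> frames;
    std::vector<int> choice(n, -1);
    int k = 2;
    int nextNode = n;
    while (k >= 2) {
      int ne_before = 2 * (k - 1) - 3 + 2;  // edges in tree with k leaves... computed directly:
      ne_before = (int)E.size();
      int next = choice[k] + 1;
      if (next >= ne_before) {
        choice[k] = -1;
        --k;
        --nextNode;
        if (k >= 2 && !frames.empty()) {
          Frame f = frames.back();
          frames.pop_back();
          undo_insert(E, f.e, f.old);
        }
        continue;
      }
      choice[k] = next;
      // if we had inserted at this level before, undo happened on backtrack;
      // insert current choice
      std::array<int, 2> old = insert_taxon(E, next, k, nextNode);
      double s = sc.score(E, use_bound ? best : INF);
      bool prune = use_bound && s > best + 1e-9;
      if (!prune && k == n - 1) {
        if (s < best - 1e-9) {
          best = s;
          pool.clear();
          saturated = false;
        }
        if (std::abs(s - best) <= 1e-9) {
          if ((int)pool.size() < max_trees)
            pool.insert(nb.canonical(E, n, labs, 2 * n));
          else
            saturated = true;
        }
        undo_insert(E, next, old);
        continue;
      }
      if (prune) {
        undo_insert(E, next, old);
        continue;
      }
      Frame f;
      f.e = next;
      f.old = old;
      frames.push_back(f);
      ++k;
      ++nextNode;
    }
  }

  CharacterVector trees(pool.size());
  int i = 0;
  for (std::set<std::string>::iterator it = pool.begin(); it != pool.end(); ++it)
    trees[i++] = *it;
  return List::create(_["length"] = best, _["trees"] = trees,
                      _["saturated"] = saturated,
                      _["initial_bound"] = initial_bound);
}

// Collect the edge lists of both components after bisecting edge `be`;
// returns false if the bisection is trivial in a way we cannot use.
static void component_edges(const EdgeList &E, int be, int start,
                            std::vector<int> &compNodes, EdgeList &compE,
                            std::array<int, 2> &merged, bool &hasMerged,
                            int ntaxa) {
  // adjacency excluding edge be
  std::map<int, std::vector<std::pair<int, int> > > adj;  // node -> (nbr, edge idx)
  for (int e = 0; e < (int)E.size(); ++e) {
    if (e == be) continue;
    adj[E[e][0]].push_back(std::make_pair(E[e][1], e));
    adj[E[e][1]].push_back(std::make_pair(E[e][0], e));
  }
  // BFS
  std::set<int> seen;
  std::vector<int> q;
  q.push_back(start);
  seen.insert(start);
  std::set<int> eidx;
  while (!q.empty()) {
    int v = q.back();
    q.pop_back();
    std::vector<std::pair<int, int> > &a = adj[v];
    for (size_t k = 0; k < a.size(); ++k) {
      eidx.insert(a[k].second);
      if (!seen.count(a[k].first)) {
        seen.insert(a[k].first);
        q.push_back(a[k].first);
      }
    }
  }
  compNodes.assign(seen.begin(), seen.end());
  compE.clear();
  hasMerged = false;
  // suppress `start` if it now has degree 2 (it was internal)
  int d = (int)adj[start].size();
  if (d == 2) {
    int a = adj[start][0].first, b = adj[start][1].first;
    int ea = adj[start][0].second, eb = adj[start][1].second;
    merged[0] = a;
    merged[1] = b;
    hasMerged = true;
    for (std::set<int>::iterator it = eidx.begin(); it != eidx.end(); ++it) {
      if (*it == ea || *it == eb) continue;
      compE.push_back(E[*it]);
    }
    std::array<int, 2> m = {{a, b}};
    compE.push_back(m);
  } else {
    for (std::set<int>::iterator it = eidx.begin(); it != eidx.end(); ++it)
      compE.push_back(E[*it]);
  }
}

// all TBR reconnections of the bisection of each edge
static void tbr_neighbors(const EdgeList &E, int ntaxa,
                          std::vector<EdgeList> &out) {
  out.clear();
  int ne = (int)E.size();
  if (ne < 2) return;
  for (int be = 0; be < ne; ++be) {
    int u = E[be][0], v = E[be][1];
    std::vector<int> n1, n2;
    EdgeList E1, E2;
    std::array<int, 2> m1, m2;
    bool hm1, hm2;
    component_edges(E, be, u, n1, E1, m1, hm1, ntaxa);
    component_edges(E, be, v, n2, E2, m2, hm2, ntaxa);
    // cases: a component may be a single leaf (no edges)
    if (E1.empty() && E2.empty()) continue;  // 2-taxon tree
    if (E1.empty()) {
      // u is a leaf: reattach u on every edge of E2 (v suppressed)
      for (int e2 = 0; e2 < (int)E2.size(); ++e2) {
        EdgeList nb = E2;
        std::array<int, 2> tgt = nb[e2];
        nb[e2][1] = v;
        std::array<int, 2> a1 = {{v, tgt[1]}};
        std::array<int, 2> a2 = {{v, u}};
        nb.push_back(a1);
        nb.push_back(a2);
        out.push_back(nb);
      }
      continue;
    }
    if (E2.empty()) {
      for (int e1 = 0; e1 < (int)E1.size(); ++e1) {
        EdgeList nb = E1;
        std::array<int, 2> tgt = nb[e1];
        nb[e1][1] = u;
        std::array<int, 2> a1 = {{u, tgt[1]}};
        std::array<int, 2> a2 = {{u, v}};
        nb.push_back(a1);
        nb.push_back(a2);
        out.push_back(nb);
      }
      continue;
    }
    // both components have >= 1 edge; u and v are reusable internal nodes
    for (int e1 = 0; e1 < (int)E1.size(); ++e1) {
      for (int e2 = 0; e2 < (int)E2.size(); ++e2) {
        EdgeList nb;
        nb.reserve(E1.size() + E2.size() + 3);
        for (int e = 0; e < (int)E1.size(); ++e)
          if (e != e1) nb.push_back(E1[e]);
        for (int e = 0; e < (int)E2.size(); ++e)
          if (e != e2) nb.push_back(E2[e]);
        // subdivide e1 with u, e2 with v, join u-v
        std::array<int, 2> t1 = E1[e1], t2 = E2[e2];
        std::array<int, 2> b1 = {{t1[0], u}};
        std::array<int, 2> b2 = {{u, t1[1]}};
        std::array<int, 2> b3 = {{t2[0], v}};
        std::array<int, 2> b4 = {{v, t2[1]}};
        std::array<int, 2> b5 = {{u, v}};
        nb.push_back(b1);
        nb.push_back(b2);
        nb.push_back(b3);
        nb.push_back(b4);
        nb.push_back(b5);
        out.push_back(nb);
      }
    }
  }
}

// Heuristic search: `nreps` random-addition stepwise starts, TBR branch
// swapping with a MULTREES-style pool of equal-length trees (capped).
// [[Rcpp::export(name = ".cpp_heuristic")]]
List cpp_heuristic(IntegerMatrix states, LogicalVector ordered, int nreps,
                   int max_trees, int seed) {
  int n = states.nrow(), nchar = states.ncol();
  std::vector<int> ord(nchar);
  for (int c = 0; c < nchar; ++c) ord[c] = ordered[c] ? 1 : 0;
  std::vector<double> w(nchar, 1.0);
  Scorer sc(states.begin(), n, nchar, ord.data(), w.data());
  std::mt19937 rng(seed);
  std::vector<std::string> labs(n);
  for (int i = 0; i < n; ++i) labs[i] = "t" + std::to_string(i + 1);
  NewickBuilder nb;

  double best = INF;
  std::set<std::string> global;
  bool saturated = false;
  NumericVector repLengths(nreps);

  for (int rep = 0; rep < nreps; ++rep) {
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::shuffle(order.begin(), order.end(), rng);
    EdgeList cur = stepwise_tree(sc, order, rng, true);
    double curLen = sc.score(cur, INF);
    if (n >= 4) {
      // TBR with equal-length pool
      std::map<std::string, EdgeList> pool;
      std::vector<std::string> queue;
      std::string key = nb.canonical(cur, n, labs, 2 * n);
      pool[key] = cur;
      queue.push_back(key);
      while (!queue.empty()) {
        std::string k = queue.back();
        queue.pop_back();
        EdgeList t = pool[k];
        std::vector<EdgeList> nbs;
        tbr_neighbors(t, n, nbs);
        bool improved = false;
        for (size_t i = 0; i < nbs.size(); ++i) {
          double s = sc.score(nbs[i], curLen);
          if (s < curLen - 1e-9) {
            curLen = s;
            pool.clear();
            queue.clear();
            std::string nk = nb.canonical(nbs[i], n, labs, 2 * n);
            pool[nk] = nbs[i];
            queue.push_back(nk);
            improved = true;
            break;
          } else if (s <= curLen + 1e-9 && (int)pool.size() < max_trees) {
            std::string nk = nb.canonical(nbs[i], n, labs, 2 * n);
            if (!pool.count(nk)) {
              pool[nk] = nbs[i];
              queue.push_back(nk);
            }
          } else if (s <= curLen + 1e-9 && (int)pool.size() >= max_trees) {
            saturated = true;
          }
        }
        if (improved) continue;
      }
      repLengths[rep] = curLen;
      if (curLen < best - 1e-9) {
        best = curLen;
        global.clear();
      }
      if (std::abs(curLen - best) <= 1e-9) {
        for (std::map<std::string, EdgeList>::iterator it = pool.begin();
             it != pool.end(); ++it) {
          if ((int)global.size() < max_trees) global.insert(it->first);
          else saturated = true;
        }
      }
    } else {
      repLengths[rep] = curLen;
      if (curLen < best - 1e-9) {
        best = curLen;
        global.clear();
      }
      if (std::abs(curLen - best) <= 1e-9)
        global.insert(nb.canonical(cur, n, labs, 2 * n));
    }
  }

  CharacterVector trees(global.size());
  int i = 0;
  for (std::set<std::string>::iterator it = global.begin(); it != global.end();
       ++it)
    trees[i++] = *it;
  return List::create(_["length"] = best, _["trees"] = trees,
                      _["saturated"] = saturated,
                      _["rep_lengths"] = repLengths);
}

// Lengths of `n_random` uniformly sampled unrooted binary topologies
// (random addition with uniform edge choice is uniform over topologies).
// [[Rcpp::export(name = ".cpp_random_lengths")]]
NumericVector cpp_random_lengths(IntegerMatrix states, LogicalVector ordered,
                                 int n_random, int seed) {
  int n = states.nrow(), nchar = states.ncol();
  std::vector<int> ord(nchar);
  for (int c = 0; c < nchar; ++c) ord[c] = ordered[c] ? 1 : 0;
  std::vector<double> w(nchar, 1.0);
  Scorer sc(states.begin(), n, nchar, ord.data(), w.data());
  std::mt19937 rng(seed);
  NumericVector out(n_random);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int r = 0; r < n_random; ++r) {
    EdgeList E = stepwise_tree(sc, order, rng, false);
    out[r] = sc.score(E, INF);
  }
  return out;
}

// "Fast" bootstrap: per replicate resample characters with replacement,
// build one stepwise-addition tree under a random taxon order (no branch
// swapping), tally bipartitions (side not containing taxon 0).
// [[Rcpp::export(name = ".cpp_bootstrap")]]
List cpp_bootstrap(IntegerMatrix states, LogicalVector ordered, int nreps,
                   int seed) {
  int n = states.nrow(), nchar = states.ncol();
  std::vector<int> ord(nchar);
  for (int c = 0; c < nchar; ++c) ord[c] = ordered[c] ? 1 : 0;
  std::vector<double> w(nchar, 1.0);
  Scorer sc(states.begin(), n, nchar, ord.data(), w.data());
  std::mt19937 rng(seed);
  std::map<std::string, int> tally;
  std::uniform_int_distribution<int> pickc(0, nchar - 1);

  for (int rep = 0; rep < nreps; ++rep) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int c = 0; c < nchar; ++c) w[pickc(rng)] += 1.0;
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::shuffle(order.begin(), order.end(), rng);
    EdgeList E = stepwise_tree(sc, order, rng, true);
    // bipartitions: for each internal edge, leaves on the side without 0
    std::map<int, std::vector<int> > adj;
    for (size_t e = 0; e < E.size(); ++e) {
      adj[E[e][0]].push_back(E[e][1]);
      adj[E[e][1]].push_back(E[e][0]);
    }
    for (size_t e = 0; e < E.size(); ++e) {
      int u = E[e][0], v = E[e][1];
      if (u < n || v < n) continue;  // pendant edges are trivial
      // BFS from v avoiding u
      std::vector<int> leaves;
      std::vector<int> q;
      std::set<int> seen;
      q.push_back(v);
      seen.insert(v);
      seen.insert(u);
      while (!q.empty()) {
        int x = q.back();
        q.pop_back();
        if (x < n) leaves.push_back(x);
        std::vector<int> &a = adj[x];
        for (size_t k = 0; k < a.size(); ++k)
          if (!seen.count(a[k])) {
            seen.insert(a[k]);
            q.push_back(a[k]);
          }
      }
      bool has0 = false;
      for (size_t i = 0; i < leaves.size(); ++i)
        if (leaves[i] == 0) has0 = true;
      if (has0) {
        // take the complement
        std::set<int> inside(leaves.begin(), leaves.end());
        leaves.clear();
        for (int i = 0; i < n; ++i)
          if (!inside.count(i)) leaves.push_back(i);
      }
      std::sort(leaves.begin(), leaves.end());
      if ((int)leaves.size() < 2 || (int)leaves.size() > n - 2) continue;
      std::string key;
      for (size_t i = 0; i < leaves.size(); ++i) {
        if (i) key += ",";
        key += std::to_string(leaves[i] + 1);
      }
      tally[key] += 1;
    }
  }
  CharacterVector keys(tally.size());
  IntegerVector counts(tally.size());
  int i = 0;
  for (std::map<std::string, int>::iterator it = tally.begin();
       it != tally.end(); ++it) {
    keys[i] = it->first;
    counts[i] = it->second;
    ++i;
  }
  return List::create(_["clade"] = keys, _["count"] = counts,
                      _["nreps"] = nreps);
}

// General Sankoff scorer for ape-format trees (any degree, rooted or not):
// per-character minimal steps under linear (ordered) or 0/1 (unordered)
// costs; O(states) per parent/child transition via distance transforms.
// [[Rcpp::export(name = ".cpp_score_tree")]]
NumericVector cpp_score_tree(IntegerMatrix edge, int ntip,
                             IntegerMatrix states, LogicalVector ordered) {
  int nedge = edge.nrow();
  int nnode = 0;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  std::vector<std::vector<int> > children(nnode + 1);
  std::vector<int> hasParent(nnode + 1, 0);
  for (int e = 0; e < nedge; ++e) {
    children[edge(e, 0)].push_back(edge(e, 1));
    hasParent[edge(e, 1)] = 1;
  }
  int root = -1;
  for (int v = 1; v <= nnode; ++v)
    if (!hasParent[v] && !children[v].empty()) root = v;
  // postorder
  std::vector<int> post, stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    post.push_back(v);
    for (size_t k = 0; k < children[v].size(); ++k)
      stack.push_back(children[v][k]);
  }
  std::reverse(post.begin(), post.end());

  int ntaxa = states.nrow(), nchar = states.ncol();
  int smax = 0;
  for (int c = 0; c < nchar; ++c)
    for (int t = 0; t < ntaxa; ++t) smax = std::max(smax, states(t, c));
  int S = smax + 1;

  NumericVector out(nchar);
  std::vector<double> f((size_t)(nnode + 1) * S);
  std::vector<double> g(S);
  for (int c = 0; c < nchar; ++c) {
    for (size_t pi = 0; pi < post.size(); ++pi) {
      int v = post[pi];
      double *fv = &f[(size_t)v * S];
      if (children[v].empty()) {
        int s = states(v - 1, c);  // ape tips are 1..ntip, rows 0..ntip-1
        for (int x = 0; x < S; ++x) fv[x] = (s < 0 || x == s) ? 0.0 : INF;
        continue;
      }
      for (int x = 0; x < S; ++x) fv[x] = 0.0;
      for (size_t k = 0; k < children[v].size(); ++k) {
        double *fc = &f[(size_t)children[v][k] * S];
        if (ordered[c]) {
          for (int x = 0; x < S; ++x) g[x] = fc[x];
          for (int x = 1; x < S; ++x) g[x] = std::min(g[x], g[x - 1] + 1.0);
          for (int x = S - 2; x >= 0; --x) g[x] = std::min(g[x], g[x + 1] + 1.0);
        } else {
          double m = INF;
          for (int x = 0; x < S; ++x) m = std::min(m, fc[x]);
          for (int x = 0; x < S; ++x) g[x] = std::min(fc[x], m + 1.0);
        }
        for (int x = 0; x < S; ++x) fv[x] += g[x];
      }
    }
    double best = INF;
    double *fr = &f[(size_t)root * S];
    for (int x = 0; x < S; ++x) best = std::min(best, fr[x]);
    out[c] = best;
  }
  return out;
}
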