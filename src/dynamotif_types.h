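#ifndef DYNAMOTIF_TYPES_H
#define DYNAMOTIF_TYPES_H

// Core counting engine.
//
// Implements, on 0-based integer node ids:
//   * unique enumeration of connected edge subsets isomorphic to a small
//     motif (ESU-style extension on the line graph, each subset visited
//     exactly once), classified by an exhaustive-permutation canonical form;
//   * the per-edge embedding index D_e (one id list per host edge);
//   * the min-degree greedy on the (implicit) overlap graph -- nodes
//     visited in ascending initial-degree order, each selection removing
//     its closed neighbourhood -- for edge-disjoint (F2) and
//     node-disjoint (F3) embedding sets;
//   * incremental F1/F2 maintenance under single edge deletions/insertions:
//     deletion drops D_e and attempts one replacement embedding for a lost
//     F2 member; insertion discovers embeddings containing the new edge by
//     anchored enumeration and admits at most one whose edges are all free.
//
// The overlap graph is never materialised at scale: overlap degrees come
// from inclusion-exclusion over shared key subsets, and neighbourhoods
// from the D_e buckets.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <string>

using namespace Rcpp;

static const int MAXN = 10;  // max motif nodes (exhaustive canonical form)
static const int MAXQ = 12;  // max motif edges

static inline uint64_t ekey(int u, int v) {
  if (u > v) std::swap(u, v);
  return (static_cast<uint64_t>(static_cast<uint32_t>(u)) << 32) |
         static_cast<uint32_t>(v);
}

// Minimum upper-triangular adjacency encoding over all node permutations.
// Exact and exhaustive; intended for motif-sized graphs only (n <= MAXN).
static uint64_t canon64(int n, const std::vector<std::pair<int, int> >& edges) {
  if (n > MAXN) stop("canonical form supports at most %d nodes", MAXN);
  uint16_t adj[MAXN];
  std::fill(adj, adj + MAXN, 0);
  for (size_t i = 0; i < edges.size(); ++i) {
    adj[edges[i].first]  |= static_cast<uint16_t>(1 << edges[i].second);
    adj[edges[i].second] |= static_cast<uint16_t>(1 << edges[i].first);
  }
  std::vector<int> q(n);  // q[new label] = old node
  for (int i = 0; i < n; ++i) q[i] = i;
  uint64_t best = ~0ULL;
  do {
    uint64_t code = 0;
    int bit = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++bit)
        if ((adj[q[i]] >> q[j]) & 1) code |= (1ULL << bit);
    if (code < best) best = code;
  } while (std::next_permutation(q.begin(), q.end()));
  return best;
}

// ---------------------------------------------------------------------------
// Min-degree greedy on the implicit conflict graph.
//
// items are local indices 0..m-1; keys[i] lists the conflict keys (edge ids
// for F2, node ids for F3) of item i; two items conflict iff they share a
// key. Items are selected in ascending (initial conflict-graph degree,
// index) order -- ties broken by smallest index, or uniformly at random
// within a tied group when randomTie -- and each selection removes the
// selected item's closed neighbourhood, so the result is a maximal
// independent set of the conflict (overlap) graph.
//
// Degrees are exact but the conflict graph is never materialised: by
// inclusion-exclusion over shared key subsets,
//   deg(i) = sum_{k>=1} (-1)^(k+1) sum_{S subset keys[i], |S|=k} t_S  - 1,
// where t_S counts the items whose key set contains S. Size-1 counts come
// from the key buckets; larger shared subsets are counted once via a
// sort-and-compress pass (subsets of up to 4 keys packed into 128-bit
// codes; wider key sets fall back to an ordered map and only arise for
// large motifs on small hosts). This is O(F1 * 2^q) instead of
// Theta(overlap edges), which is what makes hub-dense hosts (e.g. the
// 3-star motif on scale-free networks) tractable.
// ---------------------------------------------------------------------------
static std::vector<int> greedySelect(const std::vector<std::vector<int> >& keys,
                                     bool randomTie) {
  const int m = static_cast<int>(keys.size());
  std::vector<int> sel;
  if (m == 0) return sel;

  std::unordered_map<int, std::vector<int> > kb;
  for (int i = 0; i < m; ++i)
    for (size_t t = 0; t < keys[i].size(); ++t) kb[keys[i][t]].push_back(i);

  int kmax = 0;
  for (int i = 0; i < m; ++i)
    kmax = std::max(kmax, static_cast<int>(keys[i].size()));
  if (kmax > 20) stop("conflict key sets too large for degree computation");
  long long emissions = 0;
  for (int i = 0; i < m; ++i) emissions += 1LL << keys[i].size();
  if (emissions > 200000000LL)
    stop("conflict-degree computation too large for this input");

  typedef unsigned __int128 u128;
  const uint32_t PAD = 0xFFFFFFFFu;
  std::vector<u128> subs;
  std::map<std::vector<int>, int> big;  // shared subsets of > 4 keys
  std::vector<int> ks;                  // sorted key set of one item
  std::vector<int> sub;
  for (int i = 0; i < m; ++i) {
    ks.assign(keys[i].begin(), keys[i].end());
    std::sort(ks.begin(), ks.end());
    int k = static_cast<int>(ks.size());
    for (int mask = 1; mask < (1 << k); ++mask) {
      int pc = __builtin_popcount(mask);
      if (pc < 2) continue;
      if (pc <= 4) {
        uint32_t w[4] = {PAD, PAD, PAD, PAD};
        int t = 0;
        for (int b = 0; b < k; ++b)
          if (mask & (1 << b)) w[t++] = static_cast<uint32_t>(ks[b]);
        u128 code = ((u128)w[0] << 96) | ((u128)w[1] << 64) |
                    ((u128)w[2] << 32) | (u128)w[3];
        subs.push_back(code);
      } else {
        sub.clear();
        for (int b = 0; b < k; ++b) if (mask & (1 << b)) sub.push_back(ks[b]);
        ++big[sub];
      }
    }
  }
  std::sort(subs.begin(), subs.end());
  // compress runs, keeping only subsets shared by >= 2 items (a missing
  // subset is contained in exactly one item: t_S = 1)
  std::vector<u128> subKey;
  std::vector<int> subCnt;
  for (size_t i = 0; i < subs.size();) {
    size_t j = i;
    while (j < subs.size() && subs[j] == subs[i]) ++j;
    if (j - i >= 2) {
      subKey.push_back(subs[i]);
      subCnt.push_back(static_cast<int>(j - i));
    }
    i = j;
  }
  std::vector<u128>().swap(subs);

  std::vector<int> deg(m, 0);
  for (int i = 0; i < m; ++i) {
    ks.assign(keys[i].begin(), keys[i].end());
    std::sort(ks.begin(), ks.end());
    int k = static_cast<int>(ks.size());
    long long acc = 0;
    for (int mask = 1; mask < (1 << k); ++mask) {
      int pc = __builtin_popcount(mask);
      long long t;
      if (pc == 1) {
        int b = 0;
        while (!(mask & (1 << b))) ++b;
        t = static_cast<long long>(kb[ks[b]].size());
      } else if (pc <= 4) {
        uint32_t w[4] = {PAD, PAD, PAD, PAD};
        int s = 0;
        for (int b = 0; b < k; ++b)
          if (mask & (1 << b)) w[s++] = static_cast<uint32_t>(ks[b]);
        u128 code = ((u128)w[0] << 96) | ((u128)w[1] << 64) |
                    ((u128)w[2] << 32) | (u128)w[3];
        std::vector<u128>::iterator it =
            std::lower_bound(subKey.begin(), subKey.end(), code);
        t = (it != subKey.end() && *it == code)
                ? subCnt[it - subKey.begin()] : 1;
      } else {
        sub.clear();
        for (int b = 0; b < k; ++b) if (mask & (1 << b)) sub.push_back(ks[b]);
        std::map<std::vector<int>, int>::const_iterator it = big.find(sub);
        t = (it != big.end()) ? it->second : 1;
      }
      acc += (pc % 2 == 1) ? t : -t;
    }
    long long d = acc - 1;  // remove the item itself
    deg[i] = static_cast<int>(d);
  }

  // selection order: ascending (degree, index); random mode shuffles
  // within each equal-degree group
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&deg](int a, int b) {
                     return deg[a] != deg[b] ? deg[a] < deg[b] : a < b;
                   });
  if (randomTie) {
    size_t i = 0;
    while (i < order.size()) {
      size_t j = i;
      while (j < order.size() && deg[order[j]] == deg[order[i]]) ++j;
      for (size_t t = j - 1; t > i; --t) {  // Fisher-Yates within the group
        size_t r = i + static_cast<size_t>(unif_rand() * (t - i + 1));
        if (r > t) r = t;
        std::swap(order[t], order[r]);
      }
      i = j;
    }
  }

  std::vector<char> state(m, 0);  // 0 residual, 1 selected, 2 removed
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int i = order[oi];
    if (state[i] != 0) continue;
    state[i] = 1;
    sel.push_back(i);
    for (size_t t = 0; t < keys[i].size(); ++t) {
      const std::vector<int>& bu = kb[keys[i][t]];
      for (size_t s = 0; s < bu.size(); ++s)
        if (state[bu[s]] == 0) state[bu[s]] = 2;
    }
  }
  std::sort(sel.begin(), sel.end());
  return sel;
}

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------
class Engine {
public:
  // motif
  int q;     // motif edge count
  int patN;  // motif node count
  uint64_t patCanon;
  std::vector<int> patDeg;  // sorted motif degree sequence
  bool randomTie;

  // host graph
  std::vector<std::vector<std::pair<int, int> > > adj;  // node -> (nbr, edge)
  std::unordered_map<uint64_t, int> edgeIdOf;
  std::vector<int> eu, ev;
  std::vector<char> eAlive;
  long long nEdgesAlive;

  // embeddings
  std::vector<int> embEdges;  // flat, q entries per embedding (sorted ids)
  std::vector<char> embAlive, embMember;
  long long f1, f2;
  std::vector<std::vector<int> > D;  // edge id -> embedding ids (lazy dead)
  std::vector<int> Ddead;
  std::vector<int> owner;  // edge id -> owning F2 member, or -1

  std::vector<char> mark;  // scratch, indexed by edge id

  Engine(const IntegerMatrix& edges, int nNodes,
         const IntegerMatrix& pat, int patNodes, bool randTie)
      : randomTie(randTie), nEdgesAlive(0), f1(0), f2(0) {
    q = pat.nrow();
    patN = patNodes;
    if (q < 1 || q > MAXQ) stop("motif must have between 1 and %d edges", MAXQ);
    if (patN > MAXN) stop("motif must have at most %d nodes", MAXN);
    std::vector<std::pair<int, int> > pe(q);
    std::vector<int> pdeg(patN, 0);
    for (int i = 0; i < q; ++i) {
      pe[i] = std::make_pair(pat(i, 0), pat(i, 1));
      ++pdeg[pe[i].first];
      ++pdeg[pe[i].second];
    }
    patCanon = canon64(patN, pe);
    std::sort(pdeg.begin(), pdeg.end());
    patDeg = pdeg;

    adj.resize(nNodes);
    for (int i = 0; i < edges.nrow(); ++i) {
      int u = edges(i, 0), v = edges(i, 1);
      if (u == v) stop("self-loop in edge list");
      ensureNode(std::max(u, v));
      if (findAliveEdge(u, v) >= 0) stop("duplicate edge in edge list");
      addEdge(u, v);
    }
    mark.assign(eu.size(), 0);
    enumerateAll();
    initF2();
  }

  void ensureNode(int id) {
    if (id >= static_cast<int>(adj.size())) adj.resize(id + 1);
  }

  int findAliveEdge(int u, int v) const {
    std::unordered_map<uint64_t, int>::const_iterator it =
        edgeIdOf.find(ekey(u, v));
    if (it == edgeIdOf.end() || !eAlive[it->second]) return -1;
    return it->second;
  }

  int addEdge(int u, int v) {
    uint64_t k = ekey(u, v);
    std::unordered_map<uint64_t, int>::iterator it = edgeIdOf.find(k);
    int e;
    if (it == edgeIdOf.end()) {
      e = static_cast<int>(eu.size());
      edgeIdOf[k] = e;
      eu.push_back(std::min(u, v));
      ev.push_back(std::max(u, v));
      eAlive.push_back(1);
      D.push_back(std::vector<int>());
      Ddead.push_back(0);
      owner.push_back(-1);
    } else {
      e = it->second;
      eAlive[e] = 1;
    }
    adj[u].push_back(std::make_pair(v, e));
    adj[v].push_back(std::make_pair(u, e));
    ++nEdgesAlive;
    return e;
  }

  void dropEdge(int e) {
    int u = eu[e], v = ev[e];
    eAlive[e] = 0;
    --nEdgesAlive;
    for (size_t i = 0; i < adj[u].size(); ++i)
      if (adj[u][i].second == e) { adj[u].erase(adj[u].begin() + i); break; }
    for (size_t i = 0; i < adj[v].size(); ++i)
      if (adj[v][i].second == e) { adj[v].erase(adj[v].begin() + i); break; }
  }

  const int* edgesOf(int id) const { return &embEdges[static_cast<size_t>(id) * q]; }

  std::vector<int>& bucket(int e) {
    std::vector<int>& B = D[e];
    if (Ddead[e] > 0 && 2 * Ddead[e] >= static_cast<int>(B.size())) {
      size_t w = 0;
      for (size_t i = 0; i < B.size(); ++i)
        if (embAlive[B[i]]) B[w++] = B[i];
      B.resize(w);
      Ddead[e] = 0;
    }
    return B;
  }

  // --- enumeration ---------------------------------------------------------

  bool classify(const std::vector<int>& sub) const {
    int loc[2 * MAXQ];
    int nn = 0;
    std::pair<int, int> le[MAXQ];
    int ldeg[2 * MAXQ];
    for (int i = 0; i < q; ++i) {
      int a = -1, b = -1, gu = eu[sub[i]], gv = ev[sub[i]];
      for (int t = 0; t < nn; ++t) {
        if (loc[t] == gu) a = t;
        if (loc[t] == gv) b = t;
      }
      if (a < 0) { if (nn >= 2 * MAXQ) return false; loc[nn] = gu; a = nn++; }
      if (b < 0) { if (nn >= 2 * MAXQ) return false; loc[nn] = gv; b = nn++; }
      le[i] = std::make_pair(a, b);
    }
    if (nn != patN) return false;
    for (int t = 0; t < nn; ++t) ldeg[t] = 0;
    for (int i = 0; i < q; ++i) { ++ldeg[le[i].first]; ++ldeg[le[i].second]; }
    std::vector<int> ds(ldeg, ldeg + nn);
    std::sort(ds.begin(), ds.end());
    if (ds != patDeg) return false;
    std::vector<std::pair<int, int> > edges(le, le + q);
    return canon64(nn, edges) == patCanon;
  }

  void record(const std::vector<int>& sub) {
    if (!classify(sub)) return;
    int id = static_cast<int>(embAlive.size());
    std::vector<int> s(sub);
    std::sort(s.begin(), s.end());
    embEdges.insert(embEdges.end(), s.begin(), s.end());
    embAlive.push_back(1);
    embMember.push_back(0);
    ++f1;
    for (int i = 0; i < q; ++i) D[s[i]].push_back(id);
  }

  template <typename F>
  void forEachNbrEdge(int e, F f) const {
    int u = eu[e], v = ev[e];
    for (size_t i = 0; i < adj[u].size(); ++i)
      if (adj[u][i].second != e) f(adj[u][i].second);
    for (size_t i = 0; i < adj[v].size(); ++i)
      if (adj[v][i].second != e) f(adj[v][i].second);
  }

  struct Collect {
    Engine* E;
    std::vector<int>* ext;
    std::vector<int>* marked;
    int anchor;
    bool anchored;
    void operator()(int g) const {
      if (!E->eAlive[g] || E->mark[g]) return;
      if (!anchored && g <= anchor) {
        // still part of N(sub): must be excluded from deeper extensions
        E->mark[g] = 1;
        marked->push_back(g);
        return;
      }
      E->mark[g] = 1;
      marked->push_back(g);
      ext->push_back(g);
    }
  };

  void extend(std::vector<int>& sub, std::vector<int>& ext, int anchor,
              bool anchored) {
    if (static_cast<int>(sub.size()) == q) { record(sub); return; }
    while (!ext.empty()) {
      int f = ext.back();
      ext.pop_back();
      std::vector<int> ext2(ext);
      std::vector<int> marked;
      Collect c;
      c.E = this; c.ext = &ext2; c.marked = &marked;
      c.anchor = anchor; c.anchored = anchored;
      forEachNbrEdge(f, c);
      sub.push_back(f);
      extend(sub, ext2, anchor, anchored);
      sub.pop_back();
      for (size_t i = 0; i < marked.size(); ++i) mark[marked[i]] = 0;
    }
  }

  void enumerateAll() {
    std::vector<int> sub;
    sub.reserve(q);
    for (int a = 0; a < static_cast<int>(eu.size()); ++a) {
      if (!eAlive[a]) continue;
      sub.clear();
      sub.push_back(a);
      if (q == 1) { record(sub); continue; }
      std::vector<int> ext, marked;
      mark[a] = 1;
      marked.push_back(a);
      Collect c;
      c.E = this; c.ext = &ext; c.marked = &marked;
      c.anchor = a; c.anchored = false;
      forEachNbrEdge(a, c);
      extend(sub, ext, a, false);
      for (size_t i = 0; i < marked.size(); ++i) mark[marked[i]] = 0;
    }
  }

  // embeddings containing edge e (which must be freshly inserted, so every
  // subset found is new); returns their ids
  std::vector<int> discoverWithEdge(int e) {
    if (mark.size() < eu.size()) mark.resize(eu.size(), 0);
    int before = static_cast<int>(embAlive.size());
    std::vector<int> sub;
    sub.reserve(q);
    sub.push_back(e);
    if (q == 1) {
      record(sub);
    } else {
      std::vector<int> ext, marked;
      mark[e] = 1;
      marked.push_back(e);
      Collect c;
      c.E = this; c.ext = &ext; c.marked = &marked;
      c.anchor = e; c.anchored = true;
      forEachNbrEdge(e, c);
      extend(sub, ext, e, true);
      for (size_t i = 0; i < marked.size(); ++i) mark[marked[i]] = 0;
    }
    std::vector<int> ids;
    for (int id = before; id < static_cast<int>(embAlive.size()); ++id)
      ids.push_back(id);
    return ids;
  }

  // --- F2 ------------------------------------------------------------------

  std::vector<int> aliveIds() const {
    std::vector<int> ids;
    ids.reserve(static_cast<size_t>(f1));
    for (int id = 0; id < static_cast<int>(embAlive.size()); ++id)
      if (embAlive[id]) ids.push_back(id);
    return ids;
  }

  void initF2() {
    std::vector<int> ids = aliveIds();
    std::vector<std::vector<int> > keys(ids.size());
    for (size_t i = 0; i < ids.size(); ++i)
      keys[i].assign(edgesOf(ids[i]), edgesOf(ids[i]) + q);
    std::vector<int> sel = greedySelect(keys, randomTie);
    f2 = static_cast<long long>(sel.size());
    for (size_t i = 0; i < sel.size(); ++i) {
      int id = ids[sel[i]];
      embMember[id] = 1;
      for (int t = 0; t < q; ++t) owner[edgesOf(id)[t]] = id;
    }
  }

  // node-disjoint greedy over the current live embeddings (static F3)
  List nodeDisjoint() {
    std::vector<int> ids = aliveIds();
    std::vector<std::vector<int> > keys(ids.size());
    for (size_t i = 0; i < ids.size(); ++i) {
      std::vector<int> nodes;
      for (int t = 0; t < q; ++t) {
        int e = edgesOf(ids[i])[t];
        nodes.push_back(eu[e]);
        nodes.push_back(ev[e]);
      }
      std::sort(nodes.begin(), nodes.end());
      nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());
      keys[i] = nodes;
    }
    std::vector<int> sel = greedySelect(keys, randomTie);
    IntegerVector out(sel.size());
    for (size_t i = 0; i < sel.size(); ++i) out[i] = ids[sel[i]];
    return List::create(_["f3"] = static_cast<double>(sel.size()),
                        _["ids"] = out);
  }

  bool allFree(int id) const {
    for (int t = 0; t < q; ++t)
      if (owner[edgesOf(id)[t]] != -1) return false;
    return true;
  }

  // --- dynamic updates -----------------------------------------------------

  void deleteEdge(int u, int v) {
    int e = findAliveEdge(u, v);
    if (e < 0)
      stop("script-consistency error: deleting absent edge (%d, %d)", u, v);

    std::vector<int> dead;
    {
      std::vector<int>& B = bucket(e);
      for (size_t i = 0; i < B.size(); ++i)
        if (embAlive[B[i]]) dead.push_back(B[i]);
    }
    int X = -1;
    for (size_t i = 0; i < dead.size(); ++i)
      if (embMember[dead[i]]) X = dead[i];
    std::vector<int> Xedges;
    if (X >= 0) Xedges.assign(edgesOf(X), edgesOf(X) + q);

    for (size_t i = 0; i < dead.size(); ++i) {
      int id = dead[i];
      embAlive[id] = 0;
      --f1;
      for (int t = 0; t < q; ++t)
        if (edgesOf(id)[t] != e) ++Ddead[edgesOf(id)[t]];
    }
    D[e].clear();
    Ddead[e] = 0;
    dropEdge(e);

    if (X >= 0) {
      embMember[X] = 0;
      --f2;
      for (int t = 0; t < q; ++t) owner[Xedges[t]] = -1;  // release first
      // candidate replacements: surviving overlap-graph neighbours of X
      std::vector<int> cand;
      for (int t = 0; t < q; ++t) {
        if (Xedges[t] == e) continue;
        std::vector<int>& B = bucket(Xedges[t]);
        for (size_t i = 0; i < B.size(); ++i)
          if (embAlive[B[i]] && !embMember[B[i]]) cand.push_back(B[i]);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      int Y = -1;
      if (randomTie) {
        std::vector<int> ok;
        for (size_t i = 0; i < cand.size(); ++i)
          if (allFree(cand[i])) ok.push_back(cand[i]);
        if (!ok.empty()) {
          int pick = static_cast<int>(unif_rand() * ok.size());
          if (pick >= static_cast<int>(ok.size())) pick = ok.size() - 1;
          Y = ok[pick];
        }
      } else {
        for (size_t i = 0; i < cand.size(); ++i)
          if (allFree(cand[i])) { Y = cand[i]; break; }
      }
      if (Y >= 0) {
        embMember[Y] = 1;
        ++f2;
        for (int t = 0; t < q; ++t) owner[edgesOf(Y)[t]] = Y;
      }
    }
  }

  void insertEdge(int u, int v) {
    if (u == v) stop("script-consistency error: self-loop insertion");
    ensureNode(std::max(u, v));
    if (findAliveEdge(u, v) >= 0)
      stop("script-consistency error: inserting existing edge (%d, %d)", u, v);
    int e = addEdge(u, v);
    if (mark.size() < eu.size()) mark.resize(eu.size(), 0);
    std::vector<int> fresh = discoverWithEdge(e);
    int Y = -1;
    if (randomTie) {
      std::vector<int> ok;
      for (size_t i = 0; i < fresh.size(); ++i)
        if (allFree(fresh[i])) ok.push_back(fresh[i]);
      if (!ok.empty()) {
        int pick = static_cast<int>(unif_rand() * ok.size());
        if (pick >= static_cast<int>(ok.size())) pick = ok.size() - 1;
        Y = ok[pick];
      }
    } else {
      for (size_t i = 0; i < fresh.size(); ++i)
        if (allFree(fresh[i])) { Y = fresh[i]; break; }
    }
    if (Y >= 0) {
      embMember[Y] = 1;
      ++f2;
      for (int t = 0; t < q; ++t) owner[edgesOf(Y)[t]] = Y;
    }
  }
};


#endif  // DYNAMOTIF_TYPES_H
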