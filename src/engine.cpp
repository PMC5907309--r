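// Exported R interface over the counting engine (see dynamotif_types.h).

#include <Rcpp.h>
#include "dynamotif_types.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".canon_cpp")]]
std::string canon_cpp(int n, IntegerMatrix edges) {
  std::vector<std::pair<int, int> > pe(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i)
    pe[i] = std::make_pair(edges(i, 0), edges(i, 1));
  uint64_t c = canon64(n, pe);
  char buf[40];
  snprintf(buf, sizeof(buf), "%d:%llu", n, static_cast<unsigned long long>(c));
  return std::string(buf);
}

// [[Rcpp::export(name = ".greedy_cpp")]]
IntegerVector greedy_cpp(List keyList, bool randomTie) {
  std::vector<std::vector<int> > keys(keyList.size());
  for (int i = 0; i < keyList.size(); ++i) {
    IntegerVector k = keyList[i];
    keys[i].assign(k.begin(), k.end());
  }
  std::vector<int> sel = greedySelect(keys, randomTie);
  IntegerVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = sel[i] + 1;  // 1-based
  return out;
}

// [[Rcpp::export(name = ".eng_new")]]
XPtr<Engine> eng_new(IntegerMatrix edges, int nNodes, IntegerMatrix patEdges,
                     int patNodes, bool randomTie) {
  Engine* e = new Engine(edges, nNodes, patEdges, patNodes, randomTie);
  return XPtr<Engine>(e, true);
}

// [[Rcpp::export(name = ".eng_counts")]]
NumericVector eng_counts(XPtr<Engine> p) {
  return NumericVector::create(_["f1"] = static_cast<double>(p->f1),
                               _["f2"] = static_cast<double>(p->f2));
}

// [[Rcpp::export(name = ".eng_delete")]]
void eng_delete(XPtr<Engine> p, int u, int v) { p->deleteEdge(u, v); }

// [[Rcpp::export(name = ".eng_insert")]]
void eng_insert(XPtr<Engine> p, int u, int v) { p->insertEdge(u, v); }

// ops: n x 3 matrix (kind: +1 insert / -1 delete, u, v); returns per-step
// (f1, f2)
// [[Rcpp::export(name = ".eng_apply")]]
NumericMatrix eng_apply(XPtr<Engine> p, IntegerMatrix ops) {
  int n = ops.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    try {
      if (ops(i, 0) > 0)
        p->insertEdge(ops(i, 1), ops(i, 2));
      else
        p->deleteEdge(ops(i, 1), ops(i, 2));
    } catch (std::exception& ex) {
      stop("step %d: %s", i + 1, ex.what());
    }
    out(i, 0) = static_cast<double>(p->f1);
    out(i, 1) = static_cast<double>(p->f2);
  }
  return out;
}

// live embeddings: ids plus an (nEmb x 2q) matrix of node pairs per edge
// [[Rcpp::export(name = ".eng_embeddings")]]
List eng_embeddings(XPtr<Engine> p) {
  std::vector<int> ids = p->aliveIds();
  int q = p->q;
  IntegerMatrix mat(static_cast<int>(ids.size()), 2 * q);
  IntegerVector iv(ids.size()), mem(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) {
    iv[i] = ids[i];
    mem[i] = p->embMember[ids[i]] ? 1 : 0;
    for (int t = 0; t < q; ++t) {
      int e = p->edgesOf(ids[i])[t];
      mat(static_cast<int>(i), 2 * t) = p->eu[e];
      mat(static_cast<int>(i), 2 * t + 1) = p->ev[e];
    }
  }
  return List::create(_["ids"] = iv, _["edges"] = mat, _["member"] = mem);
}

// [[Rcpp::export(name = ".eng_edges")]]
IntegerMatrix eng_edges(XPtr<Engine> p) {
  std::vector<std::pair<int, int> > es;
  for (size_t e = 0; e < p->eu.size(); ++e)
    if (p->eAlive[e]) es.push_back(std::make_pair(p->eu[e], p->ev[e]));
  IntegerMatrix out(static_cast<int>(es.size()), 2);
  for (size_t i = 0; i < es.size(); ++i) {
    out(static_cast<int>(i), 0) = es[i].first;
    out(static_cast<int>(i), 1) = es[i].second;
  }
  return out;
}

// [[Rcpp::export(name = ".eng_f3")]]
List eng_f3(XPtr<Engine> p) { return p->nodeDisjoint(); }
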