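#include <Rcpp.h>
using namespace Rcpp;

// Tip states are bitmasks over character states (bit s set = state s allowed).
// Edge matrices follow ape's conventions (tips 1..ntip, internal nodes above)
// and must be in postorder so that children are visited before their parent.

static const int BIG = 1000000000;

// Classic set-valued Fitch fold. Exact on binary trees only; callers enforce.
static int fitch_one(const IntegerMatrix& edge, int ntip, const int* tips,
                     int nnode_total) {
  std::vector<int> mask(nnode_total + 1, 0);
  for (int i = 0; i < ntip; ++i) mask[i + 1] = tips[i];
  int steps = 0;
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    if (mask[p] == 0) {
      mask[p] = mask[c];
    } else {
      int inter = mask[p] & mask[c];
      if (inter) {
        mask[p] = inter;
      } else {
        mask[p] |= mask[c];
        ++steps;
      }
    }
  }
  return steps;
}

// Sankoff dynamic programme, linear cost |i-j| when ordered, unit cost
// otherwise. Exact on arbitrary (including multifurcating) trees.
static int sankoff_one(const IntegerMatrix& edge, int ntip, const int* tips,
                       int nstates, bool ordered, int nnode_total) {
  int S = nstates;
  std::vector<std::vector<int> > cost(nnode_total + 1,
                                      std::vector<int>(S, BIG));
  std::vector<bool> seen(nnode_total + 1, false);
  for (int i = 0; i < ntip; ++i) {
    for (int s = 0; s < S; ++s)
      cost[i + 1][s] = (tips[i] >> s) & 1 ? 0 : BIG;
    seen[i + 1] = true;
  }
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    if (!seen[p]) {
      std::fill(cost[p].begin(), cost[p].end(), 0);
      seen[p] = true;
    }
    // transfer cost of child c up the edge into parent p
    std::vector<int> up(S, BIG);
    if (ordered) {
      for (int s = 0; s < S; ++s) {
        int best = BIG;
        for (int t = 0; t < S; ++t) {
          if (cost[c][t] >= BIG) continue;
          int v = cost[c][t] + std::abs(s - t);
          if (v < best) best = v;
        }
        up[s] = best;
      }
    } else {
      int cmin = BIG;
      for (int t = 0; t < S; ++t) cmin = std::min(cmin, cost[c][t]);
      for (int s = 0; s < S; ++s)
        up[s] = std::min(cost[c][s], cmin == BIG ? BIG : cmin + 1);
    }
    for (int s = 0; s < S; ++s)
      cost[p][s] = (cost[p][s] >= BIG || up[s] >= BIG)
                       ? BIG
                       : cost[p][s] + up[s];
  }
  int root = edge(edge.nrow() - 1, 0);
  int best = BIG;
  for (int s = 0; s < S; ++s) best = std::min(best, cost[root][s]);
  return best;
}

// [[Rcpp::export(name = ".fitch_steps_cpp")]]
IntegerVector fitch_steps_cpp(IntegerMatrix edge, int ntip,
                              IntegerMatrix tipsets) {
  int nchar = tipsets.ncol();
  int nnode_total = ntip + edge.nrow();  // generous upper bound on node ids
  for (int e = 0; e < edge.nrow(); ++e)
    nnode_total = std::max(nnode_total, std::max(edge(e, 0), edge(e, 1)));
  IntegerVector out(nchar);
  std::vector<int> tips(ntip);
  for (int j = 0; j < nchar; ++j) {
    for (int i = 0; i < ntip; ++i) tips[i] = tipsets(i, j);
    out[j] = fitch_one(edge, ntip, tips.data(), nnode_total);
  }
  return out;
}

// [[Rcpp::export(name = ".sankoff_steps_cpp")]]
IntegerVector sankoff_steps_cpp(IntegerMatrix edge, int ntip,
                                IntegerMatrix tipsets, IntegerVector nstates,
                                LogicalVector ordered) {
  int nchar = tipsets.ncol();
  int nnode_total = ntip + edge.nrow();
  for (int e = 0; e < edge.nrow(); ++e)
    nnode_total = std::max(nnode_total, std::max(edge(e, 0), edge(e, 1)));
  IntegerVector out(nchar);
  std::vector<int> tips(ntip);
  for (int j = 0; j < nchar; ++j) {
    for (int i = 0; i < ntip; ++i) tips[i] = tipsets(i, j);
    out[j] = sankoff_one(edge, ntip, tips.data(), nstates[j], ordered[j],
                         nnode_total);
  }
  return out;
}

// Per-character steps for many trees at once (binary trees assumed: Fitch for
// unordered characters, Sankoff for ordered). Used by searches and oracles.
// [[Rcpp::export(name = ".steps_many_cpp")]]
IntegerMatrix steps_many_cpp(List edges, int ntip, IntegerMatrix tipsets,
                             IntegerVector nstates, LogicalVector ordered) {
  int ntree = edges.size(), nchar = tipsets.ncol();
  IntegerMatrix out(ntree, nchar);
  std::vector<int> tips(ntip);
  for (int k = 0; k < ntree; ++k) {
    IntegerMatrix edge = edges[k];
    int nnode_total = ntip + edge.nrow();
    for (int e = 0; e < edge.nrow(); ++e)
      nnode_total = std::max(nnode_total, std::max(edge(e, 0), edge(e, 1)));
    for (int j = 0; j < nchar; ++j) {
      for (int i = 0; i < ntip; ++i) tips[i] = tipsets(i, j);
      out(k, j) = ordered[j]
                      ? sankoff_one(edge, ntip, tips.data(), nstates[j], true,
                                    nnode_total)
                      : fitch_one(edge, ntip, tips.data(), nnode_total);
    }
  }
  return out;
}
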