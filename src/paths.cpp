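// Enumeration of transcription-activation shortest paths.
//
// A path is a simple directed edge sequence source -> ... -> target whose
// final edge is a transcription-regulation edge leaving a transcription
// factor, whose hop count is minimal among admissible paths for its
// (source, target) pair (and <= max_len), and whose number of inhibitory
// edges has the configured parity.  Parallel edges count as distinct paths.
//
// Enumeration runs backwards from each target so every prefix of a partial
// path is itself a candidate path from its own source node.

#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct PairRec {
  int best = INT_MAX;
  std::vector<std::vector<int> > paths;  // node sequences, backwards (t..s)
};

struct Enumerator {
  int n_nodes, max_len, parity;
  const IntegerVector &from, &to;
  const LogicalVector &inhib;
  std::vector<std::vector<int> > in_edges;  // per node: incoming edge idx
  std::vector<char> visited;
  std::vector<int> path;  // node sequence, starts at target
  std::unordered_map<int, PairRec> recs;  // keyed by source node

  Enumerator(int n_nodes_, int max_len_, int parity_,
             const IntegerVector &from_, const IntegerVector &to_,
             const LogicalVector &inhib_)
      : n_nodes(n_nodes_), max_len(max_len_), parity(parity_),
        from(from_), to(to_), inhib(inhib_),
        in_edges(n_nodes_ + 1), visited(n_nodes_ + 1, 0) {
    for (int e = 0; e < from_.size(); ++e) in_edges[to_[e]].push_back(e);
  }

  void extend(int v, int len, int n_inhib) {
    // the partial path target..v, read forwards, is a candidate path from v
    if ((n_inhib & 1) == parity) {
      PairRec &rec = recs[v];
      if (len < rec.best) {
        rec.best = len;
        rec.paths.clear();
        rec.paths.push_back(path);
      } else if (len == rec.best) {
        rec.paths.push_back(path);
      }
    }
    if (len == max_len) return;
    const std::vector<int> &es = in_edges[v];
    for (size_t i = 0; i < es.size(); ++i) {
      int e = es[i];
      int u = from[e];
      if (visited[u]) continue;
      visited[u] = 1;
      path.push_back(u);
      extend(u, len + 1, n_inhib + (inhib[e] ? 1 : 0));
      path.pop_back();
      visited[u] = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List enumerate_activation_paths_cpp(int n_nodes, IntegerVector edge_from,
                                    IntegerVector edge_to,
                                    LogicalVector edge_inhib,
                                    LogicalVector edge_terminal,
                                    IntegerVector targets, int max_len,
                                    int parity, bool keep_paths) {
  int n_targets = targets.size();
  IntegerMatrix containment(n_nodes, n_targets);
  IntegerVector per_target(n_targets);
  int n_paths = 0;
  List path_list;
  std::vector<SEXP> collected;
  std::vector<int> collected_target;

  for (int ti = 0; ti < n_targets; ++ti) {
    int t = targets[ti];
    Enumerator en(n_nodes, max_len, parity, edge_from, edge_to, edge_inhib);
    en.visited[t] = 1;
    en.path.push_back(t);
    // seed with every terminal transcription-regulation edge into t
    for (size_t i = 0; i < en.in_edges[t].size(); ++i) {
      int e = en.in_edges[t][i];
      if (!edge_terminal[e]) continue;
      int f = edge_from[e];
      if (en.visited[f]) continue;  // self-loop guard
      en.visited[f] = 1;
      en.path.push_back(f);
      en.extend(f, 1, edge_inhib[e] ? 1 : 0);
      en.path.pop_back();
      en.visited[f] = 0;
    }
    for (std::unordered_map<int, PairRec>::const_iterator it = en.recs.begin();
         it != en.recs.end(); ++it) {
      const PairRec &rec = it->second;
      for (size_t pi = 0; pi < rec.paths.size(); ++pi) {
        const std::vector<int> &nodes = rec.paths[pi];
        ++n_paths;
        ++per_target[ti];
        for (size_t k = 0; k < nodes.size(); ++k)
          ++containment(nodes[k] - 1, ti);
        if (keep_paths) {
          IntegerVector fwd(nodes.size());
          for (size_t k = 0; k < nodes.size(); ++k)
            fwd[k] = nodes[nodes.size() - 1 - k];
          collected.push_back(fwd);
          collected_target.push_back(t);
        }
      }
    }
  }

  List out = List::create(
      Named("n_paths") = n_paths, Named("per_target") = per_target,
      Named("containment") = containment);
  if (keep_paths) {
    List pl(collected.size());
    IntegerVector pt(collected.size());
    for (size_t i = 0; i < collected.size(); ++i) {
      pl[i] = collected[i];
      pt[i] = collected_target[i];
    }
    out["paths"] = pl;
    out["path_target"] = pt;
  }
  return out;
}
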