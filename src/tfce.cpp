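#include <Rcpp.h>
using namespace Rcpp;

// Threshold-free cluster enhancement on a channel graph.
// map: non-negative statistic per channel; adj: 0-based neighbour lists.
// For each threshold h = dh, 2dh, ... <= max(map), every suprathreshold
// channel accumulates extent(h)^E * h^H * dh, where extent(h) is the size
// of the suprathreshold connected component containing it.
// [[Rcpp::export(name = ".tfce_core")]]
NumericVector tfce_core(NumericVector map, List adj, double E, double H,
                        double dh, int n_steps) {
  int n = map.size();
  NumericVector out(n);
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) nb[i] = as<std::vector<int> >(adj[i]);
  std::vector<int> comp(n), stack;
  std::vector<int> members;
  for (int k = 1; k <= n_steps; ++k) {
    double h = k * dh;
    std::fill(comp.begin(), comp.end(), -1);
    for (int i = 0; i < n; ++i) {
      if (map[i] < h || comp[i] != -1) continue;
      members.clear();
      stack.push_back(i);
      comp[i] = i;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        members.push_back(v);
        for (size_t j = 0; j < nb[v].size(); ++j) {
          int u = nb[v][j];
          if (map[u] >= h && comp[u] == -1) { comp[u] = i; stack.push_back(u); }
        }
      }
      double add = std::pow((double)members.size(), E) * std::pow(h, H) * dh;
      for (size_t j = 0; j < members.size(); ++j) out[members[j]] += add;
    }
  }
  return out;
}
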