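#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time Markov jump chain on a rate network. Uses R's RNG so runs
// are reproducible via set.seed(). Edge classes: 1=BB 2=HB 3=HC 4=HEAT 5=COOL.
// outcome: 1 = sensor arrival, 2 = solvent absorption, 3 = t_max reached.
// [[Rcpp::export]]
List jump_chain_cpp(int n_nodes, IntegerVector from, IntegerVector to,
                    NumericVector rate, IntegerVector edge_class,
                    int source, int sensor, int solvent,
                    int n_walkers, double t_max, bool record_paths) {
  int n_edges = from.size();
  // per-node outgoing edge lists with cumulative rates for categorical draws
  std::vector<std::vector<int> > out_edges(n_nodes);
  std::vector<double> total_rate(n_nodes, 0.0);
  for (int e = 0; e < n_edges; ++e) {
    out_edges[from[e]].push_back(e);
    total_rate[from[e]] += rate[e];
  }
  std::vector<std::vector<double> > cum(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    double acc = 0.0;
    cum[v].reserve(out_edges[v].size());
    for (size_t k = 0; k < out_edges[v].size(); ++k) {
      acc += rate[out_edges[v][k]];
      cum[v].push_back(acc);
    }
  }

  IntegerVector outcome(n_walkers), seen_hb(n_walkers), seen_hc(n_walkers),
      n_jumps(n_walkers);
  NumericVector time(n_walkers);
  List paths = record_paths ? List(n_walkers) : List(0);
  std::vector<int> path_buf;

  RNGScope scope;
  for (int w = 0; w < n_walkers; ++w) {
    int node = source;
    double t = 0.0;
    int hb = 0, hc = 0, jumps = 0, res = 3;
    if (record_paths) path_buf.clear();
    if (node == sensor) {
      res = 1;
    } else {
      for (;;) {
        if (node == solvent) { res = 2; break; }
        double R = total_rate[node];
        if (R <= 0.0) { res = 3; t = t_max; break; }  // guarded in R wrapper
        t += R::rexp(1.0) / R;
        if (t > t_max) { t = t_max; res = 3; break; }
        double u = ::unif_rand() * R;
        const std::vector<double>& cv = cum[node];
        int lo = 0, hi = (int)cv.size() - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (u <= cv[mid]) hi = mid; else lo = mid + 1;
        }
        int e = out_edges[node][lo];
        ++jumps;
        if (record_paths) path_buf.push_back(e + 1);
        int cls = edge_class[e];
        if (cls == 2) hb = 1;
        else if (cls == 3) hc = 1;
        node = to[e];
        if (node == sensor) { res = 1; break; }
      }
    }
    outcome[w] = res;
    time[w] = t;
    seen_hb[w] = hb;
    seen_hc[w] = hc;
    n_jumps[w] = jumps;
    if (record_paths) paths[w] = IntegerVector(path_buf.begin(), path_buf.end());
    if ((w & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["time"] = time,
                      _["seen_hb"] = seen_hb, _["seen_hc"] = seen_hc,
                      _["n_jumps"] = n_jumps, _["paths"] = paths);
}
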