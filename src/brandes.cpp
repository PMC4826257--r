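#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

// Brandes' betweenness accumulation on an unweighted undirected graph.
// adj is a list of 0-based integer neighbour vectors, one per node.
// Accumulating the single-source dependencies from every source counts
// every ordered pair (s, t) once, which matches the normalisation
// B_v = sum / ((n-1)(n-2)) over ordered pairs; the division is done by
// the R wrapper.
// [[Rcpp::export(name = ".brandes_cpp")]]
NumericVector brandes_cpp(List adj) {
  const int n = adj.size();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
  }
  NumericVector bc(n, 0.0);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n);
  std::vector< std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    std::stack<int> order;
    for (int i = 0; i < n; ++i) {
      pred[i].clear();
      sigma[i] = 0.0;
      delta[i] = 0.0;
      dist[i] = -1;
    }
    sigma[s] = 1.0;
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push(v);
      for (int w : nb[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    while (!order.empty()) {
      int w = order.top(); order.pop();
      for (int v : pred[w]) {
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc;
}
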