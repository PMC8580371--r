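#include <Rcpp.h>
#include <vector>
#include <queue>

// Brandes betweenness for an unweighted undirected simple graph.
// Each unordered source/target pair contributes once; endpoints excluded;
// no normalization. Vertices are 0-based.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_betweenness(int n,
                                    Rcpp::IntegerVector from,
                                    Rcpp::IntegerVector to) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < from.size(); ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }
  Rcpp::NumericVector cb(n);
  std::vector<int> dist(n), order;
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();

    std::queue<int> q;
    dist[s] = 0;
    sigma[s] = 1.0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      order.push_back(v);
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
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
    // dependency accumulation in reverse BFS order
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) cb[w] += delta[w];
    }
  }
  // every unordered pair was visited from both endpoints
  for (int i = 0; i < n; ++i) cb[i] /= 2.0;
  return cb;
}
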