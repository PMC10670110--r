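#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Graph primitives for binary undirected networks, used in the online
// feedback loop where ~10^4 small-worldness evaluations per session make
// per-call overhead matter. Adjacency matrices are dense 0/1 (n <= a few
// hundred); algorithms are the textbook ones: neighbour-pair triangle
// counting for clustering, BFS for shortest paths, Maslov-Sneppen
// double-edge swaps for degree-preserving nulls.

static std::vector<std::vector<int>> adj_list(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// Node-averaged Watts-Strogatz clustering coefficient; nodes with fewer
// than two neighbours contribute 0.
// [[Rcpp::export]]
double cpp_clustering(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int)nb[i].size();
    if (k < 2) continue;
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb[i][a], nb[i][b]) != 0) ++tri;
    total += 2.0 * tri / (k * (double)(k - 1));
  }
  return total / n;
}

// Characteristic path length: mean shortest-path length over ordered pairs
// with finite distance (disconnected pairs dropped from numerator and
// denominator). Returns NA if no finite pair exists (edgeless graph).
// [[Rcpp::export]]
double cpp_path_length(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  double sum = 0.0;
  long long pairs = 0;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nb[u]) {
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          q.push(v);
        }
      }
    }
    for (int t = 0; t < n; ++t) {
      if (t != s && dist[t] > 0) { sum += dist[t]; ++pairs; }
    }
  }
  if (pairs == 0) return NA_REAL;
  return sum / pairs;
}

static double clustering_flat(const std::vector<std::vector<int>>& nb,
                              const std::vector<char>& has, int n) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int)nb[i].size();
    if (k < 2) continue;
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (has[(size_t)nb[i][a] * n + nb[i][b]]) ++tri;
    total += 2.0 * tri / (k * (double)(k - 1));
  }
  return total / n;
}

static double path_length_from_nb(const std::vector<std::vector<int>>& nb) {
  int n = (int)nb.size();
  double sum = 0.0;
  long long pairs = 0;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nb[u]) {
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
      }
    }
    for (int t = 0; t < n; ++t)
      if (t != s && dist[t] > 0) { sum += dist[t]; ++pairs; }
  }
  if (pairs == 0) return NA_REAL;
  return sum / pairs;
}

// Clustering and path length of `count` Maslov-Sneppen nulls of one graph,
// generated and measured without returning the graphs (the online engine
// only needs the ensemble means). Column 1 = C, column 2 = L; attribute
// "short" counts nulls that fell short of the target swap count.
// [[Rcpp::export]]
NumericMatrix cpp_null_metrics(const IntegerMatrix& edges, int n_nodes,
                               int count, int target_swaps, int max_attempts) {
  int m = edges.nrow();
  NumericMatrix out(count, 2);
  int n_short = 0;
  std::vector<char> has((size_t)n_nodes * n_nodes);
  for (int rep = 0; rep < count; ++rep) {
    std::vector<int> ea(m), eb(m);
    std::fill(has.begin(), has.end(), 0);
    for (int e = 0; e < m; ++e) {
      ea[e] = edges(e, 0) - 1;
      eb[e] = edges(e, 1) - 1;
      has[(size_t)ea[e] * n_nodes + eb[e]] = has[(size_t)eb[e] * n_nodes + ea[e]] = 1;
    }
    int done = 0;
    if (m >= 2) {
      for (int att = 0; att < max_attempts && done < target_swaps; ++att) {
        int e1 = (int)(unif_rand() * m);
        int e2 = (int)(unif_rand() * m);
        if (e1 == e2) continue;
        int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
        if (unif_rand() < 0.5) std::swap(c, d);
        if (a == d || c == b || a == c || b == d) continue;
        if (has[(size_t)a * n_nodes + d] || has[(size_t)c * n_nodes + b]) continue;
        has[(size_t)a * n_nodes + b] = has[(size_t)b * n_nodes + a] = 0;
        has[(size_t)c * n_nodes + d] = has[(size_t)d * n_nodes + c] = 0;
        has[(size_t)a * n_nodes + d] = has[(size_t)d * n_nodes + a] = 1;
        has[(size_t)c * n_nodes + b] = has[(size_t)b * n_nodes + c] = 1;
        eb[e1] = d;
        eb[e2] = b;
        ea[e2] = c;
        ++done;
      }
    }
    if (done < target_swaps) ++n_short;
    std::vector<std::vector<int>> nb(n_nodes);
    for (int e = 0; e < m; ++e) {
      nb[ea[e]].push_back(eb[e]);
      nb[eb[e]].push_back(ea[e]);
    }
    out(rep, 0) = clustering_flat(nb, has, n_nodes);
    out(rep, 1) = path_length_from_nb(nb);
  }
  out.attr("short") = n_short;
  return out;
}

// Degree-preserving randomization by repeated double-edge swaps.
// `edges` is an m x 2 one-based edge list. Attempts swaps until
// `target_swaps` succeed or `max_attempts` draws are spent; returns the
// rewired edge list with the achieved swap count as attribute "swaps".
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_degseq_rewire(const IntegerMatrix& edges, int n_nodes,
                                int target_swaps, int max_attempts) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  // adjacency lookup for duplicate detection
  std::vector<std::vector<bool>> has(n_nodes, std::vector<bool>(n_nodes, false));
  for (int e = 0; e < m; ++e) {
    ea[e] = edges(e, 0) - 1;
    eb[e] = edges(e, 1) - 1;
    has[ea[e]][eb[e]] = has[eb[e]][ea[e]] = true;
  }
  int done = 0;
  if (m >= 2) {
    for (int att = 0; att < max_attempts && done < target_swaps; ++att) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 == e2) continue;
      int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      // randomly orient the second edge so both pairings are reachable
      if (unif_rand() < 0.5) std::swap(c, d);
      // proposed replacement: (a,d) and (c,b)
      if (a == d || c == b) continue;
      if (a == c || b == d) continue;        // shared endpoint: swap is a no-op or loop
      if (has[a][d] || has[c][b]) continue;  // would duplicate an edge
      has[a][b] = has[b][a] = false;
      has[c][d] = has[d][c] = false;
      has[a][d] = has[d][a] = true;
      has[c][b] = has[b][c] = true;
      eb[e1] = d;
      eb[e2] = b;
      ea[e2] = c;
      ++done;
    }
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = ea[e] + 1;
    out(e, 1) = eb[e] + 1;
  }
  out.attr("swaps") = done;
  return out;
}
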