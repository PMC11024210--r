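#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Prim's algorithm on the Euclidean distances of a point set.
// pts: m x d coordinate matrix. Returns parent vector (parent[0] = -1).
static std::vector<int> prim(const std::vector<double>& pts, int m, int d) {
  std::vector<int> parent(m, -1);
  std::vector<bool> in_tree(m, false);
  std::vector<double> best(m, std::numeric_limits<double>::infinity());
  std::vector<int> best_from(m, -1);
  best[0] = 0.0;
  for (int it = 0; it < m; ++it) {
    int u = -1;
    double bu = std::numeric_limits<double>::infinity();
    for (int v = 0; v < m; ++v)
      if (!in_tree[v] && best[v] < bu) { bu = best[v]; u = v; }
    in_tree[u] = true;
    parent[u] = best_from[u];
    for (int v = 0; v < m; ++v) {
      if (in_tree[v]) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = pts[u * d + k] - pts[v * d + k];
        s += diff * diff;
      }
      if (s < best[v]) { best[v] = s; best_from[v] = u; }
    }
  }
  return parent;
}

// [[Rcpp::export(name = ".cpp_mst_edges")]]
IntegerMatrix cpp_mst_edges(NumericMatrix coords) {
  int m = coords.nrow(), d = coords.ncol();
  std::vector<double> pts(m * d);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) pts[i * d + k] = coords(i, k);
  std::vector<int> parent = prim(pts, m, d);
  IntegerMatrix edges(m - 1, 2);
  int e = 0;
  for (int v = 0; v < m; ++v)
    if (parent[v] >= 0) { edges(e, 0) = parent[v] + 1; edges(e, 1) = v + 1; ++e; }
  return edges;
}

// One bootstrap replicate: build the Euclidean MST of the subsampled cells
// and add every pairwise along-tree path length into the running sum and
// copresence matrices (upper storage, full symmetric write).
// idx: 0-based indices of the subsample into the full cell set.
// [[Rcpp::export(name = ".cpp_mst_accumulate")]]
void cpp_mst_accumulate(NumericMatrix coords, IntegerVector idx,
                        NumericMatrix dsum, IntegerMatrix dcount) {
  int m = idx.size(), d = coords.ncol();
  std::vector<double> pts(m * d);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) pts[i * d + k] = coords(idx[i], k);
  std::vector<int> parent = prim(pts, m, d);

  // adjacency lists with edge lengths
  std::vector<std::vector<std::pair<int, double> > > adj(m);
  for (int v = 0; v < m; ++v) {
    int p = parent[v];
    if (p < 0) continue;
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double diff = pts[v * d + k] - pts[p * d + k];
      s += diff * diff;
    }
    double w = std::sqrt(s);
    adj[v].push_back(std::make_pair(p, w));
    adj[p].push_back(std::make_pair(v, w));
  }

  // along-tree distances from every root via iterative DFS
  std::vector<double> dist(m);
  std::vector<int> stack(m);
  for (int r = 0; r < m; ++r) {
    std::fill(dist.begin(), dist.end(), -1.0);
    dist[r] = 0.0;
    int top = 0;
    stack[top++] = r;
    while (top > 0) {
      int u = stack[--top];
      for (size_t a = 0; a < adj[u].size(); ++a) {
        int v = adj[u][a].first;
        if (dist[v] >= 0.0) continue;
        dist[v] = dist[u] + adj[u][a].second;
        stack[top++] = v;
      }
    }
    int gi = idx[r];
    for (int v = r + 1; v < m; ++v) {
      int gj = idx[v];
      dsum(gi, gj) += dist[v];
      dsum(gj, gi) += dist[v];
      dcount(gi, gj) += 1;
      dcount(gj, gi) += 1;
    }
  }
}
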