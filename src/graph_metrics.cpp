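#include <Rcpp.h>
using namespace Rcpp;

// Graphs arrive as CSR adjacency: ptr has length n+1, idx has length 2E,
// both 0-based.  All distances are unit-weight BFS distances, which for a
// binary graph coincide with Dijkstra's algorithm.

// [[Rcpp::export]]
IntegerVector cpp_bfs_distances(IntegerVector ptr, IntegerVector idx,
                                int n, int source) {
  std::vector<int> dist(n, -1), q(n);
  int head = 0, tail = 0;
  dist[source] = 0;
  q[tail++] = source;
  while (head < tail) {
    int v = q[head++];
    int dv = dist[v];
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int u = idx[e];
      if (dist[u] < 0) {
        dist[u] = dv + 1;
        q[tail++] = u;
      }
    }
  }
  return wrap(dist);  // -1 marks unreachable
}

// Nodal global efficiency: mean of 1/d over all other nodes, 1/inf = 0.
// [[Rcpp::export]]
NumericVector cpp_eglob(IntegerVector ptr, IntegerVector idx, int n) {
  NumericVector out(n);
  if (n < 2) return out;
  std::vector<int> dist(n), q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    q[tail++] = s;
    double acc = 0.0;
    while (head < tail) {
      int v = q[head++];
      int dv = dist[v];
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int u = idx[e];
        if (dist[u] < 0) {
          dist[u] = dv + 1;
          acc += 1.0 / (dv + 1);
          q[tail++] = u;
        }
      }
    }
    out[s] = acc / (n - 1.0);
  }
  return out;
}

// Per-source sum of finite distances and count of reachable nodes,
// used for characteristic path length diagnostics.
// [[Rcpp::export]]
List cpp_distance_summary(IntegerVector ptr, IntegerVector idx, int n) {
  NumericVector dsum(n);
  IntegerVector dcount(n);
  std::vector<int> dist(n), q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    q[tail++] = s;
    double acc = 0.0;
    int cnt = 0;
    while (head < tail) {
      int v = q[head++];
      int dv = dist[v];
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int u = idx[e];
        if (dist[u] < 0) {
          dist[u] = dv + 1;
          acc += dv + 1.0;
          ++cnt;
          q[tail++] = u;
        }
      }
    }
    dsum[s] = acc;
    dcount[s] = cnt;
  }
  return List::create(_["sum"] = dsum, _["count"] = dcount);
}

// Nodal local efficiency: global efficiency over ordered pairs inside the
// subgraph induced by a node's direct neighbors (the node itself excluded).
// Degree < 2 yields 0.
// [[Rcpp::export]]
NumericVector cpp_eloc(IntegerVector ptr, IntegerVector idx, int n) {
  NumericVector out(n);
  std::vector<int> mark(n, -1);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    int k = ptr[i + 1] - ptr[i];
    if (k < 2) {
      out[i] = 0.0;
      continue;
    }
    nb.assign(idx.begin() + ptr[i], idx.begin() + ptr[i + 1]);
    for (int a = 0; a < k; ++a) mark[nb[a]] = a;
    std::vector<int> dist(k), q(k);
    double acc = 0.0;
    for (int a = 0; a < k; ++a) {
      std::fill(dist.begin(), dist.end(), -1);
      int head = 0, tail = 0;
      dist[a] = 0;
      q[tail++] = a;
      while (head < tail) {
        int v = q[head++];
        int g = nb[v];
        for (int e = ptr[g]; e < ptr[g + 1]; ++e) {
          int lu = mark[idx[e]];
          if (lu >= 0 && dist[lu] < 0) {
            dist[lu] = dist[v] + 1;
            acc += 1.0 / dist[lu];
            q[tail++] = lu;
          }
        }
      }
    }
    out[i] = acc / ((double)k * (k - 1.0));
    for (int a = 0; a < k; ++a) mark[nb[a]] = -1;
  }
  return out;
}

// Core numbers via the Batagelj-Zaversnik O(E) peeling algorithm: a node's
// core number is the largest k such that it survives iterative removal of
// all nodes with degree < k.
// [[Rcpp::export]]
IntegerVector cpp_kcore(IntegerVector ptr, IntegerVector idx, int n) {
  std::vector<int> deg(n), vert(n), pos(n);
  int md = 0;
  for (int i = 0; i < n; ++i) {
    deg[i] = ptr[i + 1] - ptr[i];
    if (deg[i] > md) md = deg[i];
  }
  std::vector<int> bin(md + 1, 0);
  for (int i = 0; i < n; ++i) bin[deg[i]]++;
  int start = 0;
  for (int d = 0; d <= md; ++d) {
    int c = bin[d];
    bin[d] = start;
    start += c;
  }
  for (int i = 0; i < n; ++i) {
    pos[i] = bin[deg[i]];
    vert[pos[i]] = i;
    bin[deg[i]]++;
  }
  for (int d = md; d > 0; --d) bin[d] = bin[d - 1];
  bin[0] = 0;
  std::vector<int> core(deg);
  for (int t = 0; t < n; ++t) {
    int v = vert[t];
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int u = idx[e];
      if (core[u] > core[v]) {
        int du = core[u], pu = pos[u], pw = bin[du], w = vert[pw];
        if (u != w) {
          pos[u] = pw;
          vert[pu] = w;
          pos[w] = pu;
          vert[pw] = u;
        }
        bin[du]++;
        core[u]--;
      }
    }
  }
  return wrap(core);
}
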