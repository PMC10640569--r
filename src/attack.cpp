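#include <Rcpp.h>
using namespace Rcpp;

// Reverse (additive) union-find component tracing: removing the first k
// nodes of an order equals building the graph up from the remaining nodes.

static int find_root(std::vector<int>& parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

static void trace_s1s2(const std::vector<std::vector<int>>& adj,
                       const int* order, int N,
                       std::vector<int>& S1, std::vector<int>& S2) {
  std::vector<int> parent(N), csize(N, 0);
  std::vector<bool> present(N, false);
  int s1 = 0, s2 = 0;
  for (int k = N; k >= 1; --k) {
    S1[k - 1] = s1;
    S2[k - 1] = s2;
    int v = order[k - 1] - 1;
    present[v] = true;
    parent[v] = v;
    csize[v] = 1;
    for (int u1 : adj[v]) {
      int u = u1 - 1;
      if (!present[u]) continue;
      int ra = find_root(parent, v), rb = find_root(parent, u);
      if (ra != rb) {
        if (csize[ra] < csize[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        csize[ra] += csize[rb];
      }
    }
    s1 = 0;
    s2 = 0;
    for (int u = 0; u < N; ++u) {
      if (present[u] && parent[u] == u) {
        int sz = csize[u];
        if (sz > s1) { s2 = s1; s1 = sz; }
        else if (sz > s2) s2 = sz;
      }
    }
  }
}

static std::vector<std::vector<int>> as_adj(List nbrs) {
  int N = nbrs.size();
  std::vector<std::vector<int>> adj(N);
  for (int v = 0; v < N; ++v) {
    IntegerVector nb = nbrs[v];
    adj[v].assign(nb.begin(), nb.end());
  }
  return adj;
}

// [[Rcpp::export]]
IntegerMatrix trace_components_cpp(List nbrs, IntegerVector order) {
  int N = order.size();
  std::vector<std::vector<int>> adj = as_adj(nbrs);
  std::vector<int> S1(N), S2(N);
  trace_s1s2(adj, order.begin(), N, S1, S2);
  IntegerMatrix out(N, 2);
  for (int k = 0; k < N; ++k) {
    out(k, 0) = S1[k];
    out(k, 1) = S2[k];
  }
  return out;
}

// One thresholded graph, many removal orders: per iteration the percolation
// point (first argmax of S2, as a fraction of N) and the set of nodes
// removed strictly before the percolation step, accumulated as counts.
// [[Rcpp::export]]
List attack_batch_cpp(List nbrs, IntegerMatrix orders) {
  int N = orders.nrow(), R = orders.ncol();
  std::vector<std::vector<int>> adj = as_adj(nbrs);
  std::vector<int> S1(N), S2(N);
  NumericVector perc(R);
  IntegerVector prefail(N);
  for (int r = 0; r < R; ++r) {
    const int* ord = &orders(0, r);
    trace_s1s2(adj, ord, N, S1, S2);
    int kstar = 1, smax = S2[0];
    for (int k = 2; k <= N; ++k) {
      if (S2[k - 1] > smax) { smax = S2[k - 1]; kstar = k; }
    }
    perc[r] = (double)kstar / N;
    for (int k = 0; k < kstar - 1; ++k) prefail[ord[k] - 1]++;
  }
  return List::create(Named("perc") = perc, Named("prefail") = prefail);
}
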