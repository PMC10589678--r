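#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// nodal degree, clustering coefficient and (Brandes) betweenness of an
// undirected unweighted graph given as a 1-based edge list
static void nodal_stats(const std::vector<int>& ei, const std::vector<int>& ej,
                        int n, std::vector<double>& deg,
                        std::vector<double>& clu, std::vector<double>& btw) {
  int m = ei.size();
  std::vector<std::vector<int>> adj(n);
  std::vector<char> A(n * n, 0);
  for (int e = 0; e < m; ++e) {
    int i = ei[e], j = ej[e];
    adj[i].push_back(j);
    adj[j].push_back(i);
    A[i + n * j] = A[j + n * i] = 1;
  }
  deg.assign(n, 0.0); clu.assign(n, 0.0); btw.assign(n, 0.0);
  for (int v = 0; v < n; ++v) deg[v] = adj[v].size();
  for (int v = 0; v < n; ++v) {
    int k = adj[v].size();
    if (k < 2) continue;
    int t = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A[adj[v][a] + n * adj[v][b]]) ++t;
    clu[v] = 2.0 * t / (double(k) * (k - 1));
  }
  // Brandes (2001), unweighted, two-pass dependency accumulation (the
  // shortest-path DAG is re-derived from BFS distances on the way back);
  // halved for undirected pair counting
  std::vector<int> dist(n), S(n);
  std::vector<double> sigma(n), delta(n);
  for (int s = 0; s < n; ++s) {
    if (adj[s].empty()) continue;
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    int head = 0, tail = 0;
    dist[s] = 0; sigma[s] = 1; S[tail++] = s;
    while (head < tail) {
      int v = S[head++];
      int dv = dist[v];
      double sv = sigma[v];
      for (int w : adj[v]) {
        if (dist[w] < 0) { dist[w] = dv + 1; S[tail++] = w; }
        if (dist[w] == dv + 1) sigma[w] += sv;
      }
    }
    for (int idx = tail - 1; idx > 0; --idx) {
      int w = S[idx];
      double coef = (1.0 + delta[w]) / sigma[w];
      int dw = dist[w];
      for (int v : adj[w])
        if (dist[v] == dw - 1) delta[v] += sigma[v] * coef;
      btw[w] += delta[w];
    }
  }
  for (int v = 0; v < n; ++v) btw[v] /= 2.0;
}

// [[Rcpp::export]]
List cpp_nodal_stats(IntegerMatrix edges, int n) {
  int m = edges.nrow();
  std::vector<int> ei(m), ej(m);
  for (int e = 0; e < m; ++e) { ei[e] = edges(e, 0) - 1; ej[e] = edges(e, 1) - 1; }
  std::vector<double> deg, clu, btw;
  nodal_stats(ei, ej, n, deg, clu, btw);
  return List::create(_["degree"] = wrap(deg), _["clustering"] = wrap(clu),
                      _["betweenness"] = wrap(btw));
}

// two-sample Kolmogorov-Smirnov statistic for pre-sorted samples
static double ks_sorted(const std::vector<double>& x,
                        const std::vector<double>& y) {
  size_t nx = x.size(), ny = y.size(), i = 0, j = 0;
  double d = 0.0;
  while (i < nx && j < ny) {
    double z = std::min(x[i], y[j]);
    while (i < nx && x[i] <= z) ++i;
    while (j < ny && y[j] <= z) ++j;
    double diff = std::fabs(double(i) / nx - double(j) / ny);
    if (diff > d) d = diff;
  }
  return d;
}

// [[Rcpp::export]]
double cpp_ks(NumericVector x, NumericVector y) {
  std::vector<double> xs = as<std::vector<double>>(x);
  std::vector<double> ys = as<std::vector<double>>(y);
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());
  return ks_sorted(xs, ys);
}

// Max-KS fit energy of a truncated simulation against observed nodal
// statistics. edges: full 1-based edge order; the first m_use rows are used.
// obs_* must be sorted ascending. dist: n x n Euclidean distances.
// [[Rcpp::export]]
double cpp_fit_energy(IntegerMatrix edges, int m_use, int n,
                      NumericMatrix dist,
                      NumericVector obs_deg, NumericVector obs_clu,
                      NumericVector obs_btw, NumericVector obs_len) {
  std::vector<int> ei(m_use), ej(m_use);
  std::vector<double> elen(m_use);
  for (int e = 0; e < m_use; ++e) {
    ei[e] = edges(e, 0) - 1; ej[e] = edges(e, 1) - 1;
    elen[e] = dist(ei[e], ej[e]);
  }
  std::vector<double> deg, clu, btw;
  nodal_stats(ei, ej, n, deg, clu, btw);
  std::sort(deg.begin(), deg.end());
  std::sort(clu.begin(), clu.end());
  std::sort(btw.begin(), btw.end());
  std::sort(elen.begin(), elen.end());
  std::vector<double> od = as<std::vector<double>>(obs_deg);
  std::vector<double> oc = as<std::vector<double>>(obs_clu);
  std::vector<double> ob = as<std::vector<double>>(obs_btw);
  std::vector<double> ol = as<std::vector<double>>(obs_len);
  double e1 = ks_sorted(deg, od), e2 = ks_sorted(clu, oc);
  double e3 = ks_sorted(btw, ob), e4 = ks_sorted(elen, ol);
  return std::max(std::max(e1, e2), std::max(e3, e4));
}
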