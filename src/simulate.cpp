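#include <Rcpp.h>
using namespace Rcpp;

// pair (i < j, 0-based) -> column-major upper-triangle slot
static inline int pair_slot(int i, int j) { return j * (j - 1) / 2 + i; }

// Grow a binary network one edge at a time.
//
// seed_edges : s x 2 (1-based) initial scaffold, never removed
// Deta       : n x n matrix of d^eta (caller defines 0^0 = 1)
// gamma, eps : matching exponent and additive offset inside (m + eps)^gamma
// m_target   : final edge count (including seed)
// noise_lo/hi: noise window as fractions of m_target; while the current edge
//              count c satisfies lo*m <= c < hi*m the next edge is drawn
//              uniformly among eligible pairs. Pass hi < 0 for no window.
//
// Uses R's RNG (one unif_rand() per added edge), eligible pairs enumerated
// in column-major upper-triangle order (i < j, i fastest). The weight of an
// eligible pair is d^eta * (m + eps)^gamma; weights change only for pairs
// containing an endpoint of the new edge, so they are updated incrementally.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(IntegerMatrix seed_edges, int n,
                           NumericMatrix Deta, double gamma_, double eps,
                           int m_target, double noise_lo, double noise_hi) {
  std::vector<int> A(n * n, 0);
  std::vector<double> deg(n, 0.0);
  std::vector<double> CN(n * n, 0.0);
  IntegerMatrix order(m_target, 2);

  int nseed = seed_edges.nrow();
  if (nseed > m_target) stop("m_target below seed edge count");
  for (int e = 0; e < nseed; ++e) {
    int i = seed_edges(e, 0) - 1, j = seed_edges(e, 1) - 1;
    if (i == j || i < 0 || j < 0 || i >= n || j >= n)
      stop("invalid seed edge");
    if (A[i + n * j]) stop("duplicate seed edge");
    A[i + n * j] = A[j + n * i] = 1;
    deg[i] += 1; deg[j] += 1;
    order(e, 0) = std::min(i, j) + 1;
    order(e, 1) = std::max(i, j) + 1;
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double c = 0;
      for (int k = 0; k < n; ++k) c += A[i + n * k] * A[k + n * j];
      CN[i + n * j] = CN[j + n * i] = c;
    }

  int npairs = n * (n - 1) / 2;
  if (m_target > npairs) stop("m_target exceeds network capacity");
  // flattened pair tables and live weights (0 for existing edges)
  std::vector<int> pi(npairs), pj(npairs);
  std::vector<double> W(npairs), D(npairs);
  std::vector<char> open(npairs);
  {
    int t = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i) {
        pi[t] = i; pj[t] = j;
        D[t] = Deta(i, j);
        ++t;
      }
  }
  auto matchf = [&](int i, int j) {
    double un = deg[i] + deg[j] - 2.0 * A[i + n * j] - CN[i + n * j];
    double m = un > 0 ? CN[i + n * j] / un : 0.0;
    return std::pow(m + eps, gamma_);
  };
  int n_open = 0;
  for (int t = 0; t < npairs; ++t) {
    open[t] = !A[pi[t] + n * pj[t]];
    W[t] = open[t] ? D[t] * matchf(pi[t], pj[t]) : 0.0;
    if (open[t]) ++n_open;
  }

  GetRNGstate();
  for (int c = nseed; c < m_target; ++c) {
    bool in_noise = noise_hi >= 0 &&
      c >= noise_lo * m_target && c < noise_hi * m_target;
    int pick = -1;
    if (in_noise) {
      double r = unif_rand() * n_open;
      double cum = 0.0;
      for (int t = 0; t < npairs; ++t) {
        if (!open[t]) continue;
        cum += 1.0;
        pick = t;
        if (cum >= r) break;
      }
    } else {
      double total = 0.0;
      for (int t = 0; t < npairs; ++t) total += W[t];
      if (!(total > 0)) {
        PutRNGstate();
        stop("no eligible pair has positive weight");
      }
      double r = unif_rand() * total, cum = 0.0;
      for (int t = 0; t < npairs; ++t) {
        if (W[t] <= 0) continue;
        cum += W[t];
        pick = t;
        if (cum >= r) break;
      }
    }
    int u = pi[pick], v = pj[pick];
    // new common-neighbor paths run through u and through v
    for (int k = 0; k < n; ++k) {
      if (A[u + n * k] && k != v) { CN[k + n * v] += 1; CN[v + n * k] += 1; }
      if (A[v + n * k] && k != u) { CN[k + n * u] += 1; CN[u + n * k] += 1; }
    }
    A[u + n * v] = A[v + n * u] = 1;
    deg[u] += 1; deg[v] += 1;
    open[pick] = 0; W[pick] = 0.0; --n_open;
    order(c, 0) = std::min(u, v) + 1;
    order(c, 1) = std::max(u, v) + 1;
    // matching (hence weight) changes only for pairs that contain u or v
    for (int k = 0; k < n; ++k) {
      if (k != u) {
        int t = pair_slot(std::min(k, u), std::max(k, u));
        if (open[t]) W[t] = D[t] * matchf(std::min(k, u), std::max(k, u));
      }
      if (k != v) {
        int t = pair_slot(std::min(k, v), std::max(k, v));
        if (open[t]) W[t] = D[t] * matchf(std::min(k, v), std::max(k, v));
      }
    }
  }
  PutRNGstate();
  return order;
}
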