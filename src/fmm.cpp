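// Front-propagation geodesic distances on a triangle mesh.
// Fast marching uses the Kimmel-Sethian planar triangle update with the
// upwind causality test, falling back to the Dijkstra edge update for
// non-admissible (obtuse) configurations; dijkstra = true uses edge
// updates everywhere (exact on the edge graph, an independent cross-check).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector fmm_distance_cpp(const NumericMatrix& V, const IntegerMatrix& Tr,
                               const IntegerVector& sources, bool dijkstra) {
  const int n = V.nrow(), nt = Tr.nrow();

  // incident-triangle lists in CSR layout
  std::vector<int> off(n + 1, 0);
  for (int t = 0; t < nt; t++)
    for (int j = 0; j < 3; j++) off[Tr(t, j)]++;
  for (int i = 0; i < n; i++) off[i + 1] += off[i];
  std::vector<int> inc(off[n]);
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int t = 0; t < nt; t++)
      for (int j = 0; j < 3; j++) inc[pos[Tr(t, j) - 1]++] = t;
  }

  std::vector<double> dist(n, R_PosInf);
  std::vector<char> alive(n, 0);
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  for (int k = 0; k < sources.size(); k++) {
    int s = sources[k] - 1;
    dist[s] = 0.0;
    pq.push(P(0.0, s));
  }

  while (!pq.empty()) {
    P top = pq.top();
    pq.pop();
    int x = top.second;
    if (alive[x] || top.first > dist[x]) continue;
    alive[x] = 1;
    const double dx_ = dist[x];
    for (int q = off[x]; q < off[x + 1]; q++) {
      const int t = inc[q];
      const int vs[3] = {Tr(t, 0) - 1, Tr(t, 1) - 1, Tr(t, 2) - 1};
      for (int j = 0; j < 3; j++) {
        const int c = vs[j];
        if (c == x || alive[c]) continue;
        int b = -1;
        for (int m = 0; m < 3; m++)
          if (vs[m] != x && vs[m] != c) b = vs[m];
        const double ec0 = V(x, 0) - V(c, 0), ec1 = V(x, 1) - V(c, 1),
                     ec2 = V(x, 2) - V(c, 2);
        const double g11 = ec0 * ec0 + ec1 * ec1 + ec2 * ec2;  // |xc|^2
        double cand = dx_ + std::sqrt(g11);
        if (b >= 0 && alive[b]) {
          const double eb0 = V(b, 0) - V(c, 0), eb1 = V(b, 1) - V(c, 1),
                       eb2 = V(b, 2) - V(c, 2);
          const double g22 = eb0 * eb0 + eb1 * eb1 + eb2 * eb2;
          if (!dijkstra) {
            const double g12 = ec0 * eb0 + ec1 * eb1 + ec2 * eb2;
            const double det = g11 * g22 - g12 * g12;
            if (det > 1e-18) {
              // unit-slope planar wavefront through the two known values
              const double q11 = g22 / det, q22 = g11 / det, q12 = -g12 / det;
              const double d1 = dx_, d2 = dist[b];
              const double al = q11 + 2.0 * q12 + q22;
              const double be = q11 * d1 + q12 * (d1 + d2) + q22 * d2;
              const double ga =
                  q11 * d1 * d1 + 2.0 * q12 * d1 * d2 + q22 * d2 * d2 - 1.0;
              const double disc = be * be - al * ga;
              if (disc >= 0.0) {
                const double cv = (be + std::sqrt(disc)) / al;
                const double w1 = q11 * (d1 - cv) + q12 * (d2 - cv);
                const double w2 = q12 * (d1 - cv) + q22 * (d2 - cv);
                if (cv >= std::max(d1, d2) && w1 <= 1e-12 && w2 <= 1e-12 &&
                    cv < cand)
                  cand = cv;
              }
            }
          }
          const double cb = dist[b] + std::sqrt(g22);
          if (cb < cand) cand = cb;
        }
        if (cand < dist[c]) {
          dist[c] = cand;
          pq.push(P(cand, c));
        }
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}
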