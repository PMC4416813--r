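#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Weighted livewire link cost between 8-adjacent pixels p -> q.
// Mirrors the R-level link_cost(): c(p,q) = wz*fz(q) + wc*fc(q) + wG*fG(q)
// + wD*fD(p,q), where fD is the intelligent-scissors gradient-direction
// cost built from the edge-tangent unit vectors at p and q and the
// orientation-normalized unit link vector.
static inline double lw_link_cost(const double *fz, const double *fc,
                                  const double *fG, const double *dr,
                                  const double *dc, int nr, int pr, int pc,
                                  int qr, int qc, double wz, double wc,
                                  double wG, double wD, bool diag_scale) {
  int q = qr + qc * nr;
  int p = pr + pc * nr;
  double lr = (double)(qr - pr), lc = (double)(qc - pc);
  double len = std::sqrt(lr * lr + lc * lc);
  double Lr = lr / len, Lc = lc / len;
  double dpr = dr[p], dpc = dc[p];
  if (dpr * Lr + dpc * Lc < 0.0) { Lr = -Lr; Lc = -Lc; }
  double dp = dpr * Lr + dpc * Lc;
  double dq = dr[q] * Lr + dc[q] * Lc;
  if (dp > 1.0) dp = 1.0; else if (dp < -1.0) dp = -1.0;
  if (dq > 1.0) dq = 1.0; else if (dq < -1.0) dq = -1.0;
  double fD = (2.0 / (3.0 * M_PI)) * (std::acos(dp) + std::acos(dq));
  double cost = wz * fz[q] + wc * fc[q] + wG * fG[q] + wD * fD;
  bool diagonal = (qr != pr) && (qc != pc);
  if (diagonal && diag_scale) cost = cost / std::sqrt(2.0);
  return cost;
}

// Dijkstra over the 8-connected pixel graph. Ties in the priority queue are
// broken by lower linear (column-major, 0-based) pixel index, so the
// settling order -- and hence the predecessor tree among equal-cost paths --
// is deterministic. Predecessors are updated on strict improvement only,
// with neighbours enumerated in a fixed order.
// [[Rcpp::export(name = ".lw_dijkstra")]]
List lw_dijkstra(NumericMatrix fz, NumericMatrix fc, NumericMatrix fG,
                 NumericMatrix dir_r, NumericMatrix dir_c,
                 NumericVector weights, bool diag_scale,
                 int seed, int target) {
  int nr = fz.nrow(), nc = fz.ncol();
  int n = nr * nc;
  if (seed < 0 || seed >= n) stop("seed outside image");
  if (target < -1 || target >= n) stop("target outside image");
  double wz = weights[0], wc = weights[1], wG = weights[2], wD = weights[3];

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, -1);
  std::vector<char> done(n, 0);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  dist[seed] = 0.0;
  pq.push(Node(0.0, seed));

  static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == target) break;
    int ur = u % nr, uc = u / nr;
    double du = dist[u];
    for (int k = 0; k < 8; ++k) {
      int vr = ur + DR[k], vc = uc + DC[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr + vc * nr;
      if (done[v]) continue;
      double w = lw_link_cost(fz.begin(), fc.begin(), fG.begin(),
                              dir_r.begin(), dir_c.begin(), nr,
                              ur, uc, vr, vc, wz, wc, wG, wD, diag_scale);
      double nd = du + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(Node(nd, v));
      }
    }
  }

  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["pred"] = IntegerVector(pred.begin(), pred.end()));
}
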