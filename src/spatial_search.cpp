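#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grid-bucketed nearest-neighbor search: squared Euclidean distance from each
// source point to its nearest target point. Targets are bucketed into square
// cells of side s; for each source we scan Chebyshev rings of cells outward
// from the source's (virtual, unclamped) cell. A ring at index k can only hold
// points at distance >= (k-1)*s from the source, so the scan stops once that
// lower bound exceeds the best squared distance found. Returns R_PosInf for a
// source when there is no target.
// [[Rcpp::export]]
NumericVector nn_sqdist_grid(NumericVector sx, NumericVector sy,
                             NumericVector tx, NumericVector ty) {
  const int ns = sx.size(), nt = tx.size();
  NumericVector out(ns, R_PosInf);
  if (nt == 0 || ns == 0) return out;

  // grid extent spans sources AND targets so every source's virtual cell
  // index stays small even when the target bounding box is degenerate
  double xmin = tx[0], xmax = tx[0], ymin = ty[0], ymax = ty[0];
  for (int i = 1; i < nt; ++i) {
    if (tx[i] < xmin) xmin = tx[i];
    if (tx[i] > xmax) xmax = tx[i];
    if (ty[i] < ymin) ymin = ty[i];
    if (ty[i] > ymax) ymax = ty[i];
  }
  double txmax = xmax, tymax = ymax;
  for (int i = 0; i < ns; ++i) {
    if (sx[i] < xmin) xmin = sx[i];
    if (sx[i] > xmax) xmax = sx[i];
    if (sy[i] < ymin) ymin = sy[i];
    if (sy[i] > ymax) ymax = sy[i];
  }
  const double w = xmax - xmin, h = ymax - ymin;
  // cell side chosen so the grid holds ~nt occupied cells; the max() keeps
  // s > 0 for fully coincident point sets
  double s = std::max(std::max(w, h) / std::ceil(std::sqrt((double) nt)), 1e-9);
  // buckets only need to cover the target extent
  const int nxc = (int) std::floor((txmax - xmin) / s) + 1;
  const int nyc = (int) std::floor((tymax - ymin) / s) + 1;

  std::vector< std::vector<int> > buckets((size_t) nxc * nyc);
  for (int i = 0; i < nt; ++i) {
    int ix = std::min((int) std::floor((tx[i] - xmin) / s), nxc - 1);
    int iy = std::min((int) std::floor((ty[i] - ymin) / s), nyc - 1);
    buckets[(size_t) iy * nxc + ix].push_back(i);
  }

  for (int i = 0; i < ns; ++i) {
    const double px = sx[i], py = sy[i];
    // virtual cell index: may lie outside the grid, never clamped, so the
    // ring lower bound (k-1)*s stays valid
    const int cx = (int) std::floor((px - xmin) / s);
    const int cy = (int) std::floor((py - ymin) / s);
    const int kmax = std::max(std::max(cx, nxc - 1 - cx),
                              std::max(cy, nyc - 1 - cy)) + 1;
    double best = R_PosInf;
    for (int k = 0; k <= kmax; ++k) {
      const double lb = (k - 1) * s;
      if (lb > 0 && lb * lb > best) break;
      const int x0 = cx - k, x1 = cx + k, y0 = cy - k, y1 = cy + k;
      for (int iy = std::max(y0, 0); iy <= std::min(y1, nyc - 1); ++iy) {
        const bool edge_row = (iy == y0 || iy == y1);
        for (int ix = std::max(x0, 0); ix <= std::min(x1, nxc - 1); ++ix) {
          if (!edge_row && ix != x0 && ix != x1) continue;  // ring only
          const std::vector<int>& b = buckets[(size_t) iy * nxc + ix];
          for (size_t j = 0; j < b.size(); ++j) {
            const double dx = px - tx[b[j]], dy = py - ty[b[j]];
            const double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
          }
        }
      }
    }
    out[i] = best;
  }
  return out;
}
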