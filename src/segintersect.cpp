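// All intersection points between two sets of short line segments, with a
// uniform-grid broad phase (marching-squares segments span at most one cell).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_segment_intersections(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  std::vector<double> px, py;
  if (na == 0 || nb == 0) return NumericMatrix(0, 2);

  // bucket B segments by the integer cell of their midpoint
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nb * 2);
  auto key = [](int ix, int iy) {
    return (long long)ix * 1048576LL + iy;
  };
  for (int j = 0; j < nb; ++j) {
    const int ix = (int)std::floor((B(j, 0) + B(j, 2)) * 0.5);
    const int iy = (int)std::floor((B(j, 1) + B(j, 3)) * 0.5);
    grid[key(ix, iy)].push_back(j);
  }

  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1);
    const double rx = A(i, 2) - ax, ry = A(i, 3) - ay;
    const int cx = (int)std::floor((A(i, 0) + A(i, 2)) * 0.5);
    const int cy = (int)std::floor((A(i, 1) + A(i, 3)) * 0.5);
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
      auto it = grid.find(key(cx + dx, cy + dy));
      if (it == grid.end()) continue;
      for (int j : it->second) {
        const double bx = B(j, 0), by = B(j, 1);
        const double sx = B(j, 2) - bx, sy = B(j, 3) - by;
        const double den = rx * sy - ry * sx;
        if (std::fabs(den) < 1e-12) continue;   // parallel / collinear
        const double qpx = bx - ax, qpy = by - ay;
        const double t = (qpx * sy - qpy * sx) / den;
        const double u = (qpx * ry - qpy * rx) / den;
        if (t < 0.0 || t > 1.0 || u < 0.0 || u > 1.0) continue;
        px.push_back(ax + t * rx);
        py.push_back(ay + t * ry);
      }
    }
  }
  NumericMatrix out(px.size(), 2);
  for (size_t k = 0; k < px.size(); ++k) {
    out(k, 0) = px[k];
    out(k, 1) = py[k];
  }
  return out;
}
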