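// Periodic-box nearest-neighbor statistics used as Monte-Carlo oracles for
// the analytic mean nearest-neighbor distance: uniform (Poisson) point sets
// and hard-sphere configurations from random sequential insertion (RSA).

#include <Rcpp.h>
#include <cmath>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline double min_image(double dx, double L) {
  dx = std::fabs(dx);
  if (dx > 0.5 * L) dx = L - dx;
  return dx;
}

static inline double pdist2(const double* a, const double* b, double L) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = min_image(a[k] - b[k], L);
    s += d * d;
  }
  return s;
}

struct CellList {
  int m;
  double h, L;
  std::vector<std::vector<int>> cells;
  const std::vector<double>& xyz;  // 3*n flattened

  CellList(const std::vector<double>& pts, int n, int m_, double L_)
      : m(m_), L(L_), xyz(pts) {
    h = L / m;
    cells.assign((size_t)m * m * m, {});
    for (int i = 0; i < n; ++i) cells[cell_of(i)].push_back(i);
  }
  int coord(double x) const {
    int c = (int)std::floor(x / h);
    if (c >= m) c = m - 1;
    if (c < 0) c = 0;
    return c;
  }
  size_t idx(int cx, int cy, int cz) const {
    return ((size_t)cx * m + cy) * m + cz;
  }
  size_t cell_of(int i) const {
    return idx(coord(xyz[3 * i]), coord(xyz[3 * i + 1]), coord(xyz[3 * i + 2]));
  }
};

// Exact nearest neighbor of point i via expanding Chebyshev shells; cells
// not yet visited after shell k hold points at distance >= k*h.
static double nn_dist(const CellList& cl, int i) {
  const double* p = &cl.xyz[3 * i];
  int m = cl.m;
  int cx = cl.coord(p[0]), cy = cl.coord(p[1]), cz = cl.coord(p[2]);
  double best2 = R_PosInf;
  std::unordered_set<size_t> visited;
  size_t total = (size_t)m * m * m;
  for (int k = 0;; ++k) {
    bool any_new = false;
    for (int dx = -k; dx <= k; ++dx)
      for (int dy = -k; dy <= k; ++dy)
        for (int dz = -k; dz <= k; ++dz) {
          if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != k)
            continue;
          int ax = ((cx + dx) % m + m) % m;
          int ay = ((cy + dy) % m + m) % m;
          int az = ((cz + dz) % m + m) % m;
          size_t c = cl.idx(ax, ay, az);
          if (!visited.insert(c).second) continue;
          any_new = true;
          for (int j : cl.cells[c]) {
            if (j == i) continue;
            double d2 = pdist2(p, &cl.xyz[3 * j], cl.L);
            if (d2 < best2) best2 = d2;
          }
        }
    bool done = visited.size() >= total || (!any_new);
    if ((R_finite(best2) && std::sqrt(best2) <= k * cl.h) || done) break;
  }
  return std::sqrt(best2);
}

// [[Rcpp::export]]
NumericVector cpp_nn_distances_periodic(NumericMatrix pts, double L) {
  int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  std::vector<double> xyz(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = pts(i, k);
  int m = std::max(1, (int)std::floor(std::cbrt(n / 4.0)));
  CellList cl(xyz, n, m, L);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = nn_dist(cl, i);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rsa_insert(int n, double radius, double L,
                             double max_attempts) {
  if (2.0 * radius >= L) stop("box too small for the sphere diameter");
  int m = std::max(1, (int)std::floor(L / (2.0 * radius)));
  double h = L / m;
  std::vector<std::vector<int>> cells((size_t)m * m * m);
  std::vector<double> xyz;
  xyz.reserve(3 * (size_t)n);
  double d2min = 4.0 * radius * radius;
  int placed = 0;
  double attempts = 0.0;
  while (placed < n) {
    if (attempts >= max_attempts)
      stop("random sequential insertion failed after %.0f attempts; "
           "use a lower volume fraction", attempts);
    attempts += 1.0;
    double p[3] = {unif_rand() * L, unif_rand() * L, unif_rand() * L};
    int cx = std::min(m - 1, (int)(p[0] / h));
    int cy = std::min(m - 1, (int)(p[1] / h));
    int cz = std::min(m - 1, (int)(p[2] / h));
    bool ok = true;
    int lo = (m >= 3) ? -1 : 0, hi = (m >= 3) ? 1 : (m - 1);
    for (int dx = lo; dx <= hi && ok; ++dx)
      for (int dy = lo; dy <= hi && ok; ++dy)
        for (int dz = lo; dz <= hi && ok; ++dz) {
          int ax = ((cx + dx) % m + m) % m;
          int ay = ((cy + dy) % m + m) % m;
          int az = ((cz + dz) % m + m) % m;
          size_t c = ((size_t)ax * m + ay) * m + az;
          for (int j : cells[c]) {
            if (pdist2(p, &xyz[3 * j], L) < d2min) {
              ok = false;
              break;
            }
          }
        }
    if (!ok) continue;
    cells[((size_t)cx * m + cy) * m + cz].push_back(placed);
    xyz.push_back(p[0]);
    xyz.push_back(p[1]);
    xyz.push_back(p[2]);
    ++placed;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = xyz[3 * i + k];
  return out;
}
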