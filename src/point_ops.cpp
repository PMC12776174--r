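#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial hash grid over point coordinates with cell size = radius, so any
// neighbour within the radius lies in the 3x3 block of cells around a point.
struct HashGrid {
  double cell;
  double x0, y0;
  std::unordered_map<long long, std::vector<int> > bins;

  HashGrid(double cell_, double x0_, double y0_)
    : cell(cell_), x0(x0_), y0(y0_) {}

  long long key(double x, double y) const {
    long long ix = (long long)std::floor((x - x0) / cell);
    long long iy = (long long)std::floor((y - y0) / cell);
    return ix * 2000003LL + iy;
  }
  void insert(int i, double x, double y) { bins[key(x, y)].push_back(i); }
};

static inline double sq(double v) { return v * v; }

// Greedy radius suppression. Points are visited in the priority order given
// (0-based indices, highest priority first); a point is kept iff no
// already-kept point lies within `radius` Euclidean distance.
// [[Rcpp::export]]
LogicalVector cpp_dedup_keep(NumericVector x, NumericVector y,
                             IntegerVector order, double radius) {
  int n = x.size();
  LogicalVector keep(n, false);
  if (n == 0) return keep;
  double x0 = *std::min_element(x.begin(), x.end());
  double y0 = *std::min_element(y.begin(), y.end());
  HashGrid grid(radius > 0 ? radius : 1.0, x0, y0);
  double r2 = radius * radius;
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    long long ix = (long long)std::floor((x[i] - x0) / grid.cell);
    long long iy = (long long)std::floor((y[i] - y0) / grid.cell);
    bool suppressed = false;
    for (long long dx = -1; dx <= 1 && !suppressed; ++dx) {
      for (long long dy = -1; dy <= 1 && !suppressed; ++dy) {
        long long kk = (ix + dx) * 2000003LL + (iy + dy);
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          grid.bins.find(kk);
        if (it == grid.bins.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t m = 0; m < v.size(); ++m) {
          int j = v[m];
          if (sq(x[i] - x[j]) + sq(y[i] - y[j]) <= r2) {
            suppressed = true;
            break;
          }
        }
      }
    }
    if (!suppressed) {
      keep[i] = true;
      grid.insert(i, x[i], y[i]);
    }
  }
  return keep;
}

// Union-find for connected components of the radius graph.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Connected components of the graph joining points at distance <= radius.
// Returns 1-based component ids.
// [[Rcpp::export]]
IntegerVector cpp_radius_components(NumericVector x, NumericVector y,
                                    double radius) {
  int n = x.size();
  IntegerVector comp(n);
  if (n == 0) return comp;
  double x0 = *std::min_element(x.begin(), x.end());
  double y0 = *std::min_element(y.begin(), y.end());
  HashGrid grid(radius > 0 ? radius : 1.0, x0, y0);
  for (int i = 0; i < n; ++i) grid.insert(i, x[i], y[i]);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor((x[i] - x0) / grid.cell);
    long long iy = (long long)std::floor((y[i] - y0) / grid.cell);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        long long kk = (ix + dx) * 2000003LL + (iy + dy);
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          grid.bins.find(kk);
        if (it == grid.bins.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t m = 0; m < v.size(); ++m) {
          int j = v[m];
          if (j <= i) continue;
          if (sq(x[i] - x[j]) + sq(y[i] - y[j]) <= r2) {
            int ri = uf_find(parent, i), rj = uf_find(parent, j);
            if (ri != rj) parent[ri] = rj;
          }
        }
      }
    }
  }
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    if (relabel.find(r) == relabel.end()) relabel[r] = ++next;
    comp[i] = relabel[r];
  }
  return comp;
}

// Exact radius counts for the local-autocorrelation grid: for each grid
// centre (gx[ix], gy[iy]) count points within `radius` and how many of them
// are targets. Returns ny x nx matrices (rows index gy).
// [[Rcpp::export]]
List cpp_la_counts(NumericVector x, NumericVector y, IntegerVector target,
                   NumericVector gx, NumericVector gy, double radius) {
  int n = x.size(), nx = gx.size(), ny = gy.size();
  IntegerMatrix counts(ny, nx), hits(ny, nx);
  if (n == 0) return List::create(_["counts"] = counts, _["hits"] = hits);
  double x0 = *std::min_element(x.begin(), x.end());
  double y0 = *std::min_element(y.begin(), y.end());
  HashGrid grid(radius > 0 ? radius : 1.0, x0, y0);
  for (int i = 0; i < n; ++i) grid.insert(i, x[i], y[i]);
  double r2 = radius * radius;
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      double cx = gx[ix], cy = gy[iy];
      long long bx0 = (long long)std::floor((cx - radius - x0) / grid.cell);
      long long bx1 = (long long)std::floor((cx + radius - x0) / grid.cell);
      long long by0 = (long long)std::floor((cy - radius - y0) / grid.cell);
      long long by1 = (long long)std::floor((cy + radius - y0) / grid.cell);
      int cnt = 0, hit = 0;
      for (long long bx = bx0; bx <= bx1; ++bx) {
        for (long long by = by0; by <= by1; ++by) {
          long long kk = bx * 2000003LL + by;
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            grid.bins.find(kk);
          if (it == grid.bins.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t m = 0; m < v.size(); ++m) {
            int j = v[m];
            if (sq(x[j] - cx) + sq(y[j] - cy) <= r2) {
              ++cnt;
              hit += target[j];
            }
          }
        }
      }
      counts(iy, ix) = cnt;
      hits(iy, ix) = hit;
    }
  }
  return List::create(_["counts"] = counts, _["hits"] = hits);
}
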