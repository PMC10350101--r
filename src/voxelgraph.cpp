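// 3D voxel-graph primitives used by the masking and unwrapping stages:
// 6-connected component labelling, spherical-ball morphology, and
// quality-guided region-growing phase unwrapping.  All operate on vectors
// in R's column-major array order with an explicit dims argument.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

static inline int sub2ind(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::vector<int> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = sub2ind(xx, yy, zz, nx, ny);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Offsets of the Euclidean ball of the given radius (in voxels).
static std::vector<std::array<int, 3> > ball_offsets(double radius) {
  std::vector<std::array<int, 3> > off;
  int r = (int)std::floor(radius + 1e-9);
  double r2 = radius * radius + 1e-9;
  for (int z = -r; z <= r; ++z)
    for (int y = -r; y <= r; ++y)
      for (int x = -r; x <= r; ++x)
        if (x * x + y * y + z * z <= r2) off.push_back({{x, y, z}});
  return off;
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector out(n);
  std::vector<std::array<int, 3> > off = ball_offsets(radius);
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) { out[i] = false; continue; }
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    bool keep = true;
    for (size_t k = 0; k < off.size() && keep; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      // voxels outside the grid count as background: erosion shrinks at edges
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
        keep = false;
      } else if (!mask[sub2ind(xx, yy, zz, nx, ny)]) {
        keep = false;
      }
    }
    out[i] = keep;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<std::array<int, 3> > off = ball_offsets(radius);
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      out[sub2ind(xx, yy, zz, nx, ny)] = true;
    }
  }
  return out;
}

struct QueueItem {
  double quality;
  int index;    // voxel to be unwrapped
  int source;   // already-unwrapped neighbour it grows from
};

struct QueueCompare {
  // max-heap on quality; ties broken by lower voxel index (deterministic)
  bool operator()(const QueueItem &a, const QueueItem &b) const {
    if (a.quality != b.quality) return a.quality < b.quality;
    return a.index > b.index;
  }
};

// Quality-guided region-growing unwrapping.  Each 6-connected component of
// the mask is grown from its maximum-quality voxel; every popped voxel is
// unwrapped against the neighbour that enqueued it by adding the integer
// multiple of 2*pi closest to their difference.  The output therefore
// differs from the input by exact multiples of 2*pi voxelwise.
// [[Rcpp::export]]
List cpp_unwrap_region_grow(NumericVector wrapped, NumericVector quality,
                            LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double TWO_PI = 2.0 * M_PI;
  NumericVector out(n, NA_REAL);
  IntegerVector comp = cpp_label3d(mask, dims);
  int ncomp = 0;
  for (int i = 0; i < n; ++i) if (comp[i] > ncomp) ncomp = comp[i];

  // seed of each component: maximum quality, ties to the lowest index
  std::vector<int> seed(ncomp + 1, -1);
  for (int i = 0; i < n; ++i) {
    int c = comp[i];
    if (c == 0) continue;
    if (seed[c] < 0 || quality[i] > quality[seed[c]]) seed[c] = i;
  }

  std::vector<char> done(n, 0);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  std::priority_queue<QueueItem, std::vector<QueueItem>, QueueCompare> pq;
  for (int c = 1; c <= ncomp; ++c) {
    int s = seed[c];
    out[s] = wrapped[s];
    done[s] = 1;
    pq.push(QueueItem{quality[s], s, s});
  }
  while (!pq.empty()) {
    QueueItem it = pq.top();
    pq.pop();
    int v = it.index;
    bool expand;
    if (v == it.source) {           // a component seed, already assigned
      expand = true;
    } else if (!done[v]) {
      double diff = out[it.source] - wrapped[v];
      out[v] = wrapped[v] + TWO_PI * std::round(diff / TWO_PI);
      done[v] = 1;
      expand = true;
    } else {
      expand = false;               // stale queue entry
    }
    if (!expand) continue;
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int w = sub2ind(xx, yy, zz, nx, ny);
      if (mask[w] && !done[w]) pq.push(QueueItem{quality[w], w, v});
    }
  }
  return List::create(_["unwrapped"] = out, _["n_components"] = ncomp);
}
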