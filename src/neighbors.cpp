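#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Uniform spatial hash over 3D points. Cell edge equals the query cutoff, so
// all points within the cutoff of a query point live in its 27-cell stencil.

typedef std::unordered_map<int64_t, std::vector<int> > HashGrid;

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const int64_t B = 1 << 20;
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         ((int64_t)(iz + B));
}

static HashGrid build_grid(const NumericMatrix& X, double h) {
  HashGrid g;
  g.reserve(X.nrow() * 2);
  for (int i = 0; i < X.nrow(); ++i) {
    int ix = (int)std::floor(X(i, 0) / h);
    int iy = (int)std::floor(X(i, 1) / h);
    int iz = (int)std::floor(X(i, 2) / h);
    g[cell_key(ix, iy, iz)].push_back(i);
  }
  return g;
}

// [[Rcpp::export]]
LogicalVector grid_any_close(NumericMatrix X, NumericMatrix Y, double cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive");
  int nx = X.nrow();
  LogicalVector out(nx);
  if (Y.nrow() == 0) return out;
  double h = cutoff, c2 = cutoff * cutoff;
  HashGrid g = build_grid(Y, h);
  for (int i = 0; i < nx; ++i) {
    double x = X(i, 0), y = X(i, 1), z = X(i, 2);
    int ix = (int)std::floor(x / h);
    int iy = (int)std::floor(y / h);
    int iz = (int)std::floor(z / h);
    bool hit = false;
    for (int dx = -1; dx <= 1 && !hit; ++dx)
      for (int dy = -1; dy <= 1 && !hit; ++dy)
        for (int dz = -1; dz <= 1 && !hit; ++dz) {
          HashGrid::const_iterator it =
              g.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == g.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) {
            double ddx = x - Y(v[k], 0), ddy = y - Y(v[k], 1),
                   ddz = z - Y(v[k], 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) { hit = true; break; }
          }
        }
    out[i] = hit;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix grid_close_pairs(NumericMatrix X, NumericMatrix Y,
                               double cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive");
  std::vector<int> ri, rj;
  if (X.nrow() > 0 && Y.nrow() > 0) {
    double h = cutoff, c2 = cutoff * cutoff;
    HashGrid g = build_grid(Y, h);
    for (int i = 0; i < X.nrow(); ++i) {
      double x = X(i, 0), y = X(i, 1), z = X(i, 2);
      int ix = (int)std::floor(x / h);
      int iy = (int)std::floor(y / h);
      int iz = (int)std::floor(z / h);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            HashGrid::const_iterator it =
                g.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == g.end()) continue;
            const std::vector<int>& v = it->second;
            for (size_t k = 0; k < v.size(); ++k) {
              double ddx = x - Y(v[k], 0), ddy = y - Y(v[k], 1),
                     ddz = z - Y(v[k], 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                ri.push_back(i + 1);
                rj.push_back(v[k] + 1);
              }
            }
          }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k];
    out(k, 1) = rj[k];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix grid_self_pairs(NumericMatrix X, double cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive");
  std::vector<int> ri, rj;
  if (X.nrow() > 1) {
    double h = cutoff, c2 = cutoff * cutoff;
    HashGrid g = build_grid(X, h);
    for (int i = 0; i < X.nrow(); ++i) {
      double x = X(i, 0), y = X(i, 1), z = X(i, 2);
      int ix = (int)std::floor(x / h);
      int iy = (int)std::floor(y / h);
      int iz = (int)std::floor(z / h);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            HashGrid::const_iterator it =
                g.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == g.end()) continue;
            const std::vector<int>& v = it->second;
            for (size_t k = 0; k < v.size(); ++k) {
              int j = v[k];
              if (j <= i) continue;
              double ddx = x - X(j, 0), ddy = y - X(j, 1), ddz = z - X(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                ri.push_back(i + 1);
                rj.push_back(j + 1);
              }
            }
          }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k];
    out(k, 1) = rj[k];
  }
  return out;
}
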