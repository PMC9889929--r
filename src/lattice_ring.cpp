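#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// Closed self-avoiding ring growth on the cubic lattice, with retraction on
// dead ends and a compactness bias. Uses R's RNG so results are reproducible
// under set.seed(). Site indices run over a (2L+1)^3 block; `allowed` marks
// sites inside the boundary and outside obstacles.

static inline int site_index(int x, int y, int z, int L, int dn) {
  return (x + L) + dn * (y + L) + dn * dn * (z + L);
}

// [[Rcpp::export]]
List grow_ring_lattice(int n, int L, LogicalVector allowed,
                       double locality_bias, int retract_depth,
                       double max_attempts) {
  const int dn = 2 * L + 1;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  std::vector<char> occ(allowed.size(), 0);
  std::vector<int> px(n), py(n), pz(n);
  double attempts = 0;
  int best = 0;

  while (true) {
    // random allowed start site
    int sx = 0, sy = 0, sz = 0;
    bool found = false;
    for (int t = 0; t < 256 && !found; ++t) {
      sx = (int)std::floor(unif_rand() * dn) - L;
      sy = (int)std::floor(unif_rand() * dn) - L;
      sz = (int)std::floor(unif_rand() * dn) - L;
      if (sx < -L || sx > L) continue;
      if (allowed[site_index(sx, sy, sz, L, dn)]) found = true;
    }
    if (!found) {
      for (int i = 0; i < (int)allowed.size() && !found; ++i) {
        if (allowed[i]) {
          sx = i % dn - L;
          sy = (i / dn) % dn - L;
          sz = i / (dn * dn) - L;
          found = true;
        }
      }
      if (!found) stop("no allowed lattice sites");
    }
    std::fill(occ.begin(), occ.end(), 0);
    px[0] = sx; py[0] = sy; pz[0] = sz;
    occ[site_index(sx, sy, sz, L, dn)] = 1;
    int j = 1;          // sites placed
    int fails = 0;
    int best_run = 1;
    while (j < n) {
      int remaining = n - j;
      int hx = px[j - 1], hy = py[j - 1], hz = pz[j - 1];
      int cand[6];
      double w[6];
      int nc = 0;
      for (int s = 0; s < 6; ++s) {
        int cx = hx + dx[s], cy = hy + dy[s], cz = hz + dz[s];
        if (cx < -L || cx > L || cy < -L || cy > L || cz < -L || cz > L)
          continue;
        int ci = site_index(cx, cy, cz, L, dn);
        if (!allowed[ci] || occ[ci]) continue;
        int manh = std::abs(cx - sx) + std::abs(cy - sy) + std::abs(cz - sz);
        if (manh > remaining) continue;  // ring could no longer close
        double weight = 1.0;
        if (locality_bias > 0) {
          int nocc = 0;
          for (int t = 0; t < 6; ++t) {
            int nx2 = cx + dx[t], ny2 = cy + dy[t], nz2 = cz + dz[t];
            if (nx2 < -L || nx2 > L || ny2 < -L || ny2 > L || nz2 < -L ||
                nz2 > L) { ++nocc; continue; }
            int ni = site_index(nx2, ny2, nz2, L, dn);
            if (occ[ni] || !allowed[ni]) ++nocc;
          }
          weight = std::pow(1.0 + nocc, locality_bias);
        }
        cand[nc] = s;
        w[nc] = weight;
        ++nc;
      }
      attempts += 1;
      if (attempts > max_attempts) {
        List out = List::create(Named("ok") = false,
                                Named("longest") = std::max(best, j));
        return out;
      }
      if (nc == 0) {
        if (j > best) best = j;
        ++fails;
        if (fails > 60) break;  // persistent stall: restart from scratch
        int r = retract_depth * (1 + fails / 8);
        if (r > j - 1) r = j - 1;
        if (r <= 0) break;
        for (int k = j - r; k < j; ++k) {
          occ[site_index(px[k], py[k], pz[k], L, dn)] = 0;
        }
        j -= r;
        continue;
      }
      int pick = 0;
      if (nc > 1) {
        double tot = 0;
        for (int k = 0; k < nc; ++k) tot += w[k];
        double u = unif_rand() * tot;
        double acc2 = 0;
        for (int k = 0; k < nc; ++k) {
          acc2 += w[k];
          if (u <= acc2) { pick = k; break; }
          pick = k;
        }
      }
      int s = cand[pick];
      px[j] = hx + dx[s]; py[j] = hy + dy[s]; pz[j] = hz + dz[s];
      occ[site_index(px[j], py[j], pz[j], L, dn)] = 1;
      ++j;
      if (j > best_run) {
        best_run = j;
        if (fails > 0) --fails;
      }
    }
    if (j == n) {
      IntegerMatrix path(n, 3);
      for (int k = 0; k < n; ++k) {
        path(k, 0) = px[k]; path(k, 1) = py[k]; path(k, 2) = pz[k];
      }
      return List::create(Named("ok") = true, Named("path") = path);
    }
  }
}
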