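// 3D binary-volume primitives for the bile-canaliculi pipeline.
//
// Volumes are R arrays with dim = c(nz, ny, nx); the linear (column-major)
// index of voxel (z, y, x) is z + nz * (y + ny * x), all 0-based here.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// [[Rcpp::export(name = "cpp_median3d")]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dims, int radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if (radius <= 0) return clone(vol);
  NumericVector out(vol.size());
  const int w = 2 * radius + 1;
  std::vector<double> buf(w * w * w);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        for (int dx = -radius; dx <= radius; ++dx) {
          const int xx = reflect(x + dx, nx);
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = reflect(y + dy, ny);
            for (int dz = -radius; dz <= radius; ++dz) {
              const int zz = reflect(z + dz, nz);
              buf[k++] = vol[zz + nz * (yy + ny * xx)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[z + nz * (y + ny * x)] = buf[k / 2];
      }
    }
  }
  return out;
}

// connected-component labelling, connectivity 6 or 26; 0 = background
// [[Rcpp::export(name = "cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    lab[seed] = ++next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = (int)(cur / (nz * (R_xlen_t)ny));
      const int rem = (int)(cur % (nz * (R_xlen_t)ny));
      const int y = rem / nz, z = rem % nz;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 &&
                std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz) continue;
            const R_xlen_t nb = zz + nz * (yy + ny * (R_xlen_t)xx);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return lab;
}

// background voxels 6-reachable from any volume face
// [[Rcpp::export(name = "cpp_background_reach6")]]
LogicalVector cpp_background_reach6(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  LogicalVector reach(n, false);
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        if (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 ||
            z == 0 || z == nz - 1) {
          const R_xlen_t i = z + nz * (y + ny * (R_xlen_t)x);
          if (!mask[i] && !reach[i]) {
            reach[i] = true;
            stack.push_back(i);
          }
        }
      }
    }
  }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    const R_xlen_t cur = stack.back();
    stack.pop_back();
    const int x = (int)(cur / (nz * (R_xlen_t)ny));
    const int rem = (int)(cur % (nz * (R_xlen_t)ny));
    const int y = rem / nz, z = rem % nz;
    for (int k = 0; k < 6; ++k) {
      const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t nb = zz + nz * (yy + ny * (R_xlen_t)xx);
      if (!mask[nb] && !reach[nb]) {
        reach[nb] = true;
        stack.push_back(nb);
      }
    }
  }
  return reach;
}

// one 6-connected dilation or erosion step, outside treated as background
static void morph6_step(std::vector<char> &m, int nz, int ny, int nx,
                        bool dilate) {
  std::vector<char> src(m);
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i = z + nz * (y + ny * (R_xlen_t)x);
        bool v = src[i] != 0;
        for (int k = 0; k < 6 && (dilate ? !v : v); ++k) {
          const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
          bool nb = false;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            nb = src[zz + nz * (yy + ny * (R_xlen_t)xx)] != 0;
          if (dilate) {
            if (nb) v = true;
          } else {
            if (!nb) v = false;
          }
        }
        m[i] = v ? 1 : 0;
      }
    }
  }
}

// [[Rcpp::export(name = "cpp_morph6")]]
LogicalVector cpp_morph6(LogicalVector mask, IntegerVector dims,
                         int iterations, bool dilate) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < iterations; ++it) morph6_step(m, nz, ny, nx, dilate);
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// 1D lower envelope pass of the exact squared EDT (Felzenszwalb &
// Huttenlocher); "infinite" inputs are represented by 1e12, large against any
// realizable squared voxel distance yet safe for the parabola arithmetic
static const double DT_INF = 1e12;

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zb[0] = -DT_INF;
  zb[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) /
          (2.0 * q - 2.0 * p);
      if (s <= zb[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    if (s <= zb[k]) {
      // new parabola dominates the whole envelope
      k = 0;
      v[0] = q;
      zb[0] = -DT_INF;
      zb[1] = DT_INF;
    } else {
      ++k;
      v[k] = q;
      zb[k] = s;
      zb[k + 1] = DT_INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = (q - (double)p) * (q - (double)p) + f[p];
  }
}

// exact squared Euclidean distance (voxel units) from each foreground voxel
// to the nearest background; the volume border counts as background one voxel
// outside each face
// [[Rcpp::export(name = "cpp_edt3d_sq")]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? DT_INF : 0.0;
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[z + nz * (y + ny * (R_xlen_t)x)];
      f.resize(nz);
      d.resize(nz);
      dt1d(f, d, v, zb);
      f.resize(nmax);
      d.resize(nmax);
      for (int z = 0; z < nz; ++z) g[z + nz * (y + ny * (R_xlen_t)x)] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[z + nz * (y + ny * (R_xlen_t)x)];
      f.resize(ny);
      d.resize(ny);
      dt1d(f, d, v, zb);
      f.resize(nmax);
      d.resize(nmax);
      for (int y = 0; y < ny; ++y) g[z + nz * (y + ny * (R_xlen_t)x)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[z + nz * (y + ny * (R_xlen_t)x)];
      f.resize(nx);
      d.resize(nx);
      dt1d(f, d, v, zb);
      f.resize(nmax);
      d.resize(nmax);
      for (int x = 0; x < nx; ++x) g[z + nz * (y + ny * (R_xlen_t)x)] = d[x];
    }
  // the outside of the volume is background one step beyond each face
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i = z + nz * (y + ny * (R_xlen_t)x);
        if (!mask[i]) continue;
        double b = std::min(std::min(x + 1, nx - x), std::min(y + 1, ny - y));
        b = std::min(b, (double)std::min(z + 1, nz - z));
        if (b * b < g[i]) g[i] = b * b;
      }
  return g;
}

// Hildebrand-Ruegsegger local thickness: per foreground voxel, the diameter
// (voxel units) of the largest inscribed sphere containing it; spheres are
// the maximal EDT balls, painted exhaustively
// [[Rcpp::export(name = "cpp_local_thickness")]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector ed = cpp_edt3d_sq(mask, dims);
  const R_xlen_t n = mask.size();
  std::vector<R_xlen_t> fg;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) fg.push_back(i);
  std::sort(fg.begin(), fg.end(), [&](R_xlen_t a, R_xlen_t b) {
    return ed[a] > ed[b];
  });
  NumericVector out(n, 0.0);
  for (const R_xlen_t q : fg) {
    const double r2 = ed[q];
    const double r = std::sqrt(r2);
    if (out[q] >= 2.0 * r) continue;  // already inside an equal-or-larger ball
    const int x = (int)(q / (nz * (R_xlen_t)ny));
    const int rem = (int)(q % (nz * (R_xlen_t)ny));
    const int y = rem / nz, z = rem % nz;
    const int ri = (int)std::floor(r);
    for (int dx = -ri; dx <= ri; ++dx)
      for (int dy = -ri; dy <= ri; ++dy)
        for (int dz = -ri; dz <= ri; ++dz) {
          if (dx * dx + dy * dy + dz * dz > r2) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const R_xlen_t p = zz + nz * (yy + ny * (R_xlen_t)xx);
          if (mask[p] && out[p] < 2.0 * r) out[p] = 2.0 * r;
        }
  }
  return out;
}

// ---- simple-point machinery (Bertrand & Malandain characterization) -------

// local 3x3x3 neighborhood codes: index = (dz+1) + 3*(dy+1) + 9*(dx+1)
static bool simple_point(const std::vector<char> &m, int nz, int ny, int nx,
                         int z, int y, int x) {
  char nb[27];
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int xx = x + dx, yy = y + dy, zz = z + dz;
        char v = 0;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = m[zz + nz * (yy + ny * (R_xlen_t)xx)];
        nb[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = v;
      }
  const int centre = 13;
  // condition 1: exactly one 26-component of foreground in N26* (all cells of
  // the punctured neighborhood are 26-adjacent to the centre)
  int comp26 = 0;
  bool seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (s == centre || !nb[s] || seen[s]) continue;
    ++comp26;
    if (comp26 > 1) return false;
    // flood this component
    int stack[27], top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      const int c = stack[--top];
      const int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int t = 0; t < 27; ++t) {
        if (t == centre || seen[t] || !nb[t]) continue;
        const int tz = t % 3, ty = (t / 3) % 3, tx = t / 9;
        if (std::abs(tz - cz) <= 1 && std::abs(ty - cy) <= 1 &&
            std::abs(tx - cx) <= 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  if (comp26 != 1) return false;
  // condition 2: exactly one 6-component of background in N18 that is
  // 6-adjacent to the centre
  auto in18 = [](int s) {
    const int az = std::abs(s % 3 - 1), ay = std::abs((s / 3) % 3 - 1),
              ax = std::abs(s / 9 - 1);
    return (az + ay + ax >= 1) && (az + ay + ax <= 2);
  };
  auto is6 = [](int s) {
    const int az = std::abs(s % 3 - 1), ay = std::abs((s / 3) % 3 - 1),
              ax = std::abs(s / 9 - 1);
    return az + ay + ax == 1;
  };
  bool seenb[27] = {false};
  int comp6 = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18(s) || nb[s] || seenb[s] || !is6(s)) continue;
    // flood the background 6-component seeded at a face neighbor
    ++comp6;
    if (comp6 > 1) return false;
    int stack[27], top = 0;
    stack[top++] = s;
    seenb[s] = true;
    while (top) {
      const int c = stack[--top];
      const int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int t = 0; t < 27; ++t) {
        if (!in18(t) || nb[t] || seenb[t]) continue;
        const int tz = t % 3, ty = (t / 3) % 3, tx = t / 9;
        if (std::abs(tz - cz) + std::abs(ty - cy) + std::abs(tx - cx) == 1) {
          seenb[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return comp6 == 1;
}

static int count26(const std::vector<char> &m, int nz, int ny, int nx,
                   int z, int y, int x) {
  int c = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        if (m[zz + nz * (yy + ny * (R_xlen_t)xx)]) ++c;
      }
  return c;
}

// homotopy-preserving 3D thinning to a curve skeleton. Each pass runs six
// directional subiterations: candidates are the foreground voxels whose
// face-neighbor in the subiteration's direction is background AT COLLECTION
// TIME, processed in order of increasing distance from the original
// background (keeps the skeleton on the EDT ridge) and deleted only if they
// are simple points and not curve endpoints at deletion time. Directional
// candidacy bounds the retraction of free tube ends to one voxel layer per
// pass, preventing a sequential deletion cascade from consuming a branch.
// [[Rcpp::export(name = "cpp_skeletonize3d")]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  NumericVector ed = cpp_edt3d_sq(mask, dims);
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<std::pair<double, R_xlen_t>> cand;
      for (R_xlen_t i = 0; i < n; ++i) {
        if (!m[i]) continue;
        const int x = (int)(i / (nz * (R_xlen_t)ny));
        const int rem = (int)(i % (nz * (R_xlen_t)ny));
        const int y = rem / nz, z = rem % nz;
        const int xx = x + dxs[dir], yy = y + dys[dir], zz = z + dzs[dir];
        bool bg;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
          bg = true;  // outside counts as background
        } else {
          bg = !m[zz + nz * (yy + ny * (R_xlen_t)xx)];
        }
        if (bg) cand.push_back(std::make_pair(ed[i], i));
      }
      std::sort(cand.begin(), cand.end());
      for (size_t b = 0; b < cand.size(); ++b) {
        const R_xlen_t i = cand[b].second;
        if (!m[i]) continue;
        const int x = (int)(i / (nz * (R_xlen_t)ny));
        const int rem = (int)(i % (nz * (R_xlen_t)ny));
        const int y = rem / nz, z = rem % nz;
        if (count26(m, nz, ny, nx, z, y, x) == 1) continue;  // endpoint
        if (!simple_point(m, nz, ny, nx, z, y, x)) continue;
        m[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// number of foreground 26-neighbors for every voxel (0 on background)
// [[Rcpp::export(name = "cpp_neighbor_count26")]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector out(n, 0);
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!m[i]) continue;
    const int x = (int)(i / (nz * (R_xlen_t)ny));
    const int rem = (int)(i % (nz * (R_xlen_t)ny));
    const int y = rem / nz, z = rem % nz;
    out[i] = count26(m, nz, ny, nx, z, y, x);
  }
  return out;
}
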