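// Hot numeric primitives: trilinear sampling, 3D connected components,
// 8-connected grid Dijkstra (livewire), and point-to-triangle closest-point
// queries with a uniform-grid accelerator.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Trilinear interpolation. `vol` is an n1*n2*n3 array (column-major), `pts`
// is N x 3 in ZERO-based continuous voxel index coordinates. Out-of-field
// samples get `fill`; `inside` reports which samples were in-field.
// [[Rcpp::export(name = ".interp_trilinear")]]
List interp_trilinear(NumericVector vol, IntegerVector dims, NumericMatrix pts,
                      double fill) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = pts.nrow();
  NumericVector out(N);
  LogicalVector inside(N);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < N; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[i] = fill; inside[i] = false; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == n1 - 1) x0--;
    if (y0 == n2 - 1) y0--;
    if (z0 == n3 - 1) z0--;
    if (n1 == 1) x0 = 0;
    if (n2 == 1) y0 = 0;
    if (n3 == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, n1 - 1), y1 = std::min(y0 + 1, n2 - 1),
        z1 = std::min(z0 + 1, n3 - 1);
#define V(a, b, c) v[(a) + (R_xlen_t)n1 * ((b) + (R_xlen_t)n2 * (c))]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
    inside[i] = true;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// 6-connected labelling of a logical 3D mask. Returns integer labels
// (0 = background), labelled 1..K in discovery order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  const int *m = LOGICAL(mask);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!m[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % n1), y = (int)((p / n1) % n2), z = (int)(p / ((R_xlen_t)n1 * n2));
      const int dx[6] = {-1, 1, 0, 0, 0, 0}, dy[6] = {0, 0, -1, 1, 0, 0},
                dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= n1 || yy >= n2 || zz >= n3) continue;
        R_xlen_t q = xx + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * zz);
        if (m[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Dijkstra shortest path on an 8-connected pixel grid. `cost` holds the
// per-pixel local cost; a step from pixel a to neighbour b costs
// len * (cost[a] + cost[b]) / 2 with len = 1 (axial) or sqrt(2) (diagonal).
// start/goal are zero-based (row, col). Returns the path as 1-based indices.
// [[Rcpp::export(name = ".dijkstra_grid")]]
List dijkstra_grid(NumericMatrix cost, IntegerVector start, IntegerVector goal) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const R_xlen_t N = (R_xlen_t)nr * nc;
  std::vector<double> dist(N, std::numeric_limits<double>::infinity());
  std::vector<R_xlen_t> prev(N, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  R_xlen_t s = start[0] + (R_xlen_t)nr * start[1];
  R_xlen_t g = goal[0] + (R_xlen_t)nr * goal[1];
  dist[s] = 0.0;
  pq.push(QE(0.0, s));
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sq2 = std::sqrt(2.0);
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    if (u == g) break;
    int r = (int)(u % nr), c = (int)(u / nr);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      R_xlen_t v = rr + (R_xlen_t)nr * cc;
      double len = (dr[k] != 0 && dc[k] != 0) ? sq2 : 1.0;
      double w = dist[u] + len * (cost(r, c) + cost(rr, cc)) / 2.0;
      if (w < dist[v]) { dist[v] = w; prev[v] = u; pq.push(QE(w, v)); }
    }
  }
  std::vector<R_xlen_t> path;
  for (R_xlen_t p = g; p != -1; p = prev[p]) {
    path.push_back(p);
    if (p == s) break;
  }
  if (path.empty() || path.back() != s) stop("goal unreachable");
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    R_xlen_t p = path[path.size() - 1 - i];
    out(i, 0) = (int)(p % nr) + 1;
    out(i, 1) = (int)(p / nr) + 1;
  }
  return List::create(_["path"] = out, _["cost"] = dist[g]);
}

// Closest point on triangle (Ericson, Real-Time Collision Detection).
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid {
  double lo[3];
  double h;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  int clampc(double t, int n) const {
    int i = (int)std::floor(t);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
};

struct TriMeshGrid {
  std::vector<double> tv;  // 9 doubles per triangle: A, B, C
  TriGrid G;
};

static TriMeshGrid *build_grid(NumericMatrix V, IntegerMatrix F, double cell) {
  const int nt = F.nrow();
  if (nt == 0) stop("mesh has no triangles");
  TriMeshGrid *M = new TriMeshGrid();
  M->tv.resize((size_t)nt * 9);
  for (int t = 0; t < nt; ++t)
    for (int j = 0; j < 3; ++j) {
      int vi = F(t, j) - 1;
      for (int k = 0; k < 3; ++k) M->tv[(size_t)t * 9 + j * 3 + k] = V(vi, k);
    }
  TriGrid &G = M->G;
  double hi[3];
  for (int k = 0; k < 3; ++k) {
    G.lo[k] = R_PosInf; hi[k] = R_NegInf;
  }
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      if (V(i, k) < G.lo[k]) G.lo[k] = V(i, k);
      if (V(i, k) > hi[k]) hi[k] = V(i, k);
    }
  double ext = std::max(std::max(hi[0] - G.lo[0], hi[1] - G.lo[1]), hi[2] - G.lo[2]);
  if (cell <= 0) {
    double vol = std::max(1e-12, (hi[0] - G.lo[0]) * (hi[1] - G.lo[1]) * (hi[2] - G.lo[2]));
    cell = std::max(1.1 * std::cbrt(vol / nt), ext / 512.0);
    if (!(cell > 0)) cell = std::max(ext, 1.0);
  }
  G.h = cell;
  G.nx = std::max(1, (int)std::ceil((hi[0] - G.lo[0]) / cell));
  G.ny = std::max(1, (int)std::ceil((hi[1] - G.lo[1]) / cell));
  G.nz = std::max(1, (int)std::ceil((hi[2] - G.lo[2]) / cell));
  G.cells.resize((size_t)G.nx * G.ny * G.nz);
  for (int t = 0; t < nt; ++t) {
    double tlo[3], thi[3];
    for (int k = 0; k < 3; ++k) { tlo[k] = R_PosInf; thi[k] = R_NegInf; }
    for (int j = 0; j < 3; ++j) {
      int vi = F(t, j) - 1;
      for (int k = 0; k < 3; ++k) {
        if (V(vi, k) < tlo[k]) tlo[k] = V(vi, k);
        if (V(vi, k) > thi[k]) thi[k] = V(vi, k);
      }
    }
    int x0 = G.clampc((tlo[0] - G.lo[0]) / cell, G.nx), x1 = G.clampc((thi[0] - G.lo[0]) / cell, G.nx);
    int y0 = G.clampc((tlo[1] - G.lo[1]) / cell, G.ny), y1 = G.clampc((thi[1] - G.lo[1]) / cell, G.ny);
    int z0 = G.clampc((tlo[2] - G.lo[2]) / cell, G.nz), z1 = G.clampc((thi[2] - G.lo[2]) / cell, G.nz);
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x)
          G.cells[(size_t)x + (size_t)G.nx * (y + (size_t)G.ny * z)].push_back(t);
  }
  return M;
}

// Build a reusable uniform-grid index over a triangle mesh.
// [[Rcpp::export(name = ".mesh_grid_build")]]
SEXP mesh_grid_build(NumericMatrix V, IntegerMatrix F, double cell = -1.0) {
  XPtr<TriMeshGrid> p(build_grid(V, F, cell), true);
  return p;
}

static List query_grid(TriMeshGrid *M, NumericMatrix pts) {
  const TriGrid &G = M->G;
  const double *tv = M->tv.data();
  const R_xlen_t np = pts.nrow();
  NumericVector dist(np);
  NumericMatrix cp(np, 3);
  IntegerVector tri(np);
  const double *px = REAL(pts);
  for (R_xlen_t i = 0; i < np; ++i) {
    double p[3] = {px[i], px[i + np], px[i + 2 * np]};
    int cx = G.clampc((p[0] - G.lo[0]) / G.h, G.nx);
    int cy = G.clampc((p[1] - G.lo[1]) / G.h, G.ny);
    int cz = G.clampc((p[2] - G.lo[2]) / G.h, G.nz);
    double best = R_PosInf;
    double bestp[3] = {0, 0, 0};
    int bestt = -1;
    int kmax = G.nx + G.ny + G.nz;
    for (int k = 0; k <= kmax; ++k) {
      if (k > 0 && best <= (double)(k - 1) * G.h) break;
      int x0 = std::max(0, cx - k), x1 = std::min(G.nx - 1, cx + k);
      int y0 = std::max(0, cy - k), y1 = std::min(G.ny - 1, cy + k);
      int z0 = std::max(0, cz - k), z1 = std::min(G.nz - 1, cz + k);
      for (int z = z0; z <= z1; ++z) {
        bool zface = (z == cz - k || z == cz + k);
        for (int y = y0; y <= y1; ++y) {
          bool yface = (y == cy - k || y == cy + k);
          for (int x = x0; x <= x1; ++x) {
            if (!zface && !yface && x != cx - k && x != cx + k) continue;
            const std::vector<int> &lst = G.cells[(size_t)x + (size_t)G.nx * (y + (size_t)G.ny * z)];
            for (size_t q = 0; q < lst.size(); ++q) {
              int t = lst[q];
              const double *T = tv + (size_t)t * 9;
              double out[3];
              closest_on_triangle(p, T, T + 3, T + 6, out);
              double d = std::sqrt((p[0] - out[0]) * (p[0] - out[0]) +
                                   (p[1] - out[1]) * (p[1] - out[1]) +
                                   (p[2] - out[2]) * (p[2] - out[2]));
              if (d < best) {
                best = d; bestt = t;
                bestp[0] = out[0]; bestp[1] = out[1]; bestp[2] = out[2];
              }
            }
          }
        }
      }
    }
    dist[i] = best;
    cp(i, 0) = bestp[0]; cp(i, 1) = bestp[1]; cp(i, 2) = bestp[2];
    tri[i] = bestt + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = cp, _["triangle"] = tri);
}

// Query a prebuilt mesh grid for closest points.
// [[Rcpp::export(name = ".mesh_grid_query")]]
List mesh_grid_query(SEXP grid, NumericMatrix pts) {
  XPtr<TriMeshGrid> p(grid);
  return query_grid(p.get(), pts);
}

// Closest point on a triangle mesh for each query point (one-shot build +
// query). Uniform-grid acceleration; exact (the grid changes speed, never
// the values).
// [[Rcpp::export(name = ".closest_on_mesh")]]
List closest_on_mesh(NumericMatrix pts, NumericMatrix V, IntegerMatrix F,
                     double cell = -1.0) {
  TriMeshGrid *M = build_grid(V, F, cell);
  List out = query_grid(M, pts);
  delete M;
  return out;
}

// Mutual information (bits) between pre-binned fixed intensities and the
// moving image sampled at affine-mapped points: voxel index = M p + b
// (zero-based, continuous). Returns MI and the in-field overlap fraction.
// [[Rcpp::export(name = ".mi_affine")]]
NumericVector mi_affine(NumericVector mdat, IntegerVector mdim,
                        NumericMatrix M, NumericVector b, NumericMatrix pts,
                        IntegerVector fbin, int bins, double mlo, double mspan) {
  const int n1 = mdim[0], n2 = mdim[1], n3 = mdim[2];
  const R_xlen_t N = pts.nrow();
  const double *v = REAL(mdat);
  std::vector<int> joint((size_t)bins * bins, 0);
  R_xlen_t used = 0;
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  const double *px = REAL(pts);
  const int *fb = INTEGER(fbin);
  for (R_xlen_t i = 0; i < N; ++i) {
    double p0 = px[i], p1 = px[i + N], p2 = px[i + 2 * N];
    double x = m00 * p0 + m01 * p1 + m02 * p2 + b[0];
    double y = m10 * p0 + m11 * p1 + m12 * p2 + b[1];
    double z = m20 * p0 + m21 * p1 + m22 * p2 + b[2];
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1)
      continue;
    int x0 = (int)x, y0 = (int)y, z0 = (int)z;
    if (x0 == n1 - 1) x0--;
    if (y0 == n2 - 1) y0--;
    if (z0 == n3 - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
#define V(a, bb, c) v[(a) + (R_xlen_t)n1 * ((bb) + (R_xlen_t)n2 * (c))]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x0 + 1, y0, z0) * fx;
    double c10 = V(x0, y0 + 1, z0) * (1 - fx) + V(x0 + 1, y0 + 1, z0) * fx;
    double c01 = V(x0, y0, z0 + 1) * (1 - fx) + V(x0 + 1, y0, z0 + 1) * fx;
    double c11 = V(x0, y0 + 1, z0 + 1) * (1 - fx) + V(x0 + 1, y0 + 1, z0 + 1) * fx;
#undef V
    double val = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                 (c01 * (1 - fy) + c11 * fy) * fz;
    int mb = (int)std::ceil((val - mlo) / mspan * bins);
    if (mb < 1) mb = 1;
    if (mb > bins) mb = bins;
    joint[(size_t)(fb[i] - 1) + (size_t)bins * (mb - 1)]++;
    used++;
  }
  double overlap = (double)used / (double)N;
  if (used == 0) return NumericVector::create(0.0, 0.0);
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  double hj = 0.0;
  for (int a = 0; a < bins; ++a)
    for (int c = 0; c < bins; ++c) {
      int cnt = joint[(size_t)a + (size_t)bins * c];
      if (!cnt) continue;
      double p = (double)cnt / used;
      pf[a] += p; pm[c] += p;
      hj -= p * std::log2(p);
    }
  double hf = 0.0, hm = 0.0;
  for (int a = 0; a < bins; ++a) {
    if (pf[a] > 0) hf -= pf[a] * std::log2(pf[a]);
    if (pm[a] > 0) hm -= pm[a] * std::log2(pm[a]);
  }
  return NumericVector::create(hf + hm - hj, overlap);
}
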