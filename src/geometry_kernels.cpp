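// Compiled kernels: kd-tree queries, roughness, competitive region growing,
// marching-tetrahedra iso-surfacing, Poisson-disk greedy selection.
#include <RcppArmadillo.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- kd-tree ---

struct KdTree {
  // points stored row-major (n x 3); nodes are indices into idx
  const double* pts;
  int n;
  std::vector<int> idx;    // permutation of 0..n-1
  std::vector<int> left, right, axis;
  std::vector<int> root_of; // single root
  int root;

  KdTree(const double* p, int n_) : pts(p), n(n_), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    left.assign(n, -1); right.assign(n, -1); axis.assign(n, 0);
    root = build(0, n, 0);
  }
  inline double coord(int i, int ax) const { return pts[i + ax * (size_t)n]; }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    int node = idx[mid];
    axis[node] = ax;
    left[node]  = build(lo, mid, depth + 1);
    right[node] = build(mid + 1, hi, depth + 1);
    return node;
  }

  void nn(const double* q, int node, int& best, double& bestd2) const {
    if (node < 0) return;
    double dx = coord(node, 0) - q[0];
    double dy = coord(node, 1) - q[1];
    double dz = coord(node, 2) - q[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2) { bestd2 = d2; best = node; }
    int ax = axis[node];
    double diff = q[ax] - coord(node, ax);
    int near = diff < 0 ? left[node] : right[node];
    int far  = diff < 0 ? right[node] : left[node];
    nn(q, near, best, bestd2);
    if (diff * diff < bestd2) nn(q, far, best, bestd2);
  }

  void radius(const double* q, int node, double r2, std::vector<int>& out) const {
    if (node < 0) return;
    double dx = coord(node, 0) - q[0];
    double dy = coord(node, 1) - q[1];
    double dz = coord(node, 2) - q[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 <= r2) out.push_back(node);
    int ax = axis[node];
    double diff = q[ax] - coord(node, ax);
    int near = diff < 0 ? left[node] : right[node];
    int far  = diff < 0 ? right[node] : left[node];
    radius(q, near, r2, out);
    if (diff * diff <= r2) radius(q, far, r2, out);
  }
};

// Nearest-neighbour distances (and 1-based indices) from each query row to the
// reference cloud.
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix ref, NumericMatrix query) {
  int nr = ref.nrow(), nq = query.nrow();
  if (nr == 0) stop("reference cloud is empty");
  KdTree tree(REAL(ref), nr);
  NumericVector dist(nq);
  IntegerVector ind(nq);
  std::vector<double> q(3);
  for (int i = 0; i < nq; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    int best = -1; double bestd2 = R_PosInf;
    tree.nn(q.data(), tree.root, best, bestd2);
    dist[i] = std::sqrt(bestd2);
    ind[i] = best + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = ind);
}

// ------------------------------------------------------------- roughness ----

// Per-point orthogonal distance to the least-squares plane of the neighbours
// within `radius` (query point excluded). NA when < 3 neighbours or the
// neighbour set is (numerically) collinear.
// [[Rcpp::export]]
NumericVector cpp_roughness(NumericMatrix pts, double radius) {
  int n = pts.nrow();
  NumericVector out(n, NA_REAL);
  if (n == 0) return out;
  KdTree tree(REAL(pts), n);
  double r2 = radius * radius;
  std::vector<int> nb;
  double q[3];
  arma::mat33 C;
  arma::vec3 ev;
  arma::mat33 evec;
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0); q[1] = pts(i, 1); q[2] = pts(i, 2);
    nb.clear();
    tree.radius(q, tree.root, r2, nb);
    // drop self
    int m = 0;
    double cx = 0, cy = 0, cz = 0;
    for (size_t k = 0; k < nb.size(); ++k) {
      if (nb[k] == i) continue;
      cx += pts(nb[k], 0); cy += pts(nb[k], 1); cz += pts(nb[k], 2);
      nb[m++] = nb[k];
    }
    if (m < 3) continue;
    cx /= m; cy /= m; cz /= m;
    C.zeros();
    for (int k = 0; k < m; ++k) {
      double dx = pts(nb[k], 0) - cx;
      double dy = pts(nb[k], 1) - cy;
      double dz = pts(nb[k], 2) - cz;
      C(0,0) += dx*dx; C(0,1) += dx*dy; C(0,2) += dx*dz;
      C(1,1) += dy*dy; C(1,2) += dy*dz; C(2,2) += dz*dz;
    }
    C(1,0) = C(0,1); C(2,0) = C(0,2); C(2,1) = C(1,2);
    if (!arma::eig_sym(ev, evec, C)) continue;
    // collinear: second-smallest eigenvalue ~ 0 relative to total spread
    double tr = ev(0) + ev(1) + ev(2);
    if (tr <= 0 || ev(1) <= 1e-12 * tr) continue;
    double nx = evec(0, 0), ny = evec(1, 0), nz = evec(2, 0);
    out[i] = std::fabs(nx * (q[0] - cx) + ny * (q[1] - cy) + nz * (q[2] - cz));
  }
  return out;
}

// ------------------------------------------------- competitive region grow --

// Level-synchronous multi-seed BFS over voxels >= lower; equal-distance ties
// claimed by the lower label. Connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, double lower,
                              int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(nvox, 0);
  int K = seeds.nrow();
  std::vector<std::vector<R_xlen_t>> frontier(K);
  for (int s = 0; s < K; ++s) {
    R_xlen_t v = (R_xlen_t)seeds(s, 0) +
                 (R_xlen_t)nx * (seeds(s, 1) + (R_xlen_t)ny * seeds(s, 2));
    if (vol[v] < lower)
      stop("seed %d at (%d,%d,%d) has value %g below threshold %g", s + 1,
           seeds(s, 0) + 1, seeds(s, 1) + 1, seeds(s, 2) + 1, vol[v], lower);
    if (labels[v] == 0) { labels[v] = s + 1; frontier[s].push_back(v); }
  }
  // neighbour offsets
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({dx, dy, dz});
      }
  bool alive = true;
  while (alive) {
    alive = false;
    std::vector<std::vector<R_xlen_t>> next(K);
    for (int s = 0; s < K; ++s) {
      for (R_xlen_t v : frontier[s]) {
        int x = (int)(v % nx);
        int y = (int)((v / nx) % ny);
        int z = (int)(v / ((R_xlen_t)nx * ny));
        for (auto& o : off) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (labels[w] != 0 || vol[w] < lower) continue;
          labels[w] = s + 1;
          next[s].push_back(w);
        }
      }
    }
    for (int s = 0; s < K; ++s)
      if (!next[s].empty()) { alive = true; }
    frontier.swap(next);
  }
  return labels;
}

// ------------------------------------------------------ marching tetrahedra -

// Kuhn 6-tetrahedra split of each cube; vertices interpolated on grid edges
// and exactly deduplicated by (grid-node pair) key, so the mesh is watertight
// by construction for iso-surfaces away from the volume boundary.
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, double level,
                    NumericVector spacing, NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto val = [&](int x, int y, int z) -> double {
    return field[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto gid = [&](int x, int y, int z) -> int64_t {
    return (int64_t)x + (int64_t)nx * ((int64_t)y + (int64_t)ny * z);
  };
  // the 6 tets of the Kuhn triangulation: paths 0 -> 7 via axis permutations
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  std::unordered_map<int64_t, int> edge_vertex;
  std::vector<double> verts;       // flat xyz
  std::vector<int> tris;           // flat triples (0-based)

  int corner_xyz[4][3];
  double corner_val[4];
  int64_t corner_id[4];

  auto edge_point = [&](int a, int b) -> int {
    int64_t ia = corner_id[a], ib = corner_id[b];
    int64_t key = ia < ib ? ia * (int64_t)1e9 + ib : ib * (int64_t)1e9 + ia;
    // encode robustly: use a pair-hash safe for grids < 1e9 nodes
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = corner_val[a], vb = corner_val[b];
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double p[3];
    for (int d = 0; d < 3; ++d) {
      double ca = corner_xyz[a][d], cb = corner_xyz[b][d];
      p[d] = origin[d] + spacing[d] * (ca + t * (cb - ca));
    }
    int vid = (int)(verts.size() / 3);
    verts.push_back(p[0]); verts.push_back(p[1]); verts.push_back(p[2]);
    edge_vertex.emplace(key, vid);
    return vid;
  };

  auto emit = [&](int v0, int v1, int v2, int inside_corner, int outside_corner) {
    // orient: normal points from the inside (>= level) toward the outside
    double* a = &verts[3 * v0];
    double* b = &verts[3 * v1];
    double* c = &verts[3 * v2];
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double w[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double nrm[3] = {u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0]};
    double din[3];
    for (int d = 0; d < 3; ++d) {
      double pin = origin[d] + spacing[d] * corner_xyz[inside_corner][d];
      double pout = origin[d] + spacing[d] * corner_xyz[outside_corner][d];
      din[d] = pout - pin;
    }
    double s = nrm[0]*din[0] + nrm[1]*din[1] + nrm[2]*din[2];
    if (s >= 0) { tris.push_back(v0); tris.push_back(v1); tris.push_back(v2); }
    else        { tris.push_back(v0); tris.push_back(v2); tris.push_back(v1); }
  };

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        // skip uniform cubes quickly
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          double v = val(x + (c & 1), y + ((c >> 1) & 1), z + ((c >> 2) & 1));
          if (v >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int cx = 0, cy = 0, cz = 0;
          int steps[4][3] = {{0,0,0}};
          steps[0][0] = 0; steps[0][1] = 0; steps[0][2] = 0;
          for (int s = 0; s < 3; ++s) {
            if (perms[t][s] == 0) cx = 1;
            else if (perms[t][s] == 1) cy = 1;
            else cz = 1;
            steps[s + 1][0] = cx; steps[s + 1][1] = cy; steps[s + 1][2] = cz;
          }
          int n_in = 0;
          int in_idx[4], out_idx[4];
          int n_out = 0;
          for (int c = 0; c < 4; ++c) {
            corner_xyz[c][0] = x + steps[c][0];
            corner_xyz[c][1] = y + steps[c][1];
            corner_xyz[c][2] = z + steps[c][2];
            corner_val[c] = val(corner_xyz[c][0], corner_xyz[c][1], corner_xyz[c][2]);
            corner_id[c] = gid(corner_xyz[c][0], corner_xyz[c][1], corner_xyz[c][2]);
            if (corner_val[c] >= level) in_idx[n_in++] = c;
            else out_idx[n_out++] = c;
          }
          if (n_in == 0 || n_in == 4) continue;
          if (n_in == 1) {
            int a = in_idx[0];
            int p0 = edge_point(a, out_idx[0]);
            int p1 = edge_point(a, out_idx[1]);
            int p2 = edge_point(a, out_idx[2]);
            emit(p0, p1, p2, a, out_idx[0]);
          } else if (n_in == 3) {
            int a = out_idx[0];
            int p0 = edge_point(a, in_idx[0]);
            int p1 = edge_point(a, in_idx[1]);
            int p2 = edge_point(a, in_idx[2]);
            emit(p0, p1, p2, in_idx[0], a);
          } else { // 2-2: quad split into two triangles
            int a0 = in_idx[0], a1 = in_idx[1];
            int b0 = out_idx[0], b1 = out_idx[1];
            int p00 = edge_point(a0, b0);
            int p01 = edge_point(a0, b1);
            int p10 = edge_point(a1, b0);
            int p11 = edge_point(a1, b1);
            emit(p00, p01, p11, a0, b0);
            emit(p00, p11, p10, a0, b0);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[3*i]; V(i, 1) = verts[3*i+1]; V(i, 2) = verts[3*i+2];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = tris[3*i] + 1; F(i, 1) = tris[3*i+1] + 1; F(i, 2) = tris[3*i+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ------------------------------------------------------- box smoothing ------

// One pass of a width-3 box filter along each axis (edge-replicated).
// [[Rcpp::export]]
NumericVector cpp_box_smooth(NumericVector field, IntegerVector dim, int passes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);
  auto id = [&](int x, int y, int z) -> R_xlen_t {
    return (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
  };
  for (int p = 0; p < passes; ++p) {
    for (int ax = 0; ax < 3; ++ax) {
      int nd = ax == 0 ? nx : (ax == 1 ? ny : nz);
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int c = ax == 0 ? x : (ax == 1 ? y : z);
            int lo = std::max(0, c - 1), hi = std::min(nd - 1, c + 1);
            double s = 0; int m = 0;
            for (int k = lo; k <= hi; ++k) {
              int xx = ax == 0 ? k : x, yy = ax == 1 ? k : y, zz = ax == 2 ? k : z;
              s += a[id(xx, yy, zz)]; ++m;
            }
            b[id(x, y, z)] = s / m;
          }
      a.swap(b);
    }
  }
  return NumericVector(a.begin(), a.end());
}

// --------------------------------------------------- Poisson-disk greedy ----

// Greedy selection in candidate order: accept a candidate iff no previously
// accepted point lies within r. Returns a logical keep vector.
// [[Rcpp::export]]
LogicalVector cpp_poisson_select(NumericMatrix pts, double r) {
  int n = pts.nrow();
  LogicalVector keep(n, false);
  if (n == 0) return keep;
  double cell = r > 0 ? r : 1.0;
  std::unordered_map<int64_t, std::vector<int>> grid;
  auto key = [&](double x, double y, double z) -> int64_t {
    int64_t ix = (int64_t)std::floor(x / cell);
    int64_t iy = (int64_t)std::floor(y / cell);
    int64_t iz = (int64_t)std::floor(z / cell);
    return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
  };
  double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; ++dz)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          auto it = grid.find(key(x + dx * cell, y + dy * cell, z + dz * cell));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddx = pts(j, 0) - x, ddy = pts(j, 1) - y, ddz = pts(j, 2) - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      grid[key(x, y, z)].push_back(i);
    }
  }
  return keep;
}
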