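// Low-level geometry kernels: 2D Delaunay triangulation (Bowyer-Watson),
// grid-hashed k-nearest-neighbour graph construction for point clouds, and
// point-to-polyline distances. Kept dependency-free beyond Rcpp.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Tri {
  int a, b, c;       // vertex indices
  double cx, cy, r2; // circumcircle
  bool alive;
};

// Circumcircle of (ax,ay),(bx,by),(cx,cy); returns false if degenerate.
bool circumcircle(double ax, double ay, double bx, double by,
                  double cx, double cy, double &ox, double &oy, double &r2) {
  const double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  const double a2 = ax * ax + ay * ay;
  const double b2 = bx * bx + by * by;
  const double c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  const double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
  return true;
}

} // namespace

// Delaunay triangulation of 2D points. Returns a list with an n x 3 matrix of
// 1-based vertex indices and the circumradius of each triangle.
// [[Rcpp::export]]
List cpp_delaunay(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points for triangulation");

  // working copy including 3 super-triangle vertices at the end
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  const double dmax = std::max(xmax - xmin, ymax - ymin) + 1e-9;
  const double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  const double M = 64.0 * dmax;
  px.push_back(midx - 2.0 * M); py.push_back(midy - M);
  px.push_back(midx + 2.0 * M); py.push_back(midy - M);
  px.push_back(midx);           py.push_back(midy + 2.0 * M);
  const int s0 = n, s1 = n + 1, s2 = n + 2;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  {
    Tri t; t.a = s0; t.b = s1; t.c = s2; t.alive = true;
    circumcircle(px[s0], py[s0], px[s1], py[s1], px[s2], py[s2], t.cx, t.cy, t.r2);
    tris.push_back(t);
  }

  std::vector<int> bad;
  typedef std::pair<int,int> Edge;
  std::vector<Edge> boundary;

  for (int ip = 0; ip < n; ++ip) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const double dx = px[ip] - tris[t].cx, dy = py[ip] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) bad.push_back((int)t);
    }
    // boundary = edges used by exactly one bad triangle
    boundary.clear();
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tri &t = tris[bad[b]];
      const Edge es[3] = { Edge(t.a, t.b), Edge(t.b, t.c), Edge(t.c, t.a) };
      for (int e = 0; e < 3; ++e) {
        Edge cur(std::min(es[e].first, es[e].second),
                 std::max(es[e].first, es[e].second));
        bool dup = false;
        for (size_t j = 0; j < boundary.size(); ++j) {
          Edge o(std::min(boundary[j].first, boundary[j].second),
                 std::max(boundary[j].first, boundary[j].second));
          if (o == cur) { boundary.erase(boundary.begin() + j); dup = true; break; }
        }
        if (!dup) boundary.push_back(es[e]);
      }
    }
    for (size_t b = 0; b < bad.size(); ++b) tris[bad[b]].alive = false;
    for (size_t e = 0; e < boundary.size(); ++e) {
      Tri t; t.a = boundary[e].first; t.b = boundary[e].second; t.c = ip;
      if (!circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                        t.cx, t.cy, t.r2))
        continue; // collinear sliver; skip
      t.alive = true;
      tris.push_back(t);
    }
  }

  int keep = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++keep;
  IntegerMatrix out(keep, 3);
  NumericVector crad(keep);
  int k = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive || tris[t].a >= n || tris[t].b >= n || tris[t].c >= n)
      continue;
    int v[3] = { tris[t].a, tris[t].b, tris[t].c };
    std::sort(v, v + 3);
    out(k, 0) = v[0] + 1; out(k, 1) = v[1] + 1; out(k, 2) = v[2] + 1;
    crad[k] = std::sqrt(tris[t].r2);
    ++k;
  }
  return List::create(_["triangles"] = out, _["circumradius"] = crad);
}

namespace {
inline int64_t cell_key(int ix, int iy, int iz) {
  return ((int64_t)(ix & 0x1FFFFF) << 42) |
         ((int64_t)(iy & 0x1FFFFF) << 21) |
         (int64_t)(iz & 0x1FFFFF);
}
}

// k-nearest-neighbour edge list for a 3D point cloud via uniform grid hashing.
// Returns a matrix (from, to, dist) with 1-based indices, one row per directed
// neighbour relation; symmetrisation happens in R.
// [[Rcpp::export]]
NumericMatrix cpp_knn_edges(NumericMatrix pts, int k, double cell) {
  const int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  if (cell <= 0) stop("cell size must be positive");
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve((size_t)n * 2);
  std::vector<int> cix(n), ciy(n), ciz(n);
  for (int i = 0; i < n; ++i) {
    cix[i] = (int)std::floor(pts(i, 0) / cell);
    ciy[i] = (int)std::floor(pts(i, 1) / cell);
    ciz[i] = (int)std::floor(pts(i, 2) / cell);
    grid[cell_key(cix[i], ciy[i], ciz[i])].push_back(i);
  }
  const int kk = std::min(k, n - 1);
  std::vector<double> bd(kk);
  std::vector<int> bi(kk);
  NumericMatrix out(n * kk, 3);
  long row = 0;
  std::vector<std::pair<double,int> > cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    int ring = 1;
    const int max_ring = 64;
    while (true) {
      cand.clear();
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dz = -ring; dz <= ring; ++dz) {
            std::unordered_map<int64_t, std::vector<int> >::iterator it =
              grid.find(cell_key(cix[i] + dx, ciy[i] + dy, ciz[i] + dz));
            if (it == grid.end()) continue;
            const std::vector<int> &v = it->second;
            for (size_t m = 0; m < v.size(); ++m) {
              const int j = v[m];
              if (j == i) continue;
              const double ddx = pts(i,0) - pts(j,0);
              const double ddy = pts(i,1) - pts(j,1);
              const double ddz = pts(i,2) - pts(j,2);
              cand.push_back(std::make_pair(ddx*ddx + ddy*ddy + ddz*ddz, j));
            }
          }
      if ((int)cand.size() >= kk) {
        std::nth_element(cand.begin(), cand.begin() + (kk - 1), cand.end());
        // kth distance must fit inside searched ring, else expand once more
        if (std::sqrt(cand[kk - 1].first) <= ring * cell || ring >= max_ring)
          break;
      }
      if (ring >= max_ring) break;
      ++ring;
    }
    const int have = std::min((int)cand.size(), kk);
    std::partial_sort(cand.begin(), cand.begin() + have, cand.end());
    for (int m = 0; m < have; ++m) {
      out(row, 0) = i + 1;
      out(row, 1) = cand[m].second + 1;
      out(row, 2) = std::sqrt(cand[m].first);
      ++row;
    }
  }
  if (row < out.nrow()) {
    NumericMatrix trimmed(row, 3);
    for (long r = 0; r < row; ++r)
      for (int c = 0; c < 3; ++c) trimmed(r, c) = out(r, c);
    return trimmed;
  }
  return out;
}

// Minimum distance from each query point to a set of 2D segments.
// [[Rcpp::export]]
NumericVector cpp_polyline_dist(NumericVector qx, NumericVector qy,
                                NumericVector x0, NumericVector y0,
                                NumericVector x1, NumericVector y1) {
  const int n = qx.size(), m = x0.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int s = 0; s < m; ++s) {
      const double ex = x1[s] - x0[s], ey = y1[s] - y0[s];
      const double wx = qx[i] - x0[s], wy = qy[i] - y0[s];
      const double L2 = ex * ex + ey * ey;
      double t = L2 > 0 ? (wx * ex + wy * ey) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      const double dx = wx - t * ex, dy = wy - t * ey;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
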