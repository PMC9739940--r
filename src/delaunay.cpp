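#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Bowyer-Watson 2-D Delaunay triangulation. Intended for point sets that are
// in general position (callers jitter exactly cocircular inputs such as
// regular grids). Returns an m x 3 matrix of 1-based vertex indices.
namespace {

struct Tri {
  int a, b, c;
  double cx, cy, r2;   // circumcentre and squared circumradius
  bool alive;
};

inline bool circum(const std::vector<double>& px, const std::vector<double>& py,
                   int a, int b, int c, double& cx, double& cy, double& r2) {
  const double ax = px[a], ay = py[a], bx = px[b], by = py[b],
               ccx = px[c], ccy = py[c];
  const double d = 2.0 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  const double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2 = ccx * ccx + ccy * ccy;
  cx = (a2 * (by - ccy) + b2 * (ccy - ay) + c2 * (ay - by)) / d;
  cy = (a2 * (ccx - bx) + b2 * (ax - ccx) + c2 * (bx - ax)) / d;
  const double dx = ax - cx, dy = ay - cy;
  r2 = dx * dx + dy * dy;
  return true;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());

  // enclosing super-triangle
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set");
  const double mx = 0.5 * (xmin + xmax), my = 0.5 * (ymin + ymax);
  px.push_back(mx - 20.0 * span); py.push_back(my - 10.0 * span);
  px.push_back(mx + 20.0 * span); py.push_back(my - 10.0 * span);
  px.push_back(mx);               py.push_back(my + 20.0 * span);
  const int s0 = n, s1 = n + 1, s2 = n + 2;

  std::vector<Tri> tris;
  {
    Tri t; t.a = s0; t.b = s1; t.c = s2; t.alive = true;
    if (!circum(px, py, s0, s1, s2, t.cx, t.cy, t.r2))
      stop("super-triangle degenerate");
    tris.push_back(t);
  }

  std::vector<int> bad;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const double dx = px[i] - tris[t].cx, dy = py[i] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2) bad.push_back((int)t);
    }
    // boundary polygon: edges of bad triangles not shared by two bad ones
    std::map<std::pair<int,int>, int> edges;
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& t = tris[bad[k]];
      int e[3][2] = { {t.a, t.b}, {t.b, t.c}, {t.c, t.a} };
      for (int j = 0; j < 3; ++j) {
        int u = std::min(e[j][0], e[j][1]), v = std::max(e[j][0], e[j][1]);
        edges[std::make_pair(u, v)]++;
      }
    }
    for (size_t k = 0; k < bad.size(); ++k) tris[bad[k]].alive = false;
    for (std::map<std::pair<int,int>, int>::iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (it->second != 1) continue;
      Tri t; t.a = it->first.first; t.b = it->first.second; t.c = i;
      if (!circum(px, py, t.a, t.b, t.c, t.cx, t.cy, t.r2)) continue;
      t.alive = true;
      tris.push_back(t);
    }
  }

  std::vector<int> keep;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    keep.push_back((int)t);
  }
  IntegerMatrix out(keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k) {
    out(k, 0) = tris[keep[k]].a + 1;
    out(k, 1) = tris[keep[k]].b + 1;
    out(k, 2) = tris[keep[k]].c + 1;
  }
  return out;
}
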