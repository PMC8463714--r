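// Nearest-point-on-surface kernel: exact point-to-triangle distance with an
// axis-aligned bounding-box BVH over triangles. This is the distance kernel
// behind the signed mesh-to-mesh difference and the ICP correspondence step.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
};

// Closest point on triangle (a,b,c) to p; bary receives barycentric coords
// w.r.t. (a,b,c). Ericson's real-time collision detection formulation:
// Voronoi-region classification via the edge parameterisation, exact in
// floating point up to rounding, no divisions until the final region.
static Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                const Vec3& c, double bary[3]) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0.0 && d2 <= 0.0) { bary[0] = 1; bary[1] = 0; bary[2] = 0; return a; }

  Vec3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0.0 && d4 <= d3) { bary[0] = 0; bary[1] = 1; bary[2] = 0; return b; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return a + ab * v;
  }

  Vec3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0.0 && d5 <= d6) { bary[0] = 0; bary[1] = 0; bary[2] = 1; return c; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return a + ac * w;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return b + (c - b) * w;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
  return a + ab * v + ac * w;
}

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children, or -1 for leaf
  int start, count;  // leaf triangle range into the index array
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> tri;            // permuted triangle indices
  std::vector<Vec3> a, b, c;       // triangle vertices in original order
  std::vector<Vec3> centroid;

  static const int LEAF = 8;

  int build(int start, int count) {
    BVHNode nd;
    for (int k = 0; k < 3; ++k) {
      nd.lo[k] = std::numeric_limits<double>::infinity();
      nd.hi[k] = -std::numeric_limits<double>::infinity();
    }
    for (int i = start; i < start + count; ++i) {
      int t = tri[i];
      const Vec3* vs[3] = { &a[t], &b[t], &c[t] };
      for (const Vec3* v : vs) {
        nd.lo[0] = std::min(nd.lo[0], v->x); nd.hi[0] = std::max(nd.hi[0], v->x);
        nd.lo[1] = std::min(nd.lo[1], v->y); nd.hi[1] = std::max(nd.hi[1], v->y);
        nd.lo[2] = std::min(nd.lo[2], v->z); nd.hi[2] = std::max(nd.hi[2], v->z);
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= LEAF) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].start = start; nodes[id].count = count;
      return id;
    }
    int axis = 0;
    double ext = nd.hi[0] - nd.lo[0];
    if (nd.hi[1] - nd.lo[1] > ext) { ext = nd.hi[1] - nd.lo[1]; axis = 1; }
    if (nd.hi[2] - nd.lo[2] > ext) { axis = 2; }
    int mid = start + count / 2;
    std::nth_element(tri.begin() + start, tri.begin() + mid,
                     tri.begin() + start + count,
                     [&](int i, int j) {
                       const Vec3& ci = centroid[i];
                       const Vec3& cj = centroid[j];
                       double vi = axis == 0 ? ci.x : (axis == 1 ? ci.y : ci.z);
                       double vj = axis == 0 ? cj.x : (axis == 1 ? cj.y : cj.z);
                       return vi < vj;
                     });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[id].left = l; nodes[id].right = r;
    nodes[id].start = -1; nodes[id].count = 0;
    return id;
  }

  double box_dist2(const BVHNode& nd, const Vec3& p) const {
    double d2 = 0.0, d;
    d = std::max({ nd.lo[0] - p.x, 0.0, p.x - nd.hi[0] }); d2 += d * d;
    d = std::max({ nd.lo[1] - p.y, 0.0, p.y - nd.hi[1] }); d2 += d * d;
    d = std::max({ nd.lo[2] - p.z, 0.0, p.z - nd.hi[2] }); d2 += d * d;
    return d2;
  }

  void query(int node, const Vec3& p, double& best2, int& best_tri,
             Vec3& best_pt, double best_bary[3]) const {
    const BVHNode& nd = nodes[node];
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int t = tri[i];
        double bary[3];
        Vec3 q = closest_on_triangle(p, a[t], b[t], c[t], bary);
        Vec3 d = p - q;
        double d2 = d.dot(d);
        if (d2 < best2) {
          best2 = d2; best_tri = t; best_pt = q;
          best_bary[0] = bary[0]; best_bary[1] = bary[1]; best_bary[2] = bary[2];
        }
      }
      return;
    }
    double dl = box_dist2(nodes[nd.left], p);
    double dr = box_dist2(nodes[nd.right], p);
    int first = nd.left, second = nd.right;
    if (dr < dl) { std::swap(first, second); std::swap(dl, dr); }
    if (dl < best2) query(first, p, best2, best_tri, best_pt, best_bary);
    if (dr < best2) query(second, p, best2, best_tri, best_pt, best_bary);
  }
};

// [[Rcpp::export]]
List cpp_nearest_on_surface(NumericMatrix query, NumericMatrix vertices,
                            IntegerMatrix faces) {
  const int nq = query.nrow();
  const int nf = faces.nrow();
  if (nf == 0) stop("mesh has no faces");

  BVH bvh;
  bvh.a.resize(nf); bvh.b.resize(nf); bvh.c.resize(nf);
  bvh.centroid.resize(nf);
  bvh.tri.resize(nf);
  for (int t = 0; t < nf; ++t) {
    int ia = faces(t, 0) - 1, ib = faces(t, 1) - 1, ic = faces(t, 2) - 1;
    bvh.a[t] = Vec3(vertices(ia, 0), vertices(ia, 1), vertices(ia, 2));
    bvh.b[t] = Vec3(vertices(ib, 0), vertices(ib, 1), vertices(ib, 2));
    bvh.c[t] = Vec3(vertices(ic, 0), vertices(ic, 1), vertices(ic, 2));
    bvh.centroid[t] = (bvh.a[t] + bvh.b[t] + bvh.c[t]) * (1.0 / 3.0);
    bvh.tri[t] = t;
  }
  bvh.nodes.reserve(2 * nf / BVH::LEAF + 4);
  bvh.build(0, nf);

  NumericVector dist(nq);
  IntegerVector tri(nq);
  NumericMatrix closest(nq, 3), bary(nq, 3);
  for (int i = 0; i < nq; ++i) {
    Vec3 p(query(i, 0), query(i, 1), query(i, 2));
    double best2 = std::numeric_limits<double>::infinity();
    int bt = -1;
    Vec3 bp;
    double bb[3] = { 0, 0, 0 };
    bvh.query(0, p, best2, bt, bp, bb);
    dist[i] = std::sqrt(best2);
    tri[i] = bt + 1;
    closest(i, 0) = bp.x; closest(i, 1) = bp.y; closest(i, 2) = bp.z;
    bary(i, 0) = bb[0]; bary(i, 1) = bb[1]; bary(i, 2) = bb[2];
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri,
                      _["closest"] = closest, _["bary"] = bary);
}
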