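#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- small vector helpers -------------------------------------------------

struct V3 {
  double x, y, z;
};

static inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
static inline V3 sub(const V3& a, const V3& b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 add(const V3& a, const V3& b) { return V3{a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 scl(const V3& a, double s) { return V3{a.x * s, a.y * s, a.z * s}; }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }

// Closest point on triangle (Ericson, Real-Time Collision Detection ch. 5)
static double point_tri_dist2(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { V3 d = sub(p, a); return dot(d, d); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { V3 d = sub(p, b); return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    V3 q = add(a, scl(ab, v)); V3 d = sub(p, q); return dot(d, d);
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { V3 d = sub(p, c); return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    V3 q = add(a, scl(ac, w)); V3 d = sub(p, q); return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = add(b, scl(sub(c, b), w)); V3 d = sub(p, q); return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = add(a, add(scl(ab, v), scl(ac, w)));
  V3 d = sub(p, q); return dot(d, d);
}

// ---- bounding volume hierarchy over triangles ------------------------------

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children; -1 for leaf
  int begin, end;    // triangle index range in `order` for leaves
};

struct BVH {
  std::vector<V3> va, vb, vc;     // triangle vertices by original index
  std::vector<int> order;         // triangle ids, permuted during build
  std::vector<BVHNode> nodes;
};

static void bvh_node_bounds(BVH& t, BVHNode& nd) {
  for (int k = 0; k < 3; ++k) { nd.lo[k] = std::numeric_limits<double>::infinity(); nd.hi[k] = -nd.lo[k]; }
  for (int i = nd.begin; i < nd.end; ++i) {
    int f = t.order[i];
    const V3* vs[3] = {&t.va[f], &t.vb[f], &t.vc[f]};
    for (const V3* v : vs) {
      nd.lo[0] = std::min(nd.lo[0], v->x); nd.hi[0] = std::max(nd.hi[0], v->x);
      nd.lo[1] = std::min(nd.lo[1], v->y); nd.hi[1] = std::max(nd.hi[1], v->y);
      nd.lo[2] = std::min(nd.lo[2], v->z); nd.hi[2] = std::max(nd.hi[2], v->z);
    }
  }
}

static int bvh_build_rec(BVH& t, int begin, int end) {
  BVHNode nd; nd.begin = begin; nd.end = end; nd.left = nd.right = -1;
  bvh_node_bounds(t, nd);
  int n = end - begin;
  int me = (int)t.nodes.size();
  t.nodes.push_back(nd);
  if (n <= 4) return me;
  // split on the longest axis at the median triangle centroid
  int axis = 0;
  double ext[3] = {nd.hi[0] - nd.lo[0], nd.hi[1] - nd.lo[1], nd.hi[2] - nd.lo[2]};
  if (ext[1] > ext[axis]) axis = 1;
  if (ext[2] > ext[axis]) axis = 2;
  auto cen = [&](int f) {
    const V3& a = t.va[f]; const V3& b = t.vb[f]; const V3& c = t.vc[f];
    double v[3] = {(a.x + b.x + c.x), (a.y + b.y + c.y), (a.z + b.z + c.z)};
    return v[axis];
  };
  int mid = begin + n / 2;
  std::nth_element(t.order.begin() + begin, t.order.begin() + mid, t.order.begin() + end,
                   [&](int f1, int f2) { return cen(f1) < cen(f2); });
  int l = bvh_build_rec(t, begin, mid);
  int r = bvh_build_rec(t, mid, end);
  t.nodes[me].left = l; t.nodes[me].right = r;
  return me;
}

static BVH* bvh_build(const NumericMatrix& V, const IntegerMatrix& F) {
  BVH* t = new BVH();
  int nf = F.nrow();
  t->va.resize(nf); t->vb.resize(nf); t->vc.resize(nf);
  for (int i = 0; i < nf; ++i) {
    int i0 = F(i, 0) - 1, i1 = F(i, 1) - 1, i2 = F(i, 2) - 1;
    t->va[i] = v3(V(i0, 0), V(i0, 1), V(i0, 2));
    t->vb[i] = v3(V(i1, 0), V(i1, 1), V(i1, 2));
    t->vc[i] = v3(V(i2, 0), V(i2, 1), V(i2, 2));
  }
  t->order.resize(nf);
  for (int i = 0; i < nf; ++i) t->order[i] = i;
  t->nodes.reserve(2 * nf / 4 + 4);
  bvh_build_rec(*t, 0, nf);
  return t;
}

static inline double box_dist2(const BVHNode& nd, const V3& p) {
  double d2 = 0.0;
  double c[3] = {p.x, p.y, p.z};
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (c[k] < nd.lo[k]) d = nd.lo[k] - c[k];
    else if (c[k] > nd.hi[k]) d = c[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

static double bvh_query(const BVH& t, const V3& p) {
  double best = std::numeric_limits<double>::infinity();
  std::vector<int> stack;
  stack.reserve(64);
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back(); stack.pop_back();
    const BVHNode& nd = t.nodes[ni];
    if (box_dist2(nd, p) >= best) continue;
    if (nd.left < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int f = t.order[i];
        double d2 = point_tri_dist2(p, t.va[f], t.vb[f], t.vc[f]);
        if (d2 < best) best = d2;
      }
    } else {
      // visit nearer child first
      double dl = box_dist2(t.nodes[nd.left], p);
      double dr = box_dist2(t.nodes[nd.right], p);
      if (dl < dr) { stack.push_back(nd.right); stack.push_back(nd.left); }
      else { stack.push_back(nd.left); stack.push_back(nd.right); }
    }
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<BVH> ptr(bvh_build(V, F), true);
  return ptr;
}

// [[Rcpp::export]]
bool cpp_xptr_is_null(SEXP p) {
  return TYPEOF(p) != EXTPTRSXP || R_ExternalPtrAddr(p) == nullptr;
}

// [[Rcpp::export]]
NumericVector cpp_bvh_min_distance(SEXP tree, NumericMatrix Q) {
  if (cpp_xptr_is_null(tree)) stop("stale distance index: rebuild it");
  XPtr<BVH> ptr(tree);
  int n = Q.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = bvh_query(*ptr, v3(Q(i, 0), Q(i, 1), Q(i, 2)));
  return out;
}

// ---- generalized winding number (Van Oosterom & Strackee solid angles) -----

// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nf = F.nrow(), nq = Q.nrow();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    V3 p = v3(Q(q, 0), Q(q, 1), Q(q, 2));
    double total = 0.0;
    for (int i = 0; i < nf; ++i) {
      V3 a = sub(v3(V(F(i, 0) - 1, 0), V(F(i, 0) - 1, 1), V(F(i, 0) - 1, 2)), p);
      V3 b = sub(v3(V(F(i, 1) - 1, 0), V(F(i, 1) - 1, 1), V(F(i, 1) - 1, 2)), p);
      V3 c = sub(v3(V(F(i, 2) - 1, 0), V(F(i, 2) - 1, 1), V(F(i, 2) - 1, 2)), p);
      double la = norm3(a), lb = norm3(b), lc = norm3(c);
      double det = dot(a, cross(b, c));
      double den = la * lb * lc + dot(a, b) * lc + dot(b, c) * la + dot(c, a) * lb;
      total += 2.0 * std::atan2(det, den);
    }
    out[q] = total / (4.0 * M_PI);
  }
  return out;
}

// ---- ray casting (Moller-Trumbore, nearest positive hit) -------------------

// [[Rcpp::export]]
NumericMatrix cpp_ray_mesh(NumericMatrix V, IntegerMatrix F,
                           NumericMatrix origins, NumericMatrix dirs) {
  int nf = F.nrow(), nr = origins.nrow();
  NumericMatrix out(nr, 4); // t, hit x/y/z; t = NA when no hit
  const double eps = 1e-12;
  for (int r = 0; r < nr; ++r) {
    V3 o = v3(origins(r, 0), origins(r, 1), origins(r, 2));
    V3 d = v3(dirs(r, 0), dirs(r, 1), dirs(r, 2));
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < nf; ++i) {
      V3 a = v3(V(F(i, 0) - 1, 0), V(F(i, 0) - 1, 1), V(F(i, 0) - 1, 2));
      V3 b = v3(V(F(i, 1) - 1, 0), V(F(i, 1) - 1, 1), V(F(i, 1) - 1, 2));
      V3 c = v3(V(F(i, 2) - 1, 0), V(F(i, 2) - 1, 1), V(F(i, 2) - 1, 2));
      V3 e1 = sub(b, a), e2 = sub(c, a);
      V3 pv = cross(d, e2);
      double det = dot(e1, pv);
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      V3 tv = sub(o, a);
      double u = dot(tv, pv) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      V3 qv = cross(tv, e1);
      double v = dot(d, qv) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = dot(e2, qv) * inv;
      if (t > 1e-9 && t < best) best = t;
    }
    if (std::isfinite(best)) {
      out(r, 0) = best;
      out(r, 1) = o.x + best * d.x;
      out(r, 2) = o.y + best * d.y;
      out(r, 3) = o.z + best * d.z;
    } else {
      out(r, 0) = NA_REAL; out(r, 1) = NA_REAL; out(r, 2) = NA_REAL; out(r, 3) = NA_REAL;
    }
  }
  return out;
}

// ---- ring-wise breadth-first patch growth ----------------------------------

// adj: nf x 3 matrix of edge-adjacent triangle ids (1-based, 0 = none)
// Whole adjacency rings are admitted until cumulative area >= target.
// [[Rcpp::export]]
List cpp_grow_patches(IntegerMatrix adj, NumericVector areas,
                      IntegerVector centers, double target_area) {
  int nf = adj.nrow(), nc = centers.size();
  double total = 0.0;
  for (int i = 0; i < nf; ++i) total += areas[i];
  List out(nc);
  std::vector<int> mark(nf, -1);
  for (int ci = 0; ci < nc; ++ci) {
    int c = centers[ci] - 1;
    if (c < 0 || c >= nf) stop("patch center out of range");
    std::vector<int> members;
    std::vector<int> ring;
    members.push_back(c);
    ring.push_back(c);
    mark[c] = ci;
    double acc = areas[c];
    while (acc < target_area) {
      std::vector<int> next;
      for (int f : ring) {
        for (int k = 0; k < 3; ++k) {
          int nb = adj(f, k) - 1;
          if (nb >= 0 && mark[nb] != ci) { mark[nb] = ci; next.push_back(nb); }
        }
      }
      if (next.empty()) break; // disconnected or whole mesh consumed
      for (int f : next) { acc += areas[f]; members.push_back(f); }
      ring.swap(next);
    }
    IntegerVector mem(members.size());
    for (size_t i = 0; i < members.size(); ++i) mem[i] = members[i] + 1;
    out[ci] = mem;
  }
  return out;
}

// ---- analytic infinite homogeneous medium lead field -----------------------

// positions in mm, sigma in S/m; output in V per (A*m)
// [[Rcpp::export]]
NumericMatrix cpp_lead_field(NumericMatrix src_pos, NumericMatrix src_ori,
                             NumericMatrix contacts, double sigma,
                             double min_dist_mm) {
  int ns = src_pos.nrow(), m = contacts.nrow();
  NumericMatrix out(m, ns);
  const double k = 1.0 / (4.0 * M_PI * sigma);
  for (int s = 0; s < ns; ++s) {
    V3 r0 = v3(src_pos(s, 0) * 1e-3, src_pos(s, 1) * 1e-3, src_pos(s, 2) * 1e-3);
    V3 p = v3(src_ori(s, 0), src_ori(s, 1), src_ori(s, 2));
    for (int c = 0; c < m; ++c) {
      V3 r = sub(v3(contacts(c, 0) * 1e-3, contacts(c, 1) * 1e-3, contacts(c, 2) * 1e-3), r0);
      double d = norm3(r);
      if (d < min_dist_mm * 1e-3)
        stop("contact within %f mm of a dipole source (singularity)", min_dist_mm);
      out(c, s) = k * dot(p, r) / (d * d * d);
    }
  }
  return out;
}

// ---- collision matrix over 128-point electrode representations -------------

static double seg_seg_dist2(const V3& p1, const V3& q1, const V3& p2, const V3& q2) {
  // Ericson segment-segment closest point
  V3 d1 = sub(q1, p1), d2 = sub(q2, p2), r = sub(p1, p2);
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { return dot(r, r); }
  if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot(d1, r);
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  V3 c1 = add(p1, scl(d1, s)), c2 = add(p2, scl(d2, t));
  V3 d = sub(c1, c2);
  return dot(d, d);
}

// pts: n x (3*k) matrix, one electrode per row, k shaft points (x,y,z triples)
// Shaft points lie on the entry-tip segment, so the exact segment-segment
// distance is a lower bound used to prune pairs that cannot collide.
// [[Rcpp::export]]
LogicalMatrix cpp_collision_matrix(NumericMatrix pts, double threshold) {
  int n = pts.nrow();
  int k = pts.ncol() / 3;
  double thr2 = threshold * threshold;
  LogicalMatrix out(n, n);
  std::vector<V3> first(n), last(n);
  for (int i = 0; i < n; ++i) {
    first[i] = v3(pts(i, 0), pts(i, 1), pts(i, 2));
    last[i] = v3(pts(i, 3 * (k - 1)), pts(i, 3 * (k - 1) + 1), pts(i, 3 * (k - 1) + 2));
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (seg_seg_dist2(first[i], last[i], first[j], last[j]) >= thr2) continue;
      bool hit = false;
      for (int a = 0; a < k && !hit; ++a) {
        V3 pa = v3(pts(i, 3 * a), pts(i, 3 * a + 1), pts(i, 3 * a + 2));
        for (int b = 0; b < k; ++b) {
          double dx = pa.x - pts(j, 3 * b), dy = pa.y - pts(j, 3 * b + 1), dz = pa.z - pts(j, 3 * b + 2);
          if (dx * dx + dy * dy + dz * dz < thr2) { hit = true; break; }
        }
      }
      if (hit) { out(i, j) = true; out(j, i) = true; }
    }
  }
  return out;
}
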