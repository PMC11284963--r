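#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

// Balanced 3-d kd-tree over the target vertex set, median split by
// nth_element on an index array. Nodes are the (lo, hi) ranges themselves;
// the median element of a range is its splitting point. Exact nearest
// neighbour with the usual hypersphere/hyperplane pruning.

namespace {

struct KDTree {
  const double *x, *y, *z;  // column pointers into the target matrix
  int n;
  std::vector<int> ind;

  KDTree(const Rcpp::NumericMatrix &pts)
      : x(&pts(0, 0)), y(&pts(0, 1)), z(&pts(0, 2)), n(pts.nrow()), ind(n) {
    for (int i = 0; i < n; ++i) ind[i] = i;
    build(0, n, 0);
  }

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    const double *c = ax == 0 ? x : (ax == 1 ? y : z);
    std::nth_element(ind.begin() + lo, ind.begin() + mid, ind.begin() + hi,
                     [c](int a, int b) { return c[a] < c[b]; });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(double qx, double qy, double qz, int lo, int hi, int depth,
             int &best, double &bestd2) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int i = ind[mid];
    double dx = qx - x[i], dy = qy - y[i], dz = qz - z[i];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2) {
      bestd2 = d2;
      best = i;
    }
    if (hi - lo == 1) return;
    int ax = depth % 3;
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double diff = q - coord(i, ax);
    if (diff < 0) {
      query(qx, qy, qz, lo, mid, depth + 1, best, bestd2);
      if (diff * diff < bestd2)
        query(qx, qy, qz, mid + 1, hi, depth + 1, best, bestd2);
    } else {
      query(qx, qy, qz, mid + 1, hi, depth + 1, best, bestd2);
      if (diff * diff < bestd2)
        query(qx, qy, qz, lo, mid, depth + 1, best, bestd2);
    }
  }
};

}  // namespace

//' @useDynLib deltafr, .registration = TRUE
//' @importFrom Rcpp sourceCpp

// [[Rcpp::export(name = ".nn_match")]]
Rcpp::List nn_match(Rcpp::NumericMatrix target, Rcpp::NumericMatrix query) {
  if (target.ncol() != 3 || query.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  if (target.nrow() < 1) Rcpp::stop("empty target point set");
  KDTree tree(target);
  int m = query.nrow();
  Rcpp::IntegerVector idx(m);
  Rcpp::NumericVector dist(m);
  for (int j = 0; j < m; ++j) {
    int best = -1;
    double bestd2 = R_PosInf;
    tree.query(query(j, 0), query(j, 1), query(j, 2), 0, tree.n, 0, best,
               bestd2);
    idx[j] = best + 1;  // 1-based for R
    dist[j] = std::sqrt(bestd2);
  }
  return Rcpp::List::create(Rcpp::Named("index") = idx,
                            Rcpp::Named("distance") = dist);
}

namespace {

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
inline void closest_on_triangle(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    return;
  }
  double bp[3], cp[3];
  for (int k = 0; k < 3; ++k) {
    bp[k] = p[k] - b[k];
    cp[k] = p[k] - c[k];
  }
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

}  // namespace

namespace {

// Target surface with its kd-tree and vertex->face adjacency, reusable
// across ICP iterations via an external pointer. Vertex coordinates and
// face corners are flattened into plain arrays for the hot query loop.
struct SurfaceIndex {
  Rcpp::NumericMatrix vertices;  // keeps the R allocation alive
  KDTree tree;
  int nv;
  std::vector<double> vx, vy, vz;
  std::vector<double> tri;  // 9 doubles per face: a, b, c corners
  std::vector<int> start, adj;

  SurfaceIndex(Rcpp::NumericMatrix v, Rcpp::IntegerMatrix f)
      : vertices(v), tree(v), nv(v.nrow()) {
    int nf = f.nrow();
    vx.resize(nv);
    vy.resize(nv);
    vz.resize(nv);
    for (int i = 0; i < nv; ++i) {
      vx[i] = v(i, 0);
      vy[i] = v(i, 1);
      vz[i] = v(i, 2);
    }
    tri.resize(9 * nf);
    for (int ff = 0; ff < nf; ++ff)
      for (int k = 0; k < 3; ++k) {
        int vv = f(ff, k) - 1;
        tri[9 * ff + 3 * k] = vx[vv];
        tri[9 * ff + 3 * k + 1] = vy[vv];
        tri[9 * ff + 3 * k + 2] = vz[vv];
      }
    std::vector<int> count(nv, 0);
    for (int ff = 0; ff < nf; ++ff)
      for (int k = 0; k < 3; ++k) count[f(ff, k) - 1]++;
    start.assign(nv + 1, 0);
    for (int i = 0; i < nv; ++i) start[i + 1] = start[i] + count[i];
    adj.assign(start[nv], 0);
    std::vector<int> fill(nv, 0);
    for (int ff = 0; ff < nf; ++ff)
      for (int k = 0; k < 3; ++k) {
        int vv = f(ff, k) - 1;
        adj[start[vv] + fill[vv]++] = ff;
      }
  }
};

}  // namespace

// Build a reusable projection index for a target surface.
// [[Rcpp::export(name = ".surface_build")]]
SEXP surface_build(Rcpp::NumericMatrix vertices, Rcpp::IntegerMatrix faces) {
  if (vertices.ncol() != 3 || faces.ncol() != 3) Rcpp::stop("bad dimensions");
  Rcpp::XPtr<SurfaceIndex> ptr(new SurfaceIndex(vertices, faces), true);
  return ptr;
}

// Project each query point onto the indexed target surface: nearest target
// vertex by kd-tree, then the closest point among the triangles incident to
// that vertex. Returns the projection points and distances.
// [[Rcpp::export(name = ".surface_query")]]
Rcpp::List surface_query(SEXP handle, Rcpp::NumericMatrix query) {
  Rcpp::XPtr<SurfaceIndex> s(handle);
  if (query.ncol() != 3) Rcpp::stop("bad dimensions");
  int m = query.nrow();
  Rcpp::NumericMatrix proj(m, 3);
  Rcpp::NumericVector dist(m);
  const double *qx = &query(0, 0), *qy = &query(0, 1), *qz = &query(0, 2);
  double *px = &proj(0, 0), *py = &proj(0, 1), *pz = &proj(0, 2);
  double p[3], cp[3];
  for (int j = 0; j < m; ++j) {
    p[0] = qx[j];
    p[1] = qy[j];
    p[2] = qz[j];
    int best = -1;
    double bestd2 = R_PosInf;
    s->tree.query(p[0], p[1], p[2], 0, s->tree.n, 0, best, bestd2);
    double bd2 = bestd2;
    double bp[3] = {s->vx[best], s->vy[best], s->vz[best]};
    for (int st = s->start[best]; st < s->start[best + 1]; ++st) {
      const double *t = &s->tri[9 * s->adj[st]];
      closest_on_triangle(p, t, t + 3, t + 6, cp);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) d2 += (p[k] - cp[k]) * (p[k] - cp[k]);
      if (d2 < bd2) {
        bd2 = d2;
        for (int k = 0; k < 3; ++k) bp[k] = cp[k];
      }
    }
    px[j] = bp[0];
    py[j] = bp[1];
    pz[j] = bp[2];
    dist[j] = std::sqrt(bd2);
  }
  return Rcpp::List::create(Rcpp::Named("point") = proj,
                            Rcpp::Named("distance") = dist);
}
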