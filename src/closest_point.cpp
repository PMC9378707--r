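#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact closest point on a triangle (Ericson, Real-Time Collision Detection).
static inline void closest_pt_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3],
                                  double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k=0;k<3;++k) out[k]=a[k]; return; }

  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
    return;
  }

  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + w*ac[k];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + w*(c[k] - b[k]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children indices, -1 for leaf
  int start, count;  // face range (into order) for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;          // permutation of face indices
  const double *V;                 // nv x 3, column-major
  const int *F;                    // nf x 3, column-major, 0-based
  int nv, nf;
  std::vector<double> cx, cy, cz;  // face centroids

  void face_bbox(int f, double lo[3], double hi[3]) const {
    for (int k = 0; k < 3; ++k) { lo[k] = 1e300; hi[k] = -1e300; }
    for (int j = 0; j < 3; ++j) {
      int v = F[f + j * (size_t)nf];
      for (int k = 0; k < 3; ++k) {
        double x = V[v + k * (size_t)nv];
        if (x < lo[k]) lo[k] = x;
        if (x > hi[k]) hi[k] = x;
      }
    }
  }

  int build(int start, int count) {
    BVHNode nd;
    nd.start = start; nd.count = count; nd.left = nd.right = -1;
    for (int k = 0; k < 3; ++k) { nd.lo[k] = 1e300; nd.hi[k] = -1e300; }
    double lo[3], hi[3];
    for (int i = start; i < start + count; ++i) {
      face_bbox(order[i], lo, hi);
      for (int k = 0; k < 3; ++k) {
        if (lo[k] < nd.lo[k]) nd.lo[k] = lo[k];
        if (hi[k] > nd.hi[k]) nd.hi[k] = hi[k];
      }
    }
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 8) return idx;

    int axis = 0;
    double ext = nd.hi[0] - nd.lo[0];
    for (int k = 1; k < 3; ++k)
      if (nd.hi[k] - nd.lo[k] > ext) { ext = nd.hi[k] - nd.lo[k]; axis = k; }
    const std::vector<double> &cc = (axis == 0 ? cx : (axis == 1 ? cy : cz));
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&cc](int a, int b) { return cc[a] < cc[b]; });
    int l = build(start, count / 2);
    int r = build(mid, count - count / 2);
    nodes[idx].left = l;
    nodes[idx].right = r;
    return idx;
  }

  void init(const double *V_, int nv_, const int *F_, int nf_) {
    V = V_; F = F_; nv = nv_; nf = nf_;
    order.resize(nf);
    cx.resize(nf); cy.resize(nf); cz.resize(nf);
    for (int f = 0; f < nf; ++f) {
      order[f] = f;
      double s[3] = {0, 0, 0};
      for (int j = 0; j < 3; ++j) {
        int v = F[f + j * (size_t)nf];
        for (int k = 0; k < 3; ++k) s[k] += V[v + k * (size_t)nv];
      }
      cx[f] = s[0] / 3.0; cy[f] = s[1] / 3.0; cz[f] = s[2] / 3.0;
    }
    nodes.reserve(2 * nf / 8 + 4);
    build(0, nf);
  }

  static inline double box_dist2(const BVHNode &nd, const double p[3]) {
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = 0.0;
      if (p[k] < nd.lo[k]) d = nd.lo[k] - p[k];
      else if (p[k] > nd.hi[k]) d = p[k] - nd.hi[k];
      d2 += d * d;
    }
    return d2;
  }

  void query(const double p[3], double &best_d2, int &best_f,
             double best_pt[3], int node) const {
    const BVHNode &nd = nodes[node];
    if (box_dist2(nd, p) >= best_d2) return;
    if (nd.left < 0) {
      double av[3], bv[3], cv[3], q[3];
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int f = order[i];
        int ia = F[f], ib = F[f + (size_t)nf], ic = F[f + 2 * (size_t)nf];
        for (int k = 0; k < 3; ++k) {
          av[k] = V[ia + k * (size_t)nv];
          bv[k] = V[ib + k * (size_t)nv];
          cv[k] = V[ic + k * (size_t)nv];
        }
        closest_pt_tri(p, av, bv, cv, q);
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) d2 += (q[k]-p[k])*(q[k]-p[k]);
        // ties broken toward the lowest face index
        if (d2 < best_d2 - 1e-24 ||
            (d2 <= best_d2 + 1e-24 && best_f >= 0 && f < best_f && d2 <= best_d2)) {
          best_d2 = d2; best_f = f;
          for (int k = 0; k < 3; ++k) best_pt[k] = q[k];
        }
      }
      return;
    }
    // descend nearer child first
    double dl = box_dist2(nodes[nd.left], p);
    double dr = box_dist2(nodes[nd.right], p);
    if (dl < dr) { query(p, best_d2, best_f, best_pt, nd.left);
                   query(p, best_d2, best_f, best_pt, nd.right); }
    else         { query(p, best_d2, best_f, best_pt, nd.right);
                   query(p, best_d2, best_f, best_pt, nd.left); }
  }
};

// [[Rcpp::export(name = ".cpp_closest_on_mesh")]]
List cpp_closest_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nv = V.nrow(), nf = F.nrow(), nq = Q.nrow();
  if (nf < 1) stop("target mesh has no faces");
  std::vector<int> F0((size_t)nf * 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < nf; ++i) F0[i + j * (size_t)nf] = F(i, j) - 1;

  BVH tree;
  tree.init(REAL(V), nv, F0.data(), nf);

  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);
  double p[3], bp[3];
  for (int i = 0; i < nq; ++i) {
    p[0] = Q(i, 0); p[1] = Q(i, 1); p[2] = Q(i, 2);
    double bd2 = 1e300; int bf = -1;
    tree.query(p, bd2, bf, bp, 0);
    P(i, 0) = bp[0]; P(i, 1) = bp[1]; P(i, 2) = bp[2];
    D[i] = std::sqrt(bd2);
    FI[i] = bf + 1;
  }
  return List::create(_["point"] = P, _["distance"] = D, _["face"] = FI);
}
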