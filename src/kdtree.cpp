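#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact 3-d KD-tree over the reference cloud. Median-split on cycling axes;
// equal-distance ties resolved to the smallest reference index, which
// requires descending into the far half-space when the axis gap equals the
// current best distance (strict-> prune only).
namespace {

struct KDTree {
  const double* pts;  // column-major n x 3
  int n;
  std::vector<int> perm;

  double coord(int i, int a) const { return pts[i + static_cast<size_t>(a) * n]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    const int axis = depth % 3;
    const int mid = (lo + hi) / 2;
    std::nth_element(
        perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
        [&](int a, int b) {
          const double ca = coord(a, axis), cb = coord(b, axis);
          return ca < cb || (ca == cb && a < b);
        });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(int lo, int hi, int depth, const double* q,
             double& bestD2, int& bestIdx) const {
    if (hi <= lo) return;
    const int axis = depth % 3;
    const int mid = (lo + hi) / 2;
    const int i = perm[mid];
    const double dx = q[0] - coord(i, 0);
    const double dy = q[1] - coord(i, 1);
    const double dz = q[2] - coord(i, 2);
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestD2 || (d2 == bestD2 && i < bestIdx)) {
      bestD2 = d2;
      bestIdx = i;
    }
    const double diff = q[axis] - coord(i, axis);
    if (diff < 0) {
      query(lo, mid, depth + 1, q, bestD2, bestIdx);
      if (diff * diff <= bestD2) query(mid + 1, hi, depth + 1, q, bestD2, bestIdx);
    } else {
      query(mid + 1, hi, depth + 1, q, bestD2, bestIdx);
      if (diff * diff <= bestD2) query(lo, mid, depth + 1, q, bestD2, bestIdx);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".nn_kdtree")]]
List nn_kdtree(NumericMatrix reference, NumericMatrix query) {
  if (reference.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have three columns");
  const int n = reference.nrow();
  const int m = query.nrow();
  if (n < 1 || m < 1) stop("empty point cloud");

  KDTree tree;
  tree.pts = REAL(reference);
  tree.n = n;
  tree.perm.resize(n);
  for (int i = 0; i < n; ++i) tree.perm[i] = i;
  tree.build(0, n, 0);

  IntegerVector idx(m);
  NumericVector dist(m);
  const double* qp = REAL(query);
  for (int k = 0; k < m; ++k) {
    const double q[3] = {qp[k], qp[k + static_cast<size_t>(m)],
                         qp[k + 2 * static_cast<size_t>(m)]};
    double bestD2 = R_PosInf;
    int bestIdx = n;  // sentinel larger than any real index
    tree.query(0, n, 0, q, bestD2, bestIdx);
    idx[k] = bestIdx + 1;  // 1-based for R
    dist[k] = std::sqrt(bestD2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
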