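#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Large finite stand-in for +Inf; keeps parabola intersections finite.
static const double BIG = 1e30;

static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  if (connectivity == 6) {
    off = {{{1, 0, 0}}, {{-1, 0, 0}}, {{0, 1, 0}}, {{0, -1, 0}}, {{0, 0, 1}}, {{0, 0, -1}}};
  } else if (connectivity == 26) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (a || b || c) off.push_back({{a, b, c}});
  } else {
    stop("connectivity must be 6 or 26");
  }
  return off;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower
// envelope), sample positions q * s for grid step s.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && sint <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

//' Exact anisotropic 3D Euclidean distance transform.
//' mask: integer 0/1 array (1 = foreground); dims: array extents;
//' spacing: physical step per axis, in array-dimension order.
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? BIG : 0.0;
  int nd[3] = {n1, n2, n3};
  R_xlen_t stride[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
  for (int a = 0; a < 3; ++a) {
    int na = nd[a];
    if (na < 2) continue;
    double s = spacing[a];
    int b = (a == 0) ? 1 : 0;
    int c = (a == 2) ? 1 : 2;
    std::vector<double> f(na), d(na), z(na + 1);
    std::vector<int> v(na);
    for (int ib = 0; ib < nd[b]; ++ib) {
      for (int ic = 0; ic < nd[c]; ++ic) {
        R_xlen_t base = ib * stride[b] + ic * stride[c];
        for (int q = 0; q < na; ++q) f[q] = D[base + q * stride[a]];
        dt1d(f, d, v, z, na, s);
        for (int q = 0; q < na; ++q) D[base + q * stride[a]] = d[q];
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) D[i] = std::sqrt(D[i]);
  return D;
}

struct WsNode {
  double p;
  R_xlen_t ord;
  R_xlen_t idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.p != b.p) return a.p > b.p;  // min-heap on priority value
    return a.ord > b.ord;              // FIFO tie-break for determinism
  }
};

//' Marker-controlled watershed by ordered flooding (Meyer).
//' Floods masked voxels in increasing priority value starting from the
//' marker voxels; each voxel takes the label of whichever labelled
//' neighbor reached it first in the flooding order.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector markers,
                              IntegerVector mask, IntegerVector dims,
                              int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (priority.size() != n || markers.size() != n || mask.size() != n)
    stop("input length does not match dims");
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t ord = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    lab[i] = 0;
    if (markers[i] > 0 && mask[i]) pq.push({priority[i], ord++, i, markers[i]});
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    if (lab[nd.idx] != 0) continue;
    lab[nd.idx] = nd.lab;
    int i1 = (int)(nd.idx % n1);
    R_xlen_t rest = nd.idx / n1;
    int i2 = (int)(rest % n2);
    int i3 = (int)(rest / n2);
    for (size_t t = 0; t < off.size(); ++t) {
      int j1 = i1 + off[t][0], j2 = i2 + off[t][1], j3 = i3 + off[t][2];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
      R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
      if (!mask[j] || lab[j] != 0) continue;
      pq.push({priority[j], ord++, j, nd.lab});
    }
  }
  return lab;
}

//' Connected-component labelling of a 3D binary mask (scan-order seeds,
//' breadth-first growth; deterministic label order).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims, int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i1 = (int)(cur % n1);
      R_xlen_t rest = cur / n1;
      int i2 = (int)(rest % n2);
      int i3 = (int)(rest / n2);
      for (size_t t = 0; t < off.size(); ++t) {
        int j1 = i1 + off[t][0], j2 = i2 + off[t][1], j3 = i3 + off[t][2];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
        R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

//' Local maxima of img restricted to mask: voxels whose value is >= all
//' in-bounds masked neighbors. Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima3d(NumericVector img, IntegerVector mask,
                                 IntegerVector dims, int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (img.size() != n || mask.size() != n) stop("input length does not match dims");
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  std::vector<int> out;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    double v = img[i];
    int i1 = (int)(i % n1);
    R_xlen_t rest = i / n1;
    int i2 = (int)(rest % n2);
    int i3 = (int)(rest / n2);
    bool ok = true;
    for (size_t t = 0; t < off.size() && ok; ++t) {
      int j1 = i1 + off[t][0], j2 = i2 + off[t][1], j3 = i3 + off[t][2];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
      R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
      if (mask[j] && img[j] > v) ok = false;
    }
    if (ok) out.push_back((int)(i + 1));
  }
  return IntegerVector(out.begin(), out.end());
}
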