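#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding (Adams & Bischof style
// seeded region growing on the gradient image). Pixels are flooded in order
// of increasing gradient value; ties are broken by queue insertion order,
// with seeds inserted in raster-scan order, so the result is deterministic.

struct Node {
  double v;
  long long ord;
  int idx;
};

struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.v != b.v) return a.v > b.v;   // min-heap on gradient value
    return a.ord > b.ord;               // FIFO among equal values
  }
};

// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix grad, IntegerMatrix markers) {
  const int nr = grad.nrow(), nc = grad.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("gradient and marker images must have the same shape");
  IntegerMatrix lab(nr, nc); // 0 = unassigned
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  long long ord = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int m = markers(r, c);
      if (m > 0) {
        lab(r, c) = m;
        pq.push(Node{grad(r, c), ord++, r + c * nr});
      }
    }
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node n = pq.top();
    pq.pop();
    const int c = n.idx / nr, r = n.idx % nr;
    const int L = lab(r, c);
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) == 0) {
        lab(rr, cc) = L;
        pq.push(Node{grad(rr, cc), ord++, rr + cc * nr});
      }
    }
  }
  return lab;
}
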