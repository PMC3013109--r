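#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Deterministic agglomerative linkage clustering over a symmetric distance
// matrix.  Missing pairs (passed as +Inf) never merge under any linkage.
//
// Tie-breaking: among equal minimal linkage values, merge the cluster pair
// whose lexicographically smallest member id (precomputed as `rank`) is
// least, then the other cluster's smallest member.  This makes the merge
// sequence fully deterministic and reproducible by a naive scan.
//
// For average linkage the state matrix holds the SUM of inter-cluster pair
// distances (exact additions under Lance-Williams), and comparisons divide
// by the pair count on demand; this keeps the computed values identical to
// a direct mean over the original matrix whenever the summation is exact.

namespace {

struct State {
  int n;
  int method;                 // 0 complete, 1 single, 2 average
  std::vector<double> m;      // linkage value (or pair-distance sum)
  std::vector<int> size;
  std::vector<int> minRank;   // lex rank of smallest member id
  std::vector<int> repItem;   // item index (0-based) of smallest member
  std::vector<bool> active;

  double& at(int i, int j) { return m[(size_t)i * n + j]; }

  double value(int i, int j) {
    double v = at(i, j);
    if (method == 2) {
      double np = (double)size[i] * (double)size[j];
      return v / np;
    }
    return v;
  }

  // is pair (i,j) better than (k,l)?  vij/vkl are linkage values.
  bool better(double vij, int i, int j, double vkl, int k, int l) {
    if (vij < vkl) return true;
    if (vij > vkl) return false;
    int a1 = std::min(minRank[i], minRank[j]);
    int b1 = std::max(minRank[i], minRank[j]);
    int a2 = std::min(minRank[k], minRank[l]);
    int b2 = std::max(minRank[k], minRank[l]);
    if (a1 != a2) return a1 < a2;
    return b1 < b2;
  }
};

} // namespace

// [[Rcpp::export(name = ".linkageCore")]]
List linkageCore(NumericMatrix dist, IntegerVector rank, int method,
                 double maxCutoff) {
  const int n = dist.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  State st;
  st.n = n;
  st.method = method;
  st.m.assign((size_t)n * n, 0.0);
  st.size.assign(n, 1);
  st.minRank.resize(n);
  st.repItem.resize(n);
  st.active.assign(n, true);
  for (int i = 0; i < n; ++i) {
    st.minRank[i] = rank[i];
    st.repItem[i] = i;
    for (int j = 0; j < n; ++j) {
      double d = dist(i, j);
      st.at(i, j) = (i == j) ? 0.0 : (ISNA(d) || ISNAN(d) ? inf : d);
    }
  }

  // nearest "better-pair" neighbour per active cluster
  std::vector<int> nn(n, -1);
  auto scanNN = [&](int i) {
    int best = -1;
    double bestV = inf;
    for (int j = 0; j < n; ++j) {
      if (j == i || !st.active[j]) continue;
      double v = st.value(i, j);
      if (best < 0 || st.better(v, i, j, bestV, i, best)) {
        best = j; bestV = v;
      }
    }
    nn[i] = best;
  };
  for (int i = 0; i < n; ++i) scanNN(i);

  std::vector<int> outA, outB;
  std::vector<double> outH;
  int nActive = n;

  while (nActive > 1) {
    int bi = -1, bj = -1;
    double bv = inf;
    for (int i = 0; i < n; ++i) {
      if (!st.active[i] || nn[i] < 0) continue;
      int j = nn[i];
      double v = st.value(i, j);
      if (bi < 0 || st.better(v, i, j, bv, bi, bj)) {
        bi = i; bj = j; bv = v;
      }
    }
    if (bi < 0 || !(bv <= maxCutoff)) break;  // Inf or beyond the last cutoff

    // survivor = cluster holding the smaller minRank (deterministic slot)
    int a = bi, b = bj;
    if (st.minRank[b] < st.minRank[a]) std::swap(a, b);
    outA.push_back(st.repItem[a]);
    outB.push_back(st.repItem[b]);
    outH.push_back(bv);

    // Lance-Williams update of row a
    for (int k = 0; k < n; ++k) {
      if (!st.active[k] || k == a || k == b) continue;
      double dak = st.at(a, k), dbk = st.at(b, k);
      double nd;
      if (method == 0) nd = std::max(dak, dbk);
      else if (method == 1) nd = std::min(dak, dbk);
      else nd = dak + dbk;  // sums add exactly
      st.at(a, k) = nd;
      st.at(k, a) = nd;
    }
    st.size[a] += st.size[b];
    // minRank[a] already the smaller; repItem[a] stays the lex-least member
    st.active[b] = false;
    --nActive;

    if (nActive == 1) break;
    scanNN(a);
    for (int k = 0; k < n; ++k) {
      if (!st.active[k] || k == a) continue;
      if (nn[k] == b || nn[k] == a) {
        scanNN(k);
      } else {
        double va = st.value(k, a);
        double vc = st.value(k, nn[k]);
        if (st.better(va, k, a, vc, k, nn[k])) nn[k] = a;
      }
    }
  }

  return List::create(_["a"] = wrap(outA), _["b"] = wrap(outB),
                      _["height"] = wrap(outH));
}
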