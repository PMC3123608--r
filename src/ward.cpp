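#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Agglomerative Ward clustering on a precomputed dissimilarity matrix,
// cut at K clusters.
//
// Lance-Williams recurrence on SQUARED dissimilarities (the "ward.D2"
// convention): after merging clusters i and j,
//   D(ij,k) = [ (n_i+n_k) D(i,k) + (n_j+n_k) D(j,k) - n_k D(i,j) ]
//             / (n_i+n_j+n_k).
// Merges pick the globally smallest D; exact ties resolve to the smallest
// (i,j) index pair.  Nearest-neighbour caching (as in stats::hclust) keeps
// the typical cost at O(N^2), which matters because the bootstrap
// re-clusters every replicate.
//
// Returns integer labels 1..K, numbered by order of first appearance.
// [[Rcpp::export(name = ".wardLabels")]]
IntegerVector ward_labels_cpp(NumericMatrix d, int K) {
  const int n = d.nrow();
  if (d.ncol() != n) stop("distance matrix must be square");
  if (K < 1 || K > n) stop("K must be between 1 and the number of rows");

  const double INF = std::numeric_limits<double>::infinity();

  // squared dissimilarities, full symmetric storage
  std::vector<double> D((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = d(i, j);
      if (!R_finite(v)) stop("non-finite dissimilarity");
      D[(size_t)i * n + j] = v * v;
    }

  std::vector<int> sz(n, 1);
  std::vector<bool> active(n, true);
  std::vector<int> nn(n, -1);        // nearest active neighbour with index > i
  std::vector<double> nnd(n, INF);
  std::vector<int> head(n), nxt(n, -1), tail(n); // member lists per cluster
  for (int i = 0; i < n; ++i) { head[i] = i; tail[i] = i; }

  // strict '<' while scanning ascending j keeps the smallest tied neighbour
  auto computeNN = [&](int i) {
    nn[i] = -1; nnd[i] = INF;
    const double* Di = &D[(size_t)i * n];
    for (int j = i + 1; j < n; ++j)
      if (active[j] && Di[j] < nnd[i]) { nnd[i] = Di[j]; nn[i] = j; }
  };
  for (int i = 0; i < n - 1; ++i) computeNN(i);

  int nActive = n;
  while (nActive > K) {
    // globally smallest cached pair; ascending scan + strict '<' gives the
    // smallest (i, j) under ties
    int bi = -1; double best = INF;
    for (int i = 0; i < n - 1; ++i)
      if (active[i] && nn[i] >= 0 && nnd[i] < best) { best = nnd[i]; bi = i; }
    if (bi < 0) stop("internal error: no mergeable pair");
    int bj = nn[bi];

    // Lance-Williams update of D(bi, k) for all other active k
    const double ni = sz[bi], nj = sz[bj], dij = D[(size_t)bi * n + bj];
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      const double nk = sz[k];
      double v = ((ni + nk) * D[(size_t)bi * n + k] +
                  (nj + nk) * D[(size_t)bj * n + k] -
                  nk * dij) / (ni + nj + nk);
      D[(size_t)bi * n + k] = v;
      D[(size_t)k * n + bi] = v;
    }
    active[bj] = false;
    sz[bi] += sz[bj];
    nxt[tail[bi]] = head[bj];
    tail[bi] = tail[bj];
    --nActive;

    // refresh invalidated nearest-neighbour entries
    computeNN(bi);
    for (int i = 0; i < bj; ++i) {
      if (!active[i] || i == bi) continue;
      if (nn[i] == bj) { computeNN(i); continue; }
      if (i < bi) {
        double v = D[(size_t)i * n + bi];
        if (nn[i] == bi) {
          // distance to bi changed; if it grew, another cluster may be nearer
          if (v <= nnd[i]) nnd[i] = v; else computeNN(i);
        } else if (v < nnd[i] || (v == nnd[i] && bi < nn[i])) {
          nnd[i] = v; nn[i] = bi;
        }
      }
    }
  }

  // labels by order of first appearance of each surviving cluster
  IntegerVector labels(n);
  int lab = 0;
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    ++lab;
    for (int m = head[i]; m != -1; m = nxt[m]) labels[m] = lab;
  }
  return labels;
}
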