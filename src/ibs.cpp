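#include <Rcpp.h>
using namespace Rcpp;

// Pairwise allele-sharing distance over a markers x individuals genotype
// matrix (0/1/2, NA missing): d(i,j) = sum_m |g_i - g_j| / (2 * M_ij),
// with M_ij the number of markers non-missing in both.  Returns the
// distance matrix and the per-pair marker counts.
// [[Rcpp::export(name = ".ibsDistance")]]
List ibs_distance_cpp(IntegerMatrix g) {
  const int M = g.nrow(), N = g.ncol();
  NumericMatrix d(N, N);
  IntegerMatrix cnt(N, N);
  // column-wise copies for locality
  std::vector<signed char> gc((size_t)M * N);
  for (int j = 0; j < N; ++j)
    for (int m = 0; m < M; ++m) {
      int v = g(m, j);
      gc[(size_t)j * M + m] = (v == NA_INTEGER) ? (signed char)-1
                                                : (signed char)v;
    }
  for (int i = 0; i < N; ++i) {
    const signed char* gi = &gc[(size_t)i * M];
    for (int j = i + 1; j < N; ++j) {
      const signed char* gj = &gc[(size_t)j * M];
      int s = 0, c = 0;
      for (int m = 0; m < M; ++m) {
        if (gi[m] < 0 || gj[m] < 0) continue;
        s += std::abs(gi[m] - gj[m]);
        ++c;
      }
      cnt(i, j) = cnt(j, i) = c;
      double v = c > 0 ? s / (2.0 * c) : NA_REAL;
      d(i, j) = d(j, i) = v;
    }
    cnt(i, i) = M;
  }
  return List::create(_["d"] = d, _["pairCounts"] = cnt);
}
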