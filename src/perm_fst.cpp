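#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of Hudson window FST under balanced relabeling.
// H is the n x S haplotype matrix coded 0/1 with NA for unphased
// calls (n even, relabeled groups of n/2); each replicate draws a
// uniform balanced relabeling with R's RNG (so set.seed() on the R
// side makes the stream reproducible) and returns the
// ratio-of-averages FST over sites with at least two called
// haplotypes per group (NA when no site has a positive between-group
// denominator).
// [[Rcpp::export]]
NumericVector perm_fst_null_cpp(IntegerMatrix H, int B) {
  const int n = H.nrow(), S = H.ncol(), half = n / 2;
  if (n % 2 != 0) stop("balanced relabeling needs an even number of rows");
  NumericVector out(B);
  // site-major copy for contiguous access in the inner loop
  std::vector<int> hv((size_t)n * S), tot(S, 0), totn(S, 0), idx(n);
  const int* hp = INTEGER(H);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) {
      const int v = hp[(size_t)s * n + i];
      if (v == NA_INTEGER) {
        hv[(size_t)s * n + i] = -1;
      } else {
        hv[(size_t)s * n + i] = v;
        tot[s] += v;
        ++totn[s];
      }
    }
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < half; ++i) {        // partial Fisher-Yates
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    double num = 0.0, den = 0.0;
    const int* base = hv.data();
    for (int s = 0; s < S; ++s) {
      const int* col = base + (size_t)s * n;
      int c1 = 0, m1 = 0;
      for (int i = 0; i < half; ++i) {
        const int v = col[idx[i]];
        if (v >= 0) { c1 += v; ++m1; }
      }
      const int c2 = tot[s] - c1, m2 = totn[s] - m1;
      if (m1 < 2 || m2 < 2) continue;
      const double hx = 2.0 * c1 * (m1 - c1) / (m1 * (m1 - 1.0));
      const double hy = 2.0 * c2 * (m2 - c2) / (m2 * (m2 - 1.0));
      const double px = (double)c1 / m1, py = (double)c2 / m2;
      const double hb = px * (1.0 - py) + py * (1.0 - px);
      num += hb - 0.5 * (hx + hy);
      den += hb;
    }
    out[b] = den > 0 ? num / den : NA_REAL;
  }
  return out;
}
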