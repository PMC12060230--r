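#include <Rcpp.h>
using namespace Rcpp;

// Maximal identical-run span (bp) for every haplotype pair in a window.
//
// H: haplotypes x sites, values 0/1 or NA; pos: site positions (bp),
// strictly increasing. For a pair, only sites where both haplotypes are
// non-missing are used (missing sites break no run but contribute no
// length). A run from site a to site b spans pos[b] - pos[a]; a single-site
// run spans the midpoints to its flanking usable sites (clipped at the
// first/last usable site). Pairs whose usable-site fraction falls below
// 1 - max_missing are returned as NA.
// [[Rcpp::export]]
NumericVector pair_identity_spans(IntegerMatrix H, NumericVector pos,
                                  double max_missing) {
  const int n = H.nrow();
  const int S = H.ncol();
  if (pos.size() != S) stop("pos length must equal the number of sites");
  const int n_pairs = n * (n - 1) / 2;
  NumericVector out(n_pairs);
  std::vector<double> pu(S);
  std::vector<int> eq(S);
  int k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      int U = 0;
      for (int s = 0; s < S; ++s) {
        int a = H(i, s), b = H(j, s);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        pu[U] = pos[s];
        eq[U] = (a == b);
        ++U;
      }
      if (S > 0 && U < (1.0 - max_missing) * S) {
        out[k] = NA_REAL;
        continue;
      }
      double best = 0.0;
      int s = 0;
      while (s < U) {
        if (!eq[s]) { ++s; continue; }
        int e = s;
        while (e + 1 < U && eq[e + 1]) ++e;
        double span;
        if (e > s) {
          span = pu[e] - pu[s];
        } else {
          double left = (s > 0) ? (pu[s] + pu[s - 1]) / 2.0 : pu[s];
          double right = (s < U - 1) ? (pu[s] + pu[s + 1]) / 2.0 : pu[s];
          span = right - left;
        }
        if (span > best) best = span;
        s = e + 1;
      }
      out[k] = best;
    }
  }
  return out;
}
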