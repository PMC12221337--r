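#include <Rcpp.h>
using namespace Rcpp;

// All-pairs between-community mean nearest taxon distance (beta-MNTD).
// counts: samples x taxa; D: taxa x taxa patristic distances aligned to
// the count columns. Taxa absent from a sample are excluded from that
// sample's sums. One pass per pair maintains row and column minima.

// [[Rcpp::export]]
NumericMatrix bmntd_all_cpp(NumericMatrix counts, NumericMatrix D,
                            bool weighted) {
  const int S = counts.nrow();
  std::vector< std::vector<int> > present(S);
  std::vector< std::vector<double> > wts(S);
  for (int s = 0; s < S; ++s) {
    double tot = 0.0;
    for (int j = 0; j < counts.ncol(); ++j) {
      if (counts(s, j) > 0) {
        present[s].push_back(j);
        tot += counts(s, j);
      }
    }
    const int n = present[s].size();
    wts[s].resize(n);
    for (int a = 0; a < n; ++a)
      wts[s][a] = weighted ? counts(s, present[s][a]) / tot : 1.0 / n;
  }

  NumericMatrix out(S, S);
  std::vector<double> rmin, cmin;
  for (int k = 0; k < S; ++k) {
    for (int m = k + 1; m < S; ++m) {
      const std::vector<int>& A = present[k];
      const std::vector<int>& B = present[m];
      const int na = A.size(), nb = B.size();
      rmin.assign(na, R_PosInf);
      cmin.assign(nb, R_PosInf);
      for (int b = 0; b < nb; ++b) {
        const double* col = &D(0, B[b]);
        for (int a = 0; a < na; ++a) {
          const double v = col[A[a]];
          if (v < rmin[a]) rmin[a] = v;
          if (v < cmin[b]) cmin[b] = v;
        }
      }
      double s1 = 0.0, s2 = 0.0;
      for (int a = 0; a < na; ++a) s1 += wts[k][a] * rmin[a];
      for (int b = 0; b < nb; ++b) s2 += wts[m][b] * cmin[b];
      out(k, m) = out(m, k) = 0.5 * (s1 + s2);
    }
  }
  return out;
}
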