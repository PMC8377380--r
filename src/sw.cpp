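#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps (Gotoh).
// Sequences arrive as 0-based integer indices into the substitution matrix.
// A gap of length L costs gapOpen + (L - 1) * gapExtend.
// [[Rcpp::export]]
double sw_score_cpp(const IntegerVector& s1, const IntegerVector& s2,
                    const NumericMatrix& subs, double gapOpen,
                    double gapExtend) {
  const int n = s1.size(), m = s2.size();
  if (n == 0 || m == 0) return 0.0;

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> F(m + 1, R_NegInf);  // gap in s2 (vertical)
  double best = 0.0;

  for (int i = 1; i <= n; ++i) {
    const int a = s1[i - 1];
    double E = R_NegInf;                   // gap in s1 (horizontal)
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - gapOpen, E - gapExtend);
      F[j] = std::max(Hprev[j] - gapOpen, F[j] - gapExtend);
      double h = Hprev[j - 1] + subs(a, s2[j - 1]);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0.0) h = 0.0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}
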