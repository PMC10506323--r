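#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment score with affine gaps.  A gap of length
// g costs -(gap_open + g * gap_ext); characters outside ACGT (e.g. N) never
// match.  Returns the best local score.
// [[Rcpp::export]]
double sw_best_score(const std::string& query, const std::string& subject,
                     double match, double mismatch, double gap_open,
                     double gap_ext) {
  const int m = query.size(), n = subject.size();
  if (m == 0 || n == 0) return 0.0;
  const double ninf = -1e30;
  const double oe = gap_open + gap_ext;
  std::vector<double> H(n + 1, 0.0), F(n + 1, ninf);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;  // H[i-1][j-1]
    double left = 0.0;  // H[i][j-1]
    double E = ninf;    // horizontal gap state in row i
    char qc = query[i - 1];
    bool qn = !(qc == 'A' || qc == 'C' || qc == 'G' || qc == 'T');
    for (int j = 1; j <= n; ++j) {
      char sc = subject[j - 1];
      bool sn = !(sc == 'A' || sc == 'C' || sc == 'G' || sc == 'T');
      double s = (!qn && !sn && qc == sc) ? match : mismatch;
      F[j] = std::max(H[j] - oe, F[j] - gap_ext);  // H[j] is still row i-1
      E = std::max(left - oe, E - gap_ext);
      double h = std::max(0.0, diag + s);
      h = std::max(h, std::max(E, F[j]));
      diag = H[j];
      H[j] = h;
      left = h;
      if (h > best) best = h;
    }
  }
  return best;
}
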