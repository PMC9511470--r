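#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// DET(eps; l_min) over a grid of thresholds for a scalar series.
//
// Pairwise distances are laid out once, diagonal by diagonal (offsets
// k = max(theiler,1) .. n-1 of the upper triangle; the matrix is symmetric
// so lower-triangle lines mirror these and are counted by doubling). For
// each threshold the maximal runs of within-threshold points are scanned:
// every run contributes its length to the denominator (total off-Theiler
// recurrent points) and, if at least l_min long, to the numerator.
// With theiler == 0 the line of identity contributes one length-n line,
// counted once (not doubled).
// [[Rcpp::export]]
List rqa_det_curve_cpp(NumericVector x, NumericVector eps_grid,
                       int lmin, int theiler) {
  const int n = x.size();
  const int G = eps_grid.size();
  if (n < 2) stop("series too short");
  if (lmin < 1) stop("l_min must be >= 1");
  if (theiler < 0 || theiler >= n) stop("need 0 <= theiler < n");

  const int k0 = theiler > 1 ? theiler : 1;
  std::vector<double> dist;
  std::vector<int> diag_len;
  dist.reserve((size_t)n * (n - 1) / 2);
  for (int k = k0; k <= n - 1; ++k) {
    diag_len.push_back(n - k);
    for (int i = 0; i < n - k; ++i) {
      dist.push_back(std::abs(x[i] - x[i + k]));
    }
  }

  NumericVector det(G);
  NumericVector recurrences(G);
  for (int g = 0; g < G; ++g) {
    const double e = eps_grid[g];
    double num = 0.0, den = 0.0;
    size_t pos = 0;
    for (size_t dgi = 0; dgi < diag_len.size(); ++dgi) {
      const int m = diag_len[dgi];
      int run = 0;
      for (int i = 0; i < m; ++i, ++pos) {
        if (dist[pos] <= e) {
          ++run;
        } else if (run > 0) {
          den += run;
          if (run >= lmin) num += run;
          run = 0;
        }
      }
      if (run > 0) {
        den += run;
        if (run >= lmin) num += run;
      }
    }
    num *= 2.0;  // mirror diagonals below the main diagonal
    den *= 2.0;
    if (theiler == 0) {  // line of identity, counted once
      den += n;
      if (n >= lmin) num += n;
    }
    recurrences[g] = den;
    det[g] = den > 0.0 ? num / den : 0.0;
  }
  return List::create(_["det"] = det, _["recurrences"] = recurrences);
}
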