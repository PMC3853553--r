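// Isotonic (monotone non-decreasing) regression of configuration distances
// on the rank order of the input dissimilarities, plus Kruskal stress-1.
// Tied dissimilarities form one block and share a fitted value (mean-rank
// tie handling). Weighted pool-adjacent-violators, O(n).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// dh: configuration distances (original pair order)
// ord: 1-based positions sorting the input dissimilarities increasingly
// block: 1-based tie-block id per sorted position (non-decreasing)
// nblock: number of blocks
// [[Rcpp::export(name = ".stress_iso")]]
List stress_iso(NumericVector dh, IntegerVector ord, IntegerVector block,
                int nblock) {
  const int P = dh.size();
  std::vector<double> bsum(nblock, 0.0), bw(nblock, 0.0);
  for (int p = 0; p < P; ++p) {
    const double v = dh[ord[p] - 1];
    bsum[block[p] - 1] += v;
    bw[block[p] - 1] += 1.0;
  }
  // PAVA over block means with block sizes as weights
  std::vector<double> val(nblock), wt(nblock);
  std::vector<int> len(nblock);
  int top = -1;
  for (int b = 0; b < nblock; ++b) {
    double v = bsum[b] / bw[b], w = bw[b];
    int l = 1;
    while (top >= 0 && val[top] >= v) {
      v = (val[top] * wt[top] + v * w) / (wt[top] + w);
      w += wt[top];
      l += len[top];
      --top;
    }
    ++top;
    val[top] = v;
    wt[top] = w;
    len[top] = l;
  }
  std::vector<double> bfit(nblock);
  int b = 0;
  for (int s = 0; s <= top; ++s) {
    for (int l = 0; l < len[s]; ++l) bfit[b++] = val[s];
  }
  NumericVector fit(P);
  double num = 0.0, den = 0.0;
  for (int p = 0; p < P; ++p) {
    fit[ord[p] - 1] = bfit[block[p] - 1];
  }
  for (int p = 0; p < P; ++p) {
    const double r = dh[p] - fit[p];
    num += r * r;
    den += dh[p] * dh[p];
  }
  const double stress = den > 0 ? std::sqrt(num / den) : 0.0;
  return List::create(_["stress"] = stress, _["fit"] = fit);
}
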