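// Affine-gap pairwise alignment kernels (Gotoh) for short amplicons.
//
// Two modes:
//  * global:      both sequences aligned end to end, end gaps penalized.
//  * semi-global: the query is aligned in full, but the reference may
//                 overhang on either side for free; overhanging reference
//                 positions are excluded from the alignment columns.
//
// A gap of length k costs gap_open + (k - 1) * gap_extend. 'N' never
// scores as a match (it takes the mismatch score against everything,
// including another 'N') and is never counted as an identity match.
// Tie preference on equal scores is M (diagonal) > Y (gap in query) >
// X (gap in reference), fixed for determinism.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

const double NEG_INF = -1e18;

inline bool is_match(char a, char b) { return a == b && a != 'N'; }

struct AlnResult {
  double score;
  int matches;
  int columns;
};

// matrix codes: 0 = M (diagonal), 1 = X (gap in ref), 2 = Y (gap in query)
// band_w >= 0 restricts the path to diagonals within band_w of the
// straight corner-to-corner corridor; every alignment whose identity can
// reach the caller's threshold lies inside the corridor, so join/reject
// decisions match the unbanded optimum. band_w < 0 disables banding.
AlnResult align_pair(const std::string& q, const std::string& r,
                     double match, double mismatch,
                     double gap_open, double gap_extend, bool semi,
                     int band_w) {
  const int n = q.size(), m = r.size();
  const int W = m + 1;
  int dlo = -(m + 1), dhi = n + 1; // i - j bounds
  if (band_w >= 0 && !semi) {
    dlo = std::min(0, n - m) - band_w;
    dhi = std::max(0, n - m) + band_w;
  }
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1),
      tbY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + (i - 1) * gap_extend);
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    if (semi) {
      M[j] = 0.0; // free leading reference overhang: start anywhere
    } else {
      Y[j] = -(gap_open + (j - 1) * gap_extend);
      tbY[j] = (j == 1) ? 0 : 2;
    }
  }

  // pick the best of (from M, from X, from Y) with preference M > Y > X
  auto pick = [](double vm, double vx, double vy, double& best,
                 signed char& from) {
    best = vm; from = 0;
    if (vy > best) { best = vy; from = 2; }
    if (vx > best) { best = vx; from = 1; }
  };

  for (int i = 1; i <= n; ++i) {
    const int j0 = std::max(1, i - dhi), j1 = std::min(m, i - dlo);
    for (int j = j0; j <= j1; ++j) {
      const int ij = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = is_match(q[i - 1], r[j - 1]) ? match : mismatch;
      double best; signed char from;
      pick(M[dg], X[dg], Y[dg], best, from);
      if (best > NEG_INF / 2) { M[ij] = best + s; tbM[ij] = from; }
      pick(M[up] - gap_open, X[up] - gap_extend, Y[up] - gap_open, best, from);
      if (best > NEG_INF / 2) { X[ij] = best; tbX[ij] = from; }
      pick(M[lf] - gap_open, X[lf] - gap_open, Y[lf] - gap_extend, best, from);
      if (best > NEG_INF / 2) { Y[ij] = best; tbY[ij] = from; }
    }
  }

  // end cell
  int ej = m, emat = 0;
  double score;
  if (semi) {
    score = NEG_INF;
    for (int j = 0; j <= m; ++j) {
      const int ij = n * W + j;
      // free trailing overhang: alignment may end at any reference column;
      // a trailing gap in the reference (X) stays penalized
      if (M[ij] > score) { score = M[ij]; ej = j; emat = 0; }
      if (X[ij] > score) { score = X[ij]; ej = j; emat = 1; }
    }
  } else {
    const int ij = n * W + m;
    double best; signed char from;
    pick(M[ij], X[ij], Y[ij], best, from);
    score = best; emat = from;
  }

  // traceback
  int i = n, j = ej, mat = emat, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    signed char from;
    if (mat == 0) {
      if (i == 0) break; // semi-global start cell M[0][j] = 0
      from = tbM[ij];
      if (from < 0) break; // M[0][0]
      if (is_match(q[i - 1], r[j - 1])) ++matches;
      ++columns; --i; --j;
    } else if (mat == 1) {
      from = tbX[ij];
      ++columns; --i;
    } else {
      from = tbY[ij];
      ++columns; --j;
    }
    mat = from;
    if (i == 0 && j == 0) break;
  }
  return {score, matches, columns};
}

} // namespace

// [[Rcpp::export(name = ".align_batch")]]
DataFrame align_batch(std::string query, CharacterVector refs,
                      double match, double mismatch,
                      double gap_open, double gap_extend, bool semi,
                      int band_w = -1) {
  const int k = refs.size();
  NumericVector score(k);
  IntegerVector matches(k), columns(k);
  for (int t = 0; t < k; ++t) {
    const std::string r = as<std::string>(refs[t]);
    AlnResult res = align_pair(query, r, match, mismatch,
                               gap_open, gap_extend, semi, band_w);
    score[t] = res.score;
    matches[t] = res.matches;
    columns[t] = res.columns;
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["columns"] = columns);
}
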