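#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh affine-gap profile alignment over a precomputed column-pair score
// matrix M (n1 x n2 profile columns). gap_open/gap_extend are positive
// penalties; a gap of length k costs gap_open + k * gap_extend. Terminal
// gaps are free (semi-global), so truncated sequences align with clean
// overhangs rather than scattered internal gaps. Returns the alignment
// path as two integer vectors holding, per output column, the 1-based
// source column in each profile (0 = gap). Ties prefer the match state,
// then a gap in the second profile, for determinism.
// [[Rcpp::export]]
List nw_profile_path(NumericMatrix M, double gap_open, double gap_extend) {
  const int n1 = M.nrow(), n2 = M.ncol();
  const double NEG = -1e30;
  const int w = n2 + 1;
  std::vector<double> S((n1 + 1) * w, NEG), X((n1 + 1) * w, NEG),
      Y((n1 + 1) * w, NEG);
  // traceback: predecessor state 0=S, 1=X, 2=Y
  std::vector<signed char> tS((n1 + 1) * w, -1), tX((n1 + 1) * w, -1),
      tY((n1 + 1) * w, -1);
  S[0] = 0.0;
  for (int i = 1; i <= n1; ++i) {   // free leading gaps in profile 2
    X[i * w] = 0.0;
    tX[i * w] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n2; ++j) {   // free leading gaps in profile 1
    Y[j] = 0.0;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      const int c = i * w + j, up = (i - 1) * w + j, lf = i * w + j - 1,
                dg = (i - 1) * w + j - 1;
      // X: consume profile-1 column i against a gap
      double vs = S[up] - (gap_open + gap_extend);
      double vx = X[up] - gap_extend;
      double vy = Y[up] - (gap_open + gap_extend);
      if (vs >= vx && vs >= vy) { X[c] = vs; tX[c] = 0; }
      else if (vx >= vy)        { X[c] = vx; tX[c] = 1; }
      else                      { X[c] = vy; tX[c] = 2; }
      // Y: consume profile-2 column j against a gap
      vs = S[lf] - (gap_open + gap_extend);
      vx = X[lf] - (gap_open + gap_extend);
      vy = Y[lf] - gap_extend;
      if (vs >= vx && vs >= vy) { Y[c] = vs; tY[c] = 0; }
      else if (vx >= vy)        { Y[c] = vx; tY[c] = 1; }
      else                      { Y[c] = vy; tY[c] = 2; }
      // S: aligned column pair
      vs = S[dg]; vx = X[dg]; vy = Y[dg];
      double best; signed char tb;
      if (vs >= vx && vs >= vy) { best = vs; tb = 0; }
      else if (vx >= vy)        { best = vx; tb = 1; }
      else                      { best = vy; tb = 2; }
      S[c] = best + M(i - 1, j - 1);
      tS[c] = tb;
    }
  }
  // free trailing gaps: best over the last row and last column
  int bi = n1, bj = n2, state = 0;
  double best = NEG;
  for (int j = 0; j <= n2; ++j) {
    const int c = n1 * w + j;
    if (S[c] > best) { best = S[c]; bi = n1; bj = j; state = 0; }
    if (X[c] > best) { best = X[c]; bi = n1; bj = j; state = 1; }
    if (Y[c] > best) { best = Y[c]; bi = n1; bj = j; state = 2; }
  }
  for (int i = 0; i <= n1; ++i) {
    const int c = i * w + n2;
    if (S[c] > best) { best = S[c]; bi = i; bj = n2; state = 0; }
    if (X[c] > best) { best = X[c]; bi = i; bj = n2; state = 1; }
    if (Y[c] > best) { best = Y[c]; bi = i; bj = n2; state = 2; }
  }
  std::vector<int> pa, pb;
  // trailing unaligned columns (free gaps)
  for (int j = n2; j > bj; --j) { pa.push_back(0); pb.push_back(j); }
  for (int i = n1; i > bi; --i) { pa.push_back(i); pb.push_back(0); }
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    const int c = i * w + j;
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = tS[c]; --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = tX[c]; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = tY[c]; --j;
    }
  }
  const int L = pa.size();
  IntegerVector a(L), b(L);
  for (int k = 0; k < L; ++k) {
    a[k] = pa[L - 1 - k];
    b[k] = pb[L - 1 - k];
  }
  return List::create(_["a"] = a, _["b"] = b);
}
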