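#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion. A gap of length L costs open + extend*(L-1). Sequences arrive
// as 0-based indices into the substitution matrix. Ties are broken
// deterministically: diagonal (match state) first, then a gap in the second
// sequence, then a gap in the first.
//
// States: 0 = M (a_i ~ b_j), 1 = X (a_i ~ gap), 2 = Y (gap ~ b_j).

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - (i - 1) * gap_extend;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - (j - 1) * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M
      double best = M[d];
      signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      if (best > NEG / 2) {
        M[c] = best + sub(a[i - 1], b[j - 1]);
        tM[c] = arg;
      }
      // X: a_i against a gap (vertical move)
      best = M[u] - gap_open; arg = 0;
      if (X[u] - gap_extend > best) { best = X[u] - gap_extend; arg = 1; }
      if (Y[u] - gap_open > best) { best = Y[u] - gap_open; arg = 2; }
      if (best > NEG / 2) { X[c] = best; tX[c] = arg; }
      // Y: gap against b_j (horizontal move)
      best = M[l] - gap_open; arg = 0;
      if (Y[l] - gap_extend > best) { best = Y[l] - gap_extend; arg = 2; }
      if (X[l] - gap_open > best) { best = X[l] - gap_open; arg = 1; }
      if (best > NEG / 2) { Y[c] = best; tY[c] = arg; }
    }
  }
  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }
  // traceback
  std::vector<int> pa, pb;  // 1-based positions, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int c = i * W + j;
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = tX[c]; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = tY[c]; --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a_pos"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_pos"] = IntegerVector(pb.begin(), pb.end()));
}
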