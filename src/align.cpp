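#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh). A gap of length L costs
// open + L * ext. With end_gaps = false, terminal gap runs are free (EMBOSS
// needle default semantics). States: 0 = M (a_i aligned to b_j), 1 = X (gap
// in a, consuming b_j), 2 = Y (gap in b, consuming a_i). Ties prefer
// M > X > Y, giving a deterministic traceback; the score itself is
// tie-break-invariant.
// [[Rcpp::export]]
List affine_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix S,
                      double open, double ext, bool end_gaps) {
  const int n = ai.size(), m = bi.size();
  const double NEG = -1e30;
  const double c_open = open + ext; // cost of the first gap position
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> PM((n + 1) * (m + 1), -1);
  std::vector<signed char> PX((n + 1) * (m + 1), -1);
  std::vector<signed char> PY((n + 1) * (m + 1), -1);
  const int W = m + 1;
#define ID(i, j) ((i) * W + (j))
  M[ID(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[ID(0, j)] = end_gaps ? -(open + ext * j) : 0.0;
    PX[ID(0, j)] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    Y[ID(i, 0)] = end_gaps ? -(open + ext * i) : 0.0;
    PY[ID(i, 0)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(ai[i - 1], bi[j - 1]);
      // M
      double best = M[ID(i - 1, j - 1)];
      int st = 0;
      if (X[ID(i - 1, j - 1)] > best) { best = X[ID(i - 1, j - 1)]; st = 1; }
      if (Y[ID(i - 1, j - 1)] > best) { best = Y[ID(i - 1, j - 1)]; st = 2; }
      M[ID(i, j)] = best + s;
      PM[ID(i, j)] = (signed char)st;
      // X: gap in a, consuming b_j
      best = M[ID(i, j - 1)] - c_open; st = 0;
      if (X[ID(i, j - 1)] - ext > best) { best = X[ID(i, j - 1)] - ext; st = 1; }
      if (Y[ID(i, j - 1)] - c_open > best) { best = Y[ID(i, j - 1)] - c_open; st = 2; }
      X[ID(i, j)] = best;
      PX[ID(i, j)] = (signed char)st;
      // Y: gap in b, consuming a_i
      best = M[ID(i - 1, j)] - c_open; st = 0;
      if (X[ID(i - 1, j)] - c_open > best) { best = X[ID(i - 1, j)] - c_open; st = 1; }
      if (Y[ID(i - 1, j)] - ext > best) { best = Y[ID(i - 1, j)] - ext; st = 2; }
      Y[ID(i, j)] = best;
      PY[ID(i, j)] = (signed char)st;
    }
  }
  // pick the end cell; with free end gaps the alignment may end anywhere on
  // the last row/column, the remainder appended as a free terminal gap
  int ei = n, ej = m, estate = 0;
  double score;
  {
    double b0 = M[ID(n, m)]; int s0 = 0;
    if (X[ID(n, m)] > b0) { b0 = X[ID(n, m)]; s0 = 1; }
    if (Y[ID(n, m)] > b0) { b0 = Y[ID(n, m)]; s0 = 2; }
    score = b0; estate = s0;
    if (!end_gaps) {
      for (int i = n - 1; i >= 0; --i) { // trailing gap in b (a left over)
        double v = M[ID(i, m)]; int s = 0;
        if (X[ID(i, m)] > v) { v = X[ID(i, m)]; s = 1; }
        if (Y[ID(i, m)] > v) { v = Y[ID(i, m)]; s = 2; }
        if (v > score) { score = v; ei = i; ej = m; estate = s; }
      }
      for (int j = m - 1; j >= 0; --j) { // trailing gap in a (b left over)
        double v = M[ID(n, j)]; int s = 0;
        if (X[ID(n, j)] > v) { v = X[ID(n, j)]; s = 1; }
        if (Y[ID(n, j)] > v) { v = Y[ID(n, j)]; s = 2; }
        if (v > score) { score = v; ei = n; ej = j; estate = s; }
      }
    }
  }
  // traceback
  std::vector<int> opa, opb; // 0-based residue index or -1 for gap
  for (int i = n; i > ei; --i) { opa.push_back(i - 1); opb.push_back(-1); }
  for (int j = m; j > ej; --j) { opa.push_back(-1); opb.push_back(j - 1); }
  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      opa.push_back(i - 1); opb.push_back(j - 1);
      st = PM[ID(i, j)];
      --i; --j;
    } else if (st == 1) {
      opa.push_back(-1); opb.push_back(j - 1);
      st = PX[ID(i, j)];
      --j;
    } else {
      opa.push_back(i - 1); opb.push_back(-1);
      st = PY[ID(i, j)];
      --i;
    }
  }
  std::reverse(opa.begin(), opa.end());
  std::reverse(opb.begin(), opb.end());
  return List::create(_["score"] = score,
                      _["a_index"] = wrap(opa),
                      _["b_index"] = wrap(opb));
#undef ID
}
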