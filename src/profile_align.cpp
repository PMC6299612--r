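#include <Rcpp.h>
using namespace Rcpp;

// Ends-free global alignment of a residue sequence against a position
// weight profile (columns scored by per-column residue log-odds), with
// affine penalties for internal gaps. Terminal gaps on either side are
// free, so fragments and sequences with extra flanking domains map onto
// the profile region they actually cover.
//
// res: 0-based row indices into pssm for each record residue (-1 = unknown
//      residue, scored 0).
// pssm: nrow = residues, ncol = profile width.
// Returns the alignment score and, for every profile column, the 1-based
// record position aligned to it (NA when the column has no residue).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List profile_align_cpp(IntegerVector res, NumericMatrix pssm,
                       double gap_open, double gap_ext) {
  const int n = res.size();
  const int W = pssm.ncol();
  if (n == 0 || W == 0) stop("empty sequence or profile");

  // states: 1 = M (residue on column), 2 = X (column deleted),
  //         3 = Y (residue inserted)
  std::vector<double> M((n + 1) * (W + 1), NEG_INF);
  std::vector<double> X((n + 1) * (W + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (W + 1), NEG_INF);
  std::vector<signed char> pM((n + 1) * (W + 1), 0);
  std::vector<signed char> pX((n + 1) * (W + 1), 0);
  std::vector<signed char> pY((n + 1) * (W + 1), 0);
  auto at = [W](int i, int j) { return i * (W + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= W; ++j) X[at(0, j)] = 0.0;  // free leading deletions
  for (int i = 1; i <= n; ++i) Y[at(i, 0)] = 0.0;  // free leading insertions

  for (int i = 1; i <= n; ++i) {
    const int r = res[i - 1];
    for (int j = 1; j <= W; ++j) {
      const double s = (r >= 0) ? pssm(r, j - 1) : 0.0;
      const double m1 = M[at(i - 1, j - 1)], m2 = X[at(i - 1, j - 1)],
                   m3 = Y[at(i - 1, j - 1)];
      if (m1 >= m2 && m1 >= m3) { M[at(i, j)] = s + m1; pM[at(i, j)] = 1; }
      else if (m2 >= m3)        { M[at(i, j)] = s + m2; pM[at(i, j)] = 2; }
      else                      { M[at(i, j)] = s + m3; pM[at(i, j)] = 3; }

      const double x1 = M[at(i, j - 1)] - (gap_open + gap_ext);
      const double x2 = X[at(i, j - 1)] - gap_ext;
      const double x3 = Y[at(i, j - 1)] - (gap_open + gap_ext);
      if (x1 >= x2 && x1 >= x3) { X[at(i, j)] = x1; pX[at(i, j)] = 1; }
      else if (x2 >= x3)        { X[at(i, j)] = x2; pX[at(i, j)] = 2; }
      else                      { X[at(i, j)] = x3; pX[at(i, j)] = 3; }

      const double y1 = M[at(i - 1, j)] - (gap_open + gap_ext);
      const double y2 = Y[at(i - 1, j)] - gap_ext;
      const double y3 = X[at(i - 1, j)] - (gap_open + gap_ext);
      // pointer codes use the state convention (1 = M, 2 = X, 3 = Y):
      // y2 extends Y, y3 closes an X gap
      if (y1 >= y2 && y1 >= y3) { Y[at(i, j)] = y1; pY[at(i, j)] = 1; }
      else if (y2 >= y3)        { Y[at(i, j)] = y2; pY[at(i, j)] = 3; }
      else                      { Y[at(i, j)] = y3; pY[at(i, j)] = 2; }
    }
  }

  // best end cell: trailing gaps on either side are free
  double best = NEG_INF;
  int bi = n, bj = W, bs = 1;
  for (int i = 0; i <= n; ++i) {
    const double c[3] = { M[at(i, W)], X[at(i, W)], Y[at(i, W)] };
    for (int s = 0; s < 3; ++s)
      if (c[s] > best) { best = c[s]; bi = i; bj = W; bs = s + 1; }
  }
  for (int j = 0; j <= W; ++j) {
    const double c[3] = { M[at(n, j)], X[at(n, j)], Y[at(n, j)] };
    for (int s = 0; s < 3; ++s)
      if (c[s] > best) { best = c[s]; bi = n; bj = j; bs = s + 1; }
  }

  IntegerVector colmap(W, NA_INTEGER);
  int i = bi, j = bj, state = bs;
  while (!(i == 0 && j == 0)) {
    int prev;
    if (state == 1) {
      colmap[j - 1] = i;
      prev = pM[at(i, j)];
      --i; --j;
    } else if (state == 2) {
      prev = pX[at(i, j)];
      --j;
    } else {
      prev = pY[at(i, j)];
      --i;
    }
    if (prev == 0) break;                 // reached an origin cell
    state = prev;
    if (state == 2 && i == 0) break;      // free leading deletions remain
    if (state == 3 && j == 0) break;      // free leading insertions remain
  }

  return List::create(_["score"] = best, _["colmap"] = colmap);
}
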