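#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP) over a precomputed
// column-score matrix, so the same kernel serves residue-vs-residue and
// profile-vs-profile alignment.  A gap of length k costs
// gap_open + k * gap_ext (the opening column is charged both terms), and
// terminal gaps are penalized like internal ones.  Ties prefer the match
// state, then gap-in-A (consume a B column), then gap-in-B, both for the
// final cell and for every predecessor, which makes the traceback fully
// deterministic.
//
// moves: 1 = aligned column, 2 = gap in A (B column emitted alone),
//        3 = gap in B (A column emitted alone).
// [[Rcpp::export]]
List C_gotoh(NumericMatrix colscore, double gap_open, double gap_ext) {
  const int n = colscore.nrow(), m = colscore.ncol();
  const double NEG = -1e30;
  const double go = gap_open + gap_ext;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Y(0, j) = NEG;
    X(0, j) = -(gap_open + j * gap_ext);
    pX(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; X(i, 0) = NEG;
    Y(i, 0) = -(gap_open + i * gap_ext);
    pY(i, 0) = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double bm = M(i - 1, j - 1); int am = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); am = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); am = 2; }
      M(i, j) = bm + colscore(i - 1, j - 1); pM(i, j) = am;

      double bx = M(i, j - 1) - go; int ax = 0;
      if (X(i, j - 1) - gap_ext > bx) { bx = X(i, j - 1) - gap_ext; ax = 1; }
      if (Y(i, j - 1) - go     > bx) { bx = Y(i, j - 1) - go;      ax = 2; }
      X(i, j) = bx; pX(i, j) = ax;

      double by = M(i - 1, j) - go; int ay = 0;
      if (X(i - 1, j) - go      > by) { by = X(i - 1, j) - go;      ay = 1; }
      if (Y(i - 1, j) - gap_ext > by) { by = Y(i - 1, j) - gap_ext; ay = 2; }
      Y(i, j) = by; pY(i, j) = ay;
    }
  }

  int st = 0; double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); st = 1; }
  if (Y(n, m) > best) { best = Y(n, m); st = 2; }

  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0)      { moves.push_back(1); st = pM(i, j); --i; --j; }
    else if (st == 1) { moves.push_back(2); st = pX(i, j); --j; }
    else              { moves.push_back(3); st = pY(i, j); --i; }
  }
  std::reverse(moves.begin(), moves.end());

  return List::create(_["score"] = best,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
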