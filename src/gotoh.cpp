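#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed column-score
// matrix C (n1 x n2). A gap of length L costs open + L * ext, charged from
// its first residue. Returns the traceback as a vector of moves from the
// start of the alignment: 1 = diagonal, 2 = up (consume row of the first
// profile), 3 = left (consume column of the second profile), with the total
// score as attribute "score". Ties resolve diagonal > up > left.
// [[Rcpp::export(name = ".gotoh_global")]]
IntegerVector gotoh_global(NumericMatrix C, double open, double ext) {
  const int n1 = C.nrow(), n2 = C.ncol();
  const double NEG = -1e30;
  const double gfirst = open + ext;

  std::vector<double> M((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> X((n1 + 1) * (n2 + 1), NEG); // gap in profile 2 (up)
  std::vector<double> Y((n1 + 1) * (n2 + 1), NEG); // gap in profile 1 (left)
  std::vector<unsigned char> pM((n1 + 1) * (n2 + 1), 0);
  std::vector<unsigned char> pX((n1 + 1) * (n2 + 1), 0);
  std::vector<unsigned char> pY((n1 + 1) * (n2 + 1), 0);
  const int W = n2 + 1;
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n1; ++i) {
    X[at(i, 0)] = -(open + i * ext);
    pX[at(i, 0)] = (i == 1) ? 1 : 2; // 1: came from M, 2: from X
  }
  for (int j = 1; j <= n2; ++j) {
    Y[at(0, j)] = -(open + j * ext);
    pY[at(0, j)] = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      // M: diagonal move ending in (i, j)
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double best = dM; unsigned char who = 1;
      if (dX > best) { best = dX; who = 2; }
      if (dY > best) { best = dY; who = 3; }
      M[at(i, j)] = best + C(i - 1, j - 1);
      pM[at(i, j)] = who;

      // X: gap in profile 2, consuming row i
      double oM = M[at(i - 1, j)] - gfirst;
      double oX = X[at(i - 1, j)] - ext;
      double oY = Y[at(i - 1, j)] - gfirst;
      best = oM; who = 1;
      if (oX > best) { best = oX; who = 2; }
      if (oY > best) { best = oY; who = 3; }
      X[at(i, j)] = best; pX[at(i, j)] = who;

      // Y: gap in profile 1, consuming column j
      double lM = M[at(i, j - 1)] - gfirst;
      double lY = Y[at(i, j - 1)] - ext;
      double lX = X[at(i, j - 1)] - gfirst;
      best = lM; who = 1;
      if (lX > best) { best = lX; who = 2; }
      if (lY > best) { best = lY; who = 3; }
      Y[at(i, j)] = best; pY[at(i, j)] = who;
    }
  }

  double sM = M[at(n1, n2)], sX = X[at(n1, n2)], sY = Y[at(n1, n2)];
  double score = sM; int state = 1;
  if (sX > score) { score = sX; state = 2; }
  if (sY > score) { score = sY; state = 3; }

  std::vector<int> moves;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (state == 1) {
      int prev = pM[at(i, j)];
      moves.push_back(1);
      --i; --j;
      state = prev;
    } else if (state == 2) {
      int prev = pX[at(i, j)];
      moves.push_back(2);
      --i;
      state = prev;
    } else {
      int prev = pY[at(i, j)];
      moves.push_back(3);
      --j;
      state = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());
  IntegerVector out(moves.begin(), moves.end());
  out.attr("score") = score;
  return out;
}
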