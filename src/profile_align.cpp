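#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Profile-profile global alignment with affine gaps and free terminal gaps
// (Gotoh three-state recursion). Profiles are 6 x L count matrices over the
// state order A, C, G, T, N, '-'. N and '-' are scored 0 against everything;
// substitution score between observed bases is match/mismatch weighted by
// column base frequencies. Free terminal gaps are what lets 5'/3'-truncated
// copies sit flush inside a longer profile instead of paying -500 per end.
//
// Returns list(ops, score); ops walks both profiles left to right:
//   1 = advance both, 2 = advance A only (gap column added to B),
//   3 = advance B only (gap column added to A).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double col_score(const double* a, const double* b,
                               double na, double nb,
                               double match, double mismatch) {
  double s = 0.0;
  for (int x = 0; x < 4; ++x) {
    if (a[x] == 0) continue;
    for (int y = 0; y < 4; ++y) {
      if (b[y] == 0) continue;
      s += a[x] * b[y] * (x == y ? match : mismatch);
    }
  }
  return s / (na * nb);
}

// [[Rcpp::export]]
List c_profile_align(NumericMatrix profA, NumericMatrix profB,
                      double match, double mismatch,
                      double gapOpen, double gapExtend) {
  const int La = profA.ncol(), Lb = profB.ncol();
  if (profA.nrow() != 6 || profB.nrow() != 6)
    stop("profiles must have 6 rows (A,C,G,T,N,-)");
  double na = 0.0, nb = 0.0;
  for (int k = 0; k < 6; ++k) { na += profA(k, 0); nb += profB(k, 0); }
  if (na <= 0 || nb <= 0) stop("empty profile");

  const size_t W = (size_t)(Lb + 1);
  std::vector<double> Mprev(W), Xprev(W), Yprev(W), Mcur(W), Xcur(W), Ycur(W);
  std::vector<unsigned char> tbM((size_t)(La + 1) * W),
      tbX((size_t)(La + 1) * W), tbY((size_t)(La + 1) * W);
  // last column (j = Lb) scores per row for each layer
  std::vector<double> lcM(La + 1, NEG_INF), lcX(La + 1, NEG_INF),
      lcY(La + 1, NEG_INF);

  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = 0.0;
  for (int j = 1; j <= Lb; ++j) {
    Mprev[j] = NEG_INF; Xprev[j] = NEG_INF; Yprev[j] = 0.0;
    tbY[j] = 1;
  }
  lcM[0] = Mprev[Lb]; lcX[0] = Xprev[Lb]; lcY[0] = Yprev[Lb];

  for (int i = 1; i <= La; ++i) {
    const double* ai = &profA(0, i - 1);
    Mcur[0] = NEG_INF; Ycur[0] = NEG_INF; Xcur[0] = 0.0;
    tbX[(size_t)i * W] = 1;
    for (int j = 1; j <= Lb; ++j) {
      const double* bj = &profB(0, j - 1);
      double d0 = Mprev[j - 1], d1 = Xprev[j - 1], d2 = Yprev[j - 1];
      unsigned char tm = 0; double best = d0;
      if (d1 > best) { best = d1; tm = 1; }
      if (d2 > best) { best = d2; tm = 2; }
      Mcur[j] = best + col_score(ai, bj, na, nb, match, mismatch);
      tbM[(size_t)i * W + j] = tm;
      double xo = Mprev[j] + gapOpen, xe = Xprev[j] + gapExtend,
             xy = Yprev[j] + gapOpen;
      unsigned char tx = 0; double bx = xo;
      if (xe > bx) { bx = xe; tx = 1; }
      if (xy > bx) { bx = xy; tx = 2; }
      Xcur[j] = bx; tbX[(size_t)i * W + j] = tx;
      double yo = Mcur[j - 1] + gapOpen, ye = Ycur[j - 1] + gapExtend,
             yx = Xcur[j - 1] + gapOpen;
      unsigned char ty = 0; double by = yo;
      if (ye > by) { by = ye; ty = 1; }
      if (yx > by) { by = yx; ty = 2; }
      Ycur[j] = by; tbY[(size_t)i * W + j] = ty;
    }
    lcM[i] = Mcur[Lb]; lcX[i] = Xcur[Lb]; lcY[i] = Ycur[Lb];
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // choose end point: free trailing gaps.
  // candidates: last row (i = La, any j; pad B... i.e. remaining of B gets
  // op 3 against gap) and last column (j = Lb, any i; remaining of A -> op 2).
  double bestScore = NEG_INF; int ei = La, ej = Lb, elayer = 0;
  for (int j = 0; j <= Lb; ++j) {
    double m = Mprev[j], x = Xprev[j], y = Yprev[j];
    if (m > bestScore) { bestScore = m; ei = La; ej = j; elayer = 0; }
    if (x > bestScore) { bestScore = x; ei = La; ej = j; elayer = 1; }
    if (y > bestScore) { bestScore = y; ei = La; ej = j; elayer = 2; }
  }
  for (int i = 0; i <= La; ++i) {
    double m = lcM[i], x = lcX[i], y = lcY[i];
    if (m > bestScore) { bestScore = m; ei = i; ej = Lb; elayer = 0; }
    if (x > bestScore) { bestScore = x; ei = i; ej = Lb; elayer = 1; }
    if (y > bestScore) { bestScore = y; ei = i; ej = Lb; elayer = 2; }
  }

  std::vector<int> ops;
  ops.reserve((size_t)La + Lb);
  // pad the unconsumed tails (free trailing gaps)
  for (int i = La; i > ei; --i) ops.push_back(2);
  for (int j = Lb; j > ej; --j) ops.push_back(3);

  int i = ei, j = ej, layer = elayer;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(3); --j; continue; }
    if (j == 0) { ops.push_back(2); --i; continue; }
    if (layer == 0) {
      unsigned char t = tbM[(size_t)i * W + j];
      ops.push_back(1); --i; --j; layer = t;
    } else if (layer == 1) {
      unsigned char t = tbX[(size_t)i * W + j];
      ops.push_back(2); --i;
      layer = (t == 0) ? 0 : (t == 1 ? 1 : 2);
    } else {
      unsigned char t = tbY[(size_t)i * W + j];
      ops.push_back(3); --j;
      layer = (t == 0) ? 0 : (t == 1 ? 2 : 1);
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = bestScore);
}
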