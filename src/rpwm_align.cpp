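#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap alignment of an encoded window S (codes 1..4) against the
// tandem-extended profile: the profile axis has the same length as the
// window and column j of the grid reads weight-matrix column ((j-1) mod n)+1.
// Recurrences:
//   F(i,j)  = q(s(i), s2(j)) + max{ F, Fx, Fy }(i-1, j-1)
//   Fx(i,j) = max{ F(i-1,j) - d, Fx(i-1,j) - e }   (gap in the profile)
//   Fy(i,j) = max{ F(i,j-1) - d, Fy(i,j-1) - e }   (gap in the window)
// Boundaries: F(0,.) = F(.,0) = 0, Fx/Fy boundaries = -Inf.  The score is
// the maximum of F over the far boundaries F(L,j) and F(i,L) only; there is
// no max(0, .) inside the recursion.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double max3(double a, double b, double c) {
  double m = a > b ? a : b;
  return m > c ? m : c;
}

// [[Rcpp::export(name = ".dpScore")]]
double dpScore(IntegerVector s, NumericMatrix w, double d, double e) {
  const int L = s.size();
  const int n = w.ncol();
  const double *W = REAL(w);  // 4 x n, column-major
  const int *sp = INTEGER(s);
  // precompute the q row of every base over the tandem-extended profile
  std::vector<double> qtab((size_t)4 * L);
  for (int c = 0; c < 4; ++c) {
    double *row = &qtab[(size_t)c * L];
    for (int j = 0; j < L; ++j) row[j] = W[c + 4 * (j % n)];
  }

  std::vector<double> prevF(L + 1, 0.0), prevFx(L + 1, NEG_INF),
      prevFy(L + 1, NEG_INF);
  std::vector<double> curF(L + 1), curFx(L + 1), curFy(L + 1);
  // the far-boundary corners F(L,0) and F(0,L) are boundary zeros, so the
  // empty alignment (score 0) is always admissible
  double best = 0.0;

  for (int i = 1; i <= L; ++i) {
    double *cF = curF.data(), *cFx = curFx.data(), *cFy = curFy.data();
    const double *pF = prevF.data(), *pFx = prevFx.data(),
                 *pFy = prevFy.data();
    cF[0] = 0.0;
    cFx[0] = NEG_INF;
    cFy[0] = NEG_INF;
    const double *qrow = &qtab[(size_t)(sp[i - 1] - 1) * L];
    double fyPrev = NEG_INF;  // curFy[j-1]
    double fPrev = 0.0;       // curF[j-1]
    for (int j = 1; j <= L; ++j) {
      double fx = pF[j] - d, fx2 = pFx[j] - e;
      double vFx = fx > fx2 ? fx : fx2;
      double fy = fPrev - d, fy2 = fyPrev - e;
      double vFy = fy > fy2 ? fy : fy2;
      double vF = qrow[j - 1] + max3(pF[j - 1], pFx[j - 1], pFy[j - 1]);
      cFx[j] = vFx;
      cFy[j] = vFy;
      cF[j] = vF;
      fyPrev = vFy;
      fPrev = vF;
    }
    if (cF[L] > best) best = cF[L];
    std::swap(prevF, curF);
    std::swap(prevFx, curFx);
    std::swap(prevFy, curFy);
  }
  // last row: F(L, j), j = 1..L  (prevF now holds row L)
  for (int j = 1; j <= L; ++j)
    if (prevF[j] > best) best = prevF[j];
  return best;
}

// Full matrices with back pointers; returns the optimal path.
// States: 0 = F (match), 1 = Fx (gap in profile), 2 = Fy (gap in window).
// [[Rcpp::export(name = ".dpTraceback")]]
List dpTraceback(IntegerVector s, NumericMatrix w, double d, double e) {
  const int L = s.size();
  const int n = w.ncol();
  const size_t sz = (size_t)(L + 1) * (L + 1);
  std::vector<double> F(sz), Fx(sz), Fy(sz);
  std::vector<signed char> bF(sz), bFx(sz), bFy(sz);
  auto at = [L](int i, int j) { return (size_t)i * (L + 1) + j; };

  for (int j = 0; j <= L; ++j) {
    F[at(0, j)] = 0.0;
    Fx[at(0, j)] = NEG_INF;
    Fy[at(0, j)] = NEG_INF;
  }
  for (int i = 1; i <= L; ++i) {
    F[at(i, 0)] = 0.0;
    Fx[at(i, 0)] = NEG_INF;
    Fy[at(i, 0)] = NEG_INF;
  }

  for (int i = 1; i <= L; ++i) {
    const int code = s[i - 1] - 1;
    for (int j = 1; j <= L; ++j) {
      const double q = w(code, (j - 1) % n);
      const size_t up = at(i - 1, j), left = at(i, j - 1),
                   diag = at(i - 1, j - 1), cur = at(i, j);
      double open = F[up] - d, ext = Fx[up] - e;
      if (open >= ext) { Fx[cur] = open; bFx[cur] = 0; }
      else             { Fx[cur] = ext;  bFx[cur] = 1; }
      open = F[left] - d; ext = Fy[left] - e;
      if (open >= ext) { Fy[cur] = open; bFy[cur] = 0; }
      else             { Fy[cur] = ext;  bFy[cur] = 2; }
      // tie preference: diagonal (F) > vertical (Fx) > horizontal (Fy)
      double bestv = F[diag]; signed char bs = 0;
      if (Fx[diag] > bestv) { bestv = Fx[diag]; bs = 1; }
      if (Fy[diag] > bestv) { bestv = Fy[diag]; bs = 2; }
      F[cur] = q + bestv;
      bF[cur] = bs;
    }
  }

  // terminal: best F on the far boundaries (empty alignment score 0 is
  // admissible through the boundary corners), tie -> smallest coordinate
  double fmax = 0.0;
  int ti = 0, tj = 0;
  for (int i = 1; i <= L; ++i) {
    if (F[at(i, L)] > fmax) { fmax = F[at(i, L)]; ti = i; tj = L; }
  }
  for (int j = 1; j <= L; ++j) {
    if (F[at(L, j)] > fmax) { fmax = F[at(L, j)]; ti = L; tj = j; }
  }

  // walk back from (ti,tj) in state F until a cell with F == 0 is reached
  std::vector<int> si, sj;  // window pos (0 = gap), profile grid pos (0 = gap)
  int i = ti, j = tj, state = 0;
  while (!(i == 0 && j == 0)) {
    if (state == 0) {
      if (F[at(i, j)] == 0.0) break;  // alignment start (boundary or interior)
      si.push_back(i); sj.push_back(j);
      state = bF[at(i, j)];
      --i; --j;
    } else if (state == 1) {       // gap in profile: consumes window base
      si.push_back(i); sj.push_back(0);
      state = bFx[at(i, j)];
      --i;
    } else {                       // gap in window: consumes profile position
      si.push_back(0); sj.push_back(j);
      state = bFy[at(i, j)];
      --j;
    }
  }
  std::reverse(si.begin(), si.end());
  std::reverse(sj.begin(), sj.end());

  int i0 = 0, im = 0;
  for (size_t k = 0; k < si.size(); ++k)
    if (si[k] > 0) { if (i0 == 0) i0 = si[k]; im = si[k]; }
  int j0 = 0, jm = 0;
  for (size_t k = 0; k < sj.size(); ++k)
    if (sj[k] > 0) { if (j0 == 0) j0 = sj[k]; jm = sj[k]; }

  IntegerMatrix pairs(si.size(), 2);
  for (size_t k = 0; k < si.size(); ++k) {
    pairs(k, 0) = si[k];
    pairs(k, 1) = sj[k];
  }
  colnames(pairs) = CharacterVector::create("window", "grid");
  return List::create(_["fmax"] = fmax, _["i0"] = i0, _["im"] = im,
                      _["j0"] = j0, _["jm"] = jm, _["pairs"] = pairs);
}

// Exhaustive enumeration oracle: tries every monotone affine-gap path that
// starts with a match step off the zero boundary and ends in the match state
// on a far boundary (i == L or j == L).  Recursive, no memoization --
// deliberately independent of the DP above.  Guarded to tiny L in R.
struct BF {
  const int *s;
  int L, n;
  const double *w;  // 4 x n, column-major
  double d, e, best;
  void go(int i, int j, int state, double sc) {
    if (state == 0 && (i == L || j == L) && sc > best) best = sc;
    if (i == L && j == L) return;
    // match step: consumes (i+1, j+1), allowed from any state
    if (i < L && j < L) {
      double q = w[(s[i] - 1) + 4 * (j % n)];
      go(i + 1, j + 1, 0, sc + q);
    }
    // gap in profile (advance i): open from match, extend from state 1
    if (i < L) {
      if (state == 0) go(i + 1, j, 1, sc - d);
      else if (state == 1) go(i + 1, j, 1, sc - e);
    }
    // gap in window (advance j): open from match, extend from state 2
    if (j < L) {
      if (state == 0) go(i, j + 1, 2, sc - d);
      else if (state == 2) go(i, j + 1, 2, sc - e);
    }
  }
};

// [[Rcpp::export(name = ".bruteForceScore")]]
double bruteForceScore(IntegerVector s, NumericMatrix w, double d, double e) {
  BF bf;
  bf.s = INTEGER(s);
  bf.L = s.size();
  bf.n = w.ncol();
  bf.w = REAL(w);
  bf.d = d;
  bf.e = e;
  bf.best = 0.0;  // empty alignment is admissible, as in the DP
  // start anywhere on the zero boundary: (i, 0) or (0, j); state 0 score 0.
  // Enumerating from every (i,0) and (0,j) start; go() itself requires the
  // first consuming step, which from state 0 may be a match or a gap open,
  // but a path of only gaps can never end in state 0 with a match, so its
  // terminal is never recorded unless a match occurs later via state 0 --
  // gap states rejoin only through the diagonal step, as in the DP.
  for (int i = 0; i <= bf.L; ++i) bf.go(i, 0, 0, 0.0);
  for (int j = 1; j <= bf.L; ++j) bf.go(0, j, 0, 0.0);
  // the empty alignment scores 0 only if it ends on a far boundary in state F;
  // starting at (i, 0) with i == L or (0, L) gives F == 0 there.
  return bf.best;
}
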