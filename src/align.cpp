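#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh). A gap of length L costs open + ext * L.
// Deterministic traceback priority: match/mismatch > gap-in-b > gap-in-a,
// where "gap-in-b" consumes a residue of `a` (X state) and "gap-in-a"
// consumes a residue of `b` (Y state). Predecessor states are recorded at
// fill time, so the traceback is O(n + m) and unambiguous.

static const double NEG_INF = -1e300;

struct GotohDP {
  int n, m;
  std::vector<double> M, X, Y;      // row-major (n+1) x (m+1)
  std::vector<unsigned char> tbM, tbX, tbY;  // predecessor state 0/1/2
  double score;
  int final_state;

  GotohDP(int n_, int m_) : n(n_), m(m_) {
    size_t sz = (size_t)(n + 1) * (m + 1);
    M.assign(sz, NEG_INF); X.assign(sz, NEG_INF); Y.assign(sz, NEG_INF);
    tbM.assign(sz, 0); tbX.assign(sz, 0); tbY.assign(sz, 0);
  }

  inline size_t at(int i, int j) const { return (size_t)i * (m + 1) + j; }

  // scores(i-1, j-1) must return the column score for a_i vs b_j
  template <typename ScoreFun>
  void fill(ScoreFun scores, double gap_open, double gap_ext) {
    const double gi = gap_open + gap_ext, ge = gap_ext;
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) { X[at(i, 0)] = -(gap_open + gap_ext * i); tbX[at(i, 0)] = 1; }
    for (int j = 1; j <= m; ++j) { Y[at(0, j)] = -(gap_open + gap_ext * j); tbY[at(0, j)] = 2; }
    for (int i = 1; i <= n; ++i) {
      const size_t row = at(i, 0), prow = at(i - 1, 0);
      for (int j = 1; j <= m; ++j) {
        // M: diagonal, priority M > X > Y
        double dm = M[prow + j - 1], dx = X[prow + j - 1], dy = Y[prow + j - 1];
        double best = dm; unsigned char tb = 0;
        if (dx > best) { best = dx; tb = 1; }
        if (dy > best) { best = dy; tb = 2; }
        M[row + j] = best + scores(i - 1, j - 1);
        tbM[row + j] = tb;
        // X: consume a_i (gap in b)
        double xm = M[prow + j] - gi, xx = X[prow + j] - ge, xy = Y[prow + j] - gi;
        best = xm; tb = 0;
        if (xx > best) { best = xx; tb = 1; }
        if (xy > best) { best = xy; tb = 2; }
        X[row + j] = best; tbX[row + j] = tb;
        // Y: consume b_j (gap in a)
        double ym = M[row + j - 1] - gi, yx = X[row + j - 1] - gi, yy = Y[row + j - 1] - ge;
        best = ym; tb = 0;
        if (yx > best) { best = yx; tb = 1; }
        if (yy > best) { best = yy; tb = 2; }
        Y[row + j] = best; tbY[row + j] = tb;
      }
    }
    score = M[at(n, m)]; final_state = 0;
    if (X[at(n, m)] > score) { score = X[at(n, m)]; final_state = 1; }
    if (Y[at(n, m)] > score) { score = Y[at(n, m)]; final_state = 2; }
  }

  List traceback() const {
    std::vector<int> ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = n, j = m, state = final_state;
    while (i > 0 || j > 0) {
      if (state == 0) {
        state = tbM[at(i, j)];
        ra.push_back(i - 1); rb.push_back(j - 1);
        --i; --j;
      } else if (state == 1) {
        state = tbX[at(i, j)];
        ra.push_back(i - 1); rb.push_back(-1);
        --i;
      } else {
        state = tbY[at(i, j)];
        ra.push_back(-1); rb.push_back(j - 1);
        --j;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["a_idx"] = wrap(ra), _["b_idx"] = wrap(rb),
                        _["score"] = score);
  }
};

// [[Rcpp::export]]
List cpp_nw_pair(IntegerVector a, IntegerVector b, NumericMatrix S,
                 double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  // flat copy of the score matrix for cheap lookup
  std::vector<double> Sf(400);
  for (int x = 0; x < 20; ++x)
    for (int y = 0; y < 20; ++y) Sf[x * 20 + y] = S(x, y);
  const int* ap = INTEGER(a);
  const int* bp = INTEGER(b);
  GotohDP dp(n, m);
  dp.fill([&](int i, int j) { return Sf[ap[i] * 20 + bp[j]]; },
          gap_open, gap_ext);
  return dp.traceback();
}

// Profile-profile alignment. Profiles are 20 x L column frequency matrices
// (residue frequencies scaled by column occupancy). Column score = f1' S f2;
// gap fractions contribute zero.

// [[Rcpp::export]]
List cpp_nw_profile(NumericMatrix p1, NumericMatrix p2, NumericMatrix S,
                    double gap_open, double gap_ext) {
  const int n = p1.ncol(), m = p2.ncol();
  // CS[i, j] = p1[, i]' S p2[, j], computed via T = S' p1 (20 x n)
  std::vector<double> T((size_t)20 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int bres = 0; bres < 20; ++bres) {
      double acc = 0.0;
      for (int ares = 0; ares < 20; ++ares) acc += p1(ares, i) * S(ares, bres);
      T[(size_t)i * 20 + bres] = acc;
    }
  std::vector<double> CS((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    const double* ti = &T[(size_t)i * 20];
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int bres = 0; bres < 20; ++bres) acc += ti[bres] * p2(bres, j);
      CS[(size_t)i * m + j] = acc;
    }
  }
  GotohDP dp(n, m);
  dp.fill([&](int i, int j) { return CS[(size_t)i * m + j]; },
          gap_open, gap_ext);
  return dp.traceback();
}
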