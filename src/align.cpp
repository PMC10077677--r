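// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// Gap cost contract: a gap of length L costs gap_open + L * gap_extend.
// In global mode end gaps are penalized; in glocal mode the leading and
// trailing unaligned flanks of the *second* sequence (the long target
// window) are free, while the first sequence (the query) is aligned
// end-to-end. Substitution scores are match/mismatch only; 'N' scores as a
// mismatch against everything (including 'N').
//
// Traceback preference on ties: diagonal > up (gap in b) > left (gap in a).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subscore(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// Linear-memory glocal pass: free leading/trailing gaps in b. Alignment
// start positions are propagated through the DP alongside the scores, so a
// single forward pass returns the best score and the 0-based start / 1-based
// end columns (j_start, j_end) of the aligned core in b.
// [[Rcpp::export(name = ".glocal_locate")]]
List glocal_locate(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  int la = a.size(), lb = b.size();
  double open_cost = gap_open + gap_extend;
  if (la == 0)
    return List::create(_["score"] = 0.0, _["j_start"] = 0, _["j_end"] = 0);
  std::vector<double> M(lb + 1), Ia(lb + 1), Ib(lb + 1);
  std::vector<double> Mp(lb + 1), Iap(lb + 1), Ibp(lb + 1);
  std::vector<int> sM(lb + 1), sIa(lb + 1), sIb(lb + 1);
  std::vector<int> sMp(lb + 1), sIap(lb + 1), sIbp(lb + 1);
  // row i = 0: free leading flank of b; an alignment entered at column j
  // starts at j (0-based offset into b)
  for (int j = 0; j <= lb; ++j) {
    Mp[j] = 0.0; Iap[j] = NEG_INF; Ibp[j] = NEG_INF;
    sMp[j] = j; sIap[j] = j; sIbp[j] = j;
  }
  for (int i = 1; i <= la; ++i) {
    M[0] = NEG_INF; sM[0] = 0;
    Ia[0] = NEG_INF; sIa[0] = 0;
    Ib[0] = -(gap_open + i * gap_extend); sIb[0] = 0;
    for (int j = 1; j <= lb; ++j) {
      // M from best diagonal predecessor (preference M > Ib > Ia)
      double bm = Mp[j - 1]; int sm = sMp[j - 1];
      if (Ibp[j - 1] > bm) { bm = Ibp[j - 1]; sm = sIbp[j - 1]; }
      if (Iap[j - 1] > bm) { bm = Iap[j - 1]; sm = sIap[j - 1]; }
      M[j] = bm + subscore(a[i - 1], b[j - 1], match, mismatch);
      sM[j] = sm;
      // Ib: gap in b (consumes a[i-1])
      double vb = Mp[j] - open_cost; int sb = sMp[j];
      if (Ibp[j] - gap_extend > vb) { vb = Ibp[j] - gap_extend; sb = sIbp[j]; }
      if (Iap[j] - open_cost > vb) { vb = Iap[j] - open_cost; sb = sIap[j]; }
      Ib[j] = vb; sIb[j] = sb;
      // Ia: gap in a (consumes b[j-1])
      double va = M[j - 1] - open_cost; int sa = sM[j - 1];
      if (Ib[j - 1] - open_cost > va) { va = Ib[j - 1] - open_cost; sa = sIb[j - 1]; }
      if (Ia[j - 1] - gap_extend > va) { va = Ia[j - 1] - gap_extend; sa = sIa[j - 1]; }
      Ia[j] = va; sIa[j] = sa;
    }
    std::swap(M, Mp); std::swap(Ia, Iap); std::swap(Ib, Ibp);
    std::swap(sM, sMp); std::swap(sIa, sIap); std::swap(sIb, sIbp);
  }
  // free trailing flank of b: best over columns of the last row
  double best = NEG_INF; int jbest = 0, sbest = 0;
  for (int j = 0; j <= lb; ++j) {
    double v = Mp[j]; int s = sMp[j];
    if (Ibp[j] > v) { v = Ibp[j]; s = sIbp[j]; }
    if (Iap[j] > v) { v = Iap[j]; s = sIap[j]; }
    if (v > best) { best = v; jbest = j; sbest = s; }
  }
  return List::create(_["score"] = best, _["j_start"] = sbest,
                      _["j_end"] = jbest);
}

// Full global alignment with traceback (end gaps penalized).
// [[Rcpp::export(name = ".nw_global")]]
List nw_global(std::string a, std::string b,
               double match, double mismatch,
               double gap_open, double gap_extend) {
  int la = a.size(), lb = b.size();
  double open_cost = gap_open + gap_extend;
  if (la == 0 && lb == 0)
    return List::create(_["score"] = 0.0, _["aligned_a"] = "",
                        _["aligned_b"] = "");
  if (la == 0)
    return List::create(_["score"] = -(gap_open + lb * gap_extend),
                        _["aligned_a"] = std::string(lb, '-'),
                        _["aligned_b"] = b);
  if (lb == 0)
    return List::create(_["score"] = -(gap_open + la * gap_extend),
                        _["aligned_a"] = a,
                        _["aligned_b"] = std::string(la, '-'));
  double cells = (double)(la + 1) * (double)(lb + 1);
  if (cells > 3e8)
    stop("sequences too long for exact traceback DP; use the glocal mapper");

  size_t ncell = (size_t)(la + 1) * (size_t)(lb + 1);
  std::vector<double> M(ncell, NEG_INF), Ia(ncell, NEG_INF), Ib(ncell, NEG_INF);
  // traceback: for each state, which predecessor state fed it (0=M,1=Ib,2=Ia)
  std::vector<unsigned char> tM(ncell), tIb(ncell), tIa(ncell);
  auto idx = [lb](int i, int j) { return (size_t)i * (size_t)(lb + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= lb; ++j) {
    Ia[idx(0, j)] = -(gap_open + j * gap_extend);
    tIa[idx(0, j)] = 2;
  }
  for (int i = 1; i <= la; ++i) {
    Ib[idx(i, 0)] = -(gap_open + i * gap_extend);
    tIb[idx(i, 0)] = 1;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      size_t c = idx(i, j), d = idx(i - 1, j - 1), u = idx(i - 1, j),
             l = idx(i, j - 1);
      // M: preference M > Ib > Ia on ties
      double bm = M[d]; unsigned char tb = 0;
      if (Ib[d] > bm) { bm = Ib[d]; tb = 1; }
      if (Ia[d] > bm) { bm = Ia[d]; tb = 2; }
      M[c] = bm + subscore(a[i - 1], b[j - 1], match, mismatch);
      tM[c] = tb;
      // Ib: gap in b, consumes a[i-1]
      double vb = M[u] - open_cost; unsigned char tbb = 0;
      if (Ib[u] - gap_extend > vb) { vb = Ib[u] - gap_extend; tbb = 1; }
      if (Ia[u] - open_cost > vb) { vb = Ia[u] - open_cost; tbb = 2; }
      Ib[c] = vb; tIb[c] = tbb;
      // Ia: gap in a, consumes b[j-1]
      double va = M[l] - open_cost; unsigned char tba = 0;
      if (Ib[l] - open_cost > va) { va = Ib[l] - open_cost; tba = 1; }
      if (Ia[l] - gap_extend > va) { va = Ia[l] - gap_extend; tba = 2; }
      Ia[c] = va; tIa[c] = tba;
    }
  }
  size_t e = idx(la, lb);
  double best = M[e]; unsigned char st = 0;
  if (Ib[e] > best) { best = Ib[e]; st = 1; }
  if (Ia[e] > best) { best = Ia[e]; st = 2; }

  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    size_t c = idx(i, j);
    if (st == 0) {
      unsigned char prev = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == 1) {
      unsigned char prev = tIb[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; st = prev;
    } else {
      unsigned char prev = tIa[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
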