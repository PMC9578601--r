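#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Banded global pairwise alignment with affine gap penalties
// (Needleman-Wunsch / Gotoh). Gap of length L costs open + extend * L,
// matching the Biostrings::pairwiseAlignment convention. The band is
// expressed as allowed diagonal offsets d = j - i in [lo, hi]; callers
// must pick a band wide enough to contain the optimal path (the R
// wrapper derives it from the length difference plus a margin).
//
// Tie-breaking is deterministic: diagonal moves are preferred over
// gaps, and gap extension over gap opening, which places indels as a
// single left-anchored run.

static const double NEG_INF = -1e18;

// traceback codes: which matrix the predecessor lives in
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_NONE = 3 };

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int extra_band) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  const int lo = std::min(0, m - n) - extra_band;
  const int hi = std::max(0, m - n) + extra_band;
  const int W = hi - lo + 1;

  // rolling score rows; full traceback
  std::vector<double> Mprev(W, NEG_INF), Xprev(W, NEG_INF), Yprev(W, NEG_INF);
  std::vector<double> Mcur(W, NEG_INF),  Xcur(W, NEG_INF),  Ycur(W, NEG_INF);
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, FROM_NONE),
                             tbX((size_t)(n + 1) * W, FROM_NONE),
                             tbY((size_t)(n + 1) * W, FROM_NONE);

  auto K = [&](int i, int j) { return j - i - lo; }; // band column index

  // row i = 0
  for (int j = std::max(0, lo); j <= std::min(m, hi); ++j) {
    int k = K(0, j);
    if (j == 0) {
      Mprev[k] = 0.0;
    } else {
      Yprev[k] = -(gap_open + gap_extend * j);
      tbY[(size_t)0 * W + k] = (j == 1) ? FROM_M : FROM_Y;
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    const int jmin = std::max(0, i + lo);
    const int jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const int k = K(i, j);
      const size_t off = (size_t) i * W + k;
      if (j == 0) {
        // leading gap in b
        Xcur[k] = -(gap_open + gap_extend * i);
        tbX[off] = (i == 1) ? FROM_M : FROM_X;
      } else {
        // M: a[i] aligned to b[j]; predecessor at (i-1, j-1), same k
        if (j - 1 >= std::max(0, (i - 1) + lo) && j - 1 <= (i - 1) + hi) {
          const double s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? match : mismatch;
          double best = Mprev[k]; unsigned char from = FROM_M;
          if (Xprev[k] > best) { best = Xprev[k]; from = FROM_X; }
          if (Yprev[k] > best) { best = Yprev[k]; from = FROM_Y; }
          if (best > NEG_INF / 2) { Mcur[k] = best + s; tbM[off] = from; }
        }
        // X: gap in b, consumes a[i]; predecessor at (i-1, j), k+1
        if (k + 1 < W) {
          double ext  = Xprev[k + 1] - gap_extend;
          double opnM = Mprev[k + 1] - gap_open - gap_extend;
          double opnY = Yprev[k + 1] - gap_open - gap_extend;
          double best = ext; unsigned char from = FROM_X;
          if (opnM > best) { best = opnM; from = FROM_M; }
          if (opnY > best) { best = opnY; from = FROM_Y; }
          if (best > NEG_INF / 2) { Xcur[k] = best; tbX[off] = from; }
        }
        // Y: gap in a, consumes b[j]; predecessor at (i, j-1), k-1
        if (k - 1 >= 0) {
          double ext  = Ycur[k - 1] - gap_extend;
          double opnM = Mcur[k - 1] - gap_open - gap_extend;
          double opnX = Xcur[k - 1] - gap_open - gap_extend;
          double best = ext; unsigned char from = FROM_Y;
          if (opnM > best) { best = opnM; from = FROM_M; }
          if (opnX > best) { best = opnX; from = FROM_X; }
          if (best > NEG_INF / 2) { Ycur[k] = best; tbY[off] = from; }
        }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  const int kend = K(n, m);
  if (kend < 0 || kend >= W)
    stop("band does not contain the global alignment endpoint");
  double score = Mprev[kend]; int state = FROM_M;
  if (Xprev[kend] > score) { score = Xprev[kend]; state = FROM_X; }
  if (Yprev[kend] > score) { score = Yprev[kend]; state = FROM_Y; }
  if (score < NEG_INF / 2)
    stop("no alignment within band; widen 'extra_band'");

  // traceback
  std::string out_a, out_b;
  out_a.reserve(n + m); out_b.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int k = K(i, j);
    const size_t off = (size_t) i * W + k;
    if (state == FROM_M) {
      unsigned char from = tbM[off];
      out_a.push_back(a[(size_t)i - 1]); out_b.push_back(b[(size_t)j - 1]);
      --i; --j; state = from;
    } else if (state == FROM_X) {
      unsigned char from = tbX[off];
      out_a.push_back(a[(size_t)i - 1]); out_b.push_back('-');
      --i; state = from;
    } else { // FROM_Y
      unsigned char from = tbY[off];
      out_a.push_back('-'); out_b.push_back(b[(size_t)j - 1]);
      --j; state = from;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());

  return List::create(_["a"] = out_a, _["b"] = out_b, _["score"] = score);
}

// Count mismatches between rows of a read matrix (raw bytes, one read
// per row) and windows of a chromosome byte vector starting at the
// given 1-based positions. Used by the read simulator's exact
// homologous-copy scan.
// [[Rcpp::export(name = ".window_mismatch_cpp")]]
IntegerVector window_mismatch_cpp(RawVector chrom, IntegerVector starts,
                                  RawMatrix reads) {
  const int n = reads.nrow(), L = reads.ncol();
  const int clen = chrom.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const int s = starts[r] - 1;
    if (s < 0 || s + L > clen) { out[r] = NA_INTEGER; continue; }
    int mm = 0;
    for (int p = 0; p < L; ++p)
      if (chrom[s + p] != reads(r, p)) ++mm;
    out[r] = mm;
  }
  return out;
}
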