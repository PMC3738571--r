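#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman).
// Gap of length g scores gap_open + (g-1) * gap_ext, i.e. gap_open already
// includes the first gap residue. All inputs uppercase; 'N' never matches.
//
// Returns a List with score, 1-based alignment coordinates, match/mismatch/
// gap-open counts, alignment length, and the (q,s) index pairs of the
// aligned (non-gap) columns, which pileup construction consumes.

static inline int sub_score(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// traceback codes for the H (aligned) state
enum { TB_STOP = 0, TB_DIAG_H = 1, TB_FROM_E = 2, TB_FROM_F = 3 };

static List traceback_result(const std::string& a, const std::string& b,
                             int best, int bi, int bj,
                             const std::vector<int8_t>& tbH,
                             const std::vector<int8_t>& tbE,
                             const std::vector<int8_t>& tbF,
                             size_t ncol) {
  // walk back from (bi, bj) in state H
  std::vector<int> qcols, scols;
  int matches = 0, mismatches = 0, gap_opens = 0, aln_len = 0;
  int i = bi, j = bj;
  int qe = bi, se = bj, qs = bi, ss = bj;
  int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  if (best <= 0) {
    return List::create(_["score"] = 0);
  }
  while (true) {
    size_t idx = (size_t)i * ncol + j;
    if (state == 0) {
      int8_t t = tbH[idx];
      if (t == TB_STOP) break;
      if (t == TB_DIAG_H) {
        qcols.push_back(i); scols.push_back(j);
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') matches++; else mismatches++;
        aln_len++; qs = i; ss = j; i--; j--;
      } else if (t == TB_FROM_E) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: gap in query (consume subject base)
      int8_t t = tbE[idx];
      aln_len++; ss = j;
      j--;
      if (t == 1) { gap_opens++; state = 0; }
    } else { // F: gap in subject (consume query base)
      int8_t t = tbF[idx];
      aln_len++; qs = i;
      i--;
      if (t == 1) { gap_opens++; state = 0; }
    }
  }
  std::reverse(qcols.begin(), qcols.end());
  std::reverse(scols.begin(), scols.end());
  return List::create(
    _["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_opens"] = gap_opens, _["aln_len"] = aln_len,
    _["q_cols"] = wrap(qcols), _["s_cols"] = wrap(scols));
}

// [[Rcpp::export]]
List sw_full_cpp(std::string a, std::string b,
                 int match, int mismatch, int gap_open, int gap_ext) {
  const int m = a.size(), n = b.size();
  const size_t ncol = n + 1;
  const int NEG = -1000000000;
  std::vector<int> Hprev(ncol, 0), Hcur(ncol, 0);
  std::vector<int> Eprev(ncol, NEG), Ecur(ncol, NEG);
  std::vector<int> Fprev(ncol, NEG), Fcur(ncol, NEG);
  std::vector<int8_t> tbH((size_t)(m + 1) * ncol, TB_STOP);
  std::vector<int8_t> tbE((size_t)(m + 1) * ncol, 0);
  std::vector<int8_t> tbF((size_t)(m + 1) * ncol, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; i++) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= n; j++) {
      size_t idx = (size_t)i * ncol + j;
      // E: gap in query, coming from the left
      int e_open = Hcur[j - 1] + gap_open;
      int e_ext  = Ecur[j - 1] + gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[idx] = 1; }
      else                 { Ecur[j] = e_ext;  tbE[idx] = 2; }
      // F: gap in subject, coming from above
      int f_open = Hprev[j] + gap_open;
      int f_ext  = Fprev[j] + gap_ext;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[idx] = 1; }
      else                 { Fcur[j] = f_ext;  tbF[idx] = 2; }
      int diag = Hprev[j - 1] + sub_score(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; int8_t t = TB_STOP;
      if (diag > h)    { h = diag;    t = TB_DIAG_H; }
      if (Ecur[j] > h) { h = Ecur[j]; t = TB_FROM_E; }
      if (Fcur[j] > h) { h = Fcur[j]; t = TB_FROM_F; }
      Hcur[j] = h; tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  return traceback_result(a, b, best, bi, bj, tbH, tbE, tbF, ncol);
}

// Banded variant: only cells with |(j - i) - diag0| <= band are filled.
// Compact diagonal storage: row i holds j in [i + diag0 - band, i + diag0 + band].
// [[Rcpp::export]]
List sw_banded_cpp(std::string a, std::string b,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int diag0, int band) {
  const int m = a.size(), n = b.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  // compact matrices indexed [i][k], k = j - (i + diag0 - band)
  std::vector<int> Hprev(W + 2, 0), Hcur(W + 2, 0);
  std::vector<int> Eprev(W + 2, NEG), Ecur(W + 2, NEG);
  std::vector<int> Fprev(W + 2, NEG), Fcur(W + 2, NEG);
  std::vector<int8_t> tbHc((size_t)(m + 1) * W, TB_STOP);
  std::vector<int8_t> tbEc((size_t)(m + 1) * W, 0);
  std::vector<int8_t> tbFc((size_t)(m + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; i++) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    int jlo = std::max(1, i + diag0 - band);
    int jhi = std::min(n, i + diag0 + band);
    for (int j = jlo; j <= jhi; j++) {
      int k = j - (i + diag0 - band);          // 0..W-1 in row i
      int kL = k - 1;                          // (i, j-1): same row
      int kU = k + 1;                          // (i-1, j): previous row
      int kD = k;                              // (i-1, j-1): previous row
      size_t idx = (size_t)i * W + k;
      int hl = (kL >= 0) ? Hcur[kL] : 0;
      int el = (kL >= 0) ? Ecur[kL] : NEG;
      int e_open = (kL >= 0) ? hl + gap_open : NEG;
      int e_ext  = (kL >= 0) ? el + gap_ext  : NEG;
      if (e_open >= e_ext) { Ecur[k] = e_open; tbEc[idx] = 1; }
      else                 { Ecur[k] = e_ext;  tbEc[idx] = 2; }
      int hu = (kU <= W - 1 && j <= n) ? Hprev[kU] : 0;
      int fu = (kU <= W - 1) ? Fprev[kU] : NEG;
      int f_open = (kU <= W - 1) ? hu + gap_open : NEG;
      int f_ext  = (kU <= W - 1) ? fu + gap_ext  : NEG;
      if (f_open >= f_ext) { Fcur[k] = f_open; tbFc[idx] = 1; }
      else                 { Fcur[k] = f_ext;  tbFc[idx] = 2; }
      int hd = (j - 1 >= (i - 1) + diag0 - band && j - 1 <= (i - 1) + diag0 + band && j - 1 >= 0)
                 ? Hprev[kD] : 0;
      if (i == 1 || j == 1) hd = 0;
      int diag = hd + sub_score(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; int8_t t = TB_STOP;
      if (diag > h)    { h = diag;    t = TB_DIAG_H; }
      if (Ecur[k] > h) { h = Ecur[k]; t = TB_FROM_E; }
      if (Fcur[k] > h) { h = Fcur[k]; t = TB_FROM_F; }
      Hcur[k] = h; tbHc[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  if (best <= 0) return List::create(_["score"] = 0);
  // traceback on compact storage
  std::vector<int> qcols, scols;
  int matches = 0, mismatches = 0, gap_opens = 0, aln_len = 0;
  int i = bi, j = bj, qe = bi, se = bj, qs = bi, ss = bj, state = 0;
  while (true) {
    int k = j - (i + diag0 - band);
    size_t idx = (size_t)i * W + k;
    if (state == 0) {
      int8_t t = tbHc[idx];
      if (t == TB_STOP) break;
      if (t == TB_DIAG_H) {
        qcols.push_back(i); scols.push_back(j);
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') matches++; else mismatches++;
        aln_len++; qs = i; ss = j; i--; j--;
      } else if (t == TB_FROM_E) state = 1; else state = 2;
    } else if (state == 1) {
      int8_t t = tbEc[idx];
      aln_len++; ss = j; j--;
      if (t == 1) { gap_opens++; state = 0; }
    } else {
      int8_t t = tbFc[idx];
      aln_len++; qs = i; i--;
      if (t == 1) { gap_opens++; state = 0; }
    }
  }
  std::reverse(qcols.begin(), qcols.end());
  std::reverse(scols.begin(), scols.end());
  return List::create(
    _["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_opens"] = gap_opens, _["aln_len"] = aln_len,
    _["q_cols"] = wrap(qcols), _["s_cols"] = wrap(scols));
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return out;
}
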