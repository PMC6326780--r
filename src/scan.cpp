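#include <Rcpp.h>
#include <cctype>
#include <vector>
using namespace Rcpp;

// IUPAC bitmasks for the query consensus: an ambiguity code matches any
// base it lists. Unknown characters match nothing.
static inline int query_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4;
    case 'Y': return 2 | 8;
    case 'S': return 2 | 4;
    case 'W': return 1 | 8;
    case 'K': return 4 | 8;
    case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;
    case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;
    case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;
  }
}

// Subject (genome) bases: only unambiguous A/C/G/T can match; N and any
// other character never match and score as a mismatch when aligned.
static inline int subject_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    default:  return 0;
  }
}

// Local (Smith-Waterman) scan of a short pattern against a long subject
// with affine gaps: the first base of a gap costs `gap_open`, each further
// base `gap_ext`. Pass 1 is a rolling-column Gotoh recursion that flags
// every subject position where some local alignment *ending in an aligned
// column* at that position scores >= min_score. Pass 2 re-runs the DP with
// full traceback on a bounded window behind each flagged position and
// reports the alignment statistics needed for identity / length filters.
// Coordinates in the result are 0-based half-open on the subject.
// [[Rcpp::export]]
DataFrame sw_scan_cpp(std::string subject, std::string pattern,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int min_score) {
  const int L = static_cast<int>(subject.size());
  const int m = static_cast<int>(pattern.size());
  if (m == 0 || L == 0) stop("empty pattern or subject");
  std::vector<int> pm(m), sm(L);
  for (int i = 0; i < m; ++i) pm[i] = query_mask(pattern[i]);
  for (int j = 0; j < L; ++j) sm[j] = subject_mask(subject[j]);

  const int NEG = -1000000000 / 2;

  // Pass 1: candidate end columns.
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> cand;
  for (int j = 1; j <= L; ++j) {
    int F = NEG;
    int best_diag = 0;
    Hcur[0] = 0; Ecur[0] = NEG;
    for (int i = 1; i <= m; ++i) {
      const int s = (pm[i - 1] & sm[j - 1]) ? match : mismatch;
      const int diag = Hprev[i - 1] + s;
      const int e = std::max(Hprev[i] - gap_open, Eprev[i] - gap_ext);
      F = std::max(Hcur[i - 1] - gap_open, F - gap_ext);
      int h = diag;
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0) h = 0;
      Hcur[i] = h; Ecur[i] = e;
      if (diag > best_diag) best_diag = diag;
    }
    if (best_diag >= min_score) cand.push_back(j);
    Hprev.swap(Hcur); Eprev.swap(Ecur);
  }

  // Pass 2: windowed traceback per candidate. A local alignment of an
  // m-long pattern that still scores > 0 cannot consume more than ~2m
  // subject bases, so a window of 2m + 16 is always wide enough.
  const int W = 2 * m + 16;
  std::vector<int> out_s, out_e, out_score, out_match, out_cols, out_prows;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    const int j = cand[ci];
    const int ws = j > W ? j - W : 0;
    const int wl = j - ws;
    const int C = wl + 1;
    std::vector<int> H((m + 1) * C, 0), D((m + 1) * C, NEG),
                     E((m + 1) * C, NEG), Fm((m + 1) * C, NEG);
    for (int k = 1; k <= wl; ++k) {
      for (int i = 1; i <= m; ++i) {
        const int s = (pm[i - 1] & sm[ws + k - 1]) ? match : mismatch;
        const int d = H[(i - 1) * C + (k - 1)] + s;
        const int e = std::max(H[i * C + (k - 1)] - gap_open,
                               E[i * C + (k - 1)] - gap_ext);
        const int f = std::max(H[(i - 1) * C + k] - gap_open,
                               Fm[(i - 1) * C + k] - gap_ext);
        int h = d;
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        D[i * C + k] = d; E[i * C + k] = e; Fm[i * C + k] = f; H[i * C + k] = h;
      }
    }
    // The alignment must end by consuming subject column j in an aligned
    // (match/mismatch) column: pick the best diagonal entry in the last
    // window column.
    int besti = -1, bests = min_score - 1;
    for (int i = 1; i <= m; ++i) {
      if (D[i * C + wl] > bests) { bests = D[i * C + wl]; besti = i; }
    }
    if (besti < 0) continue;

    int i = besti, k = wl, state = 0;  // 0 = aligned, 1 = gap-in-pattern, 2 = gap-in-subject
    int matches = 0, cols = 0, prows = 0;
    while (true) {
      if (state == 0) {
        const int s = (pm[i - 1] & sm[ws + k - 1]) ? match : mismatch;
        ++cols; ++prows;
        if (s > 0) ++matches;
        --i; --k;
        const int h = H[i * C + k];
        if (h <= 0) break;
        if (h == D[i * C + k]) state = 0;
        else if (h == E[i * C + k]) state = 1;
        else state = 2;
      } else if (state == 1) {      // gap in pattern: consumes a subject base
        ++cols;
        const int e = E[i * C + k];
        const int fromH = H[i * C + (k - 1)] - gap_open;
        --k;
        if (e == fromH) {
          const int h = H[i * C + k];
          if (h <= 0) break;
          if (h == D[i * C + k]) state = 0;
          else if (h == E[i * C + k]) state = 1;
          else state = 2;
        }                            // else stay in E
      } else {                       // gap in subject: consumes a pattern base
        ++cols; ++prows;
        const int f = Fm[i * C + k];
        const int fromH = H[(i - 1) * C + k] - gap_open;
        --i;
        if (f == fromH) {
          const int h = H[i * C + k];
          if (h <= 0) break;
          if (h == D[i * C + k]) state = 0;
          else if (h == E[i * C + k]) state = 1;
          else state = 2;
        }                            // else stay in F
      }
    }
    out_s.push_back(ws + k);
    out_e.push_back(j);
    out_score.push_back(bests);
    out_match.push_back(matches);
    out_cols.push_back(cols);
    out_prows.push_back(prows);
  }

  return DataFrame::create(
      _["start"] = out_s, _["end"] = out_e, _["score"] = out_score,
      _["matches"] = out_match, _["columns"] = out_cols,
      _["pattern_positions"] = out_prows);
}
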