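#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Local affine-gap alignment of a residue-index sequence against a
// position-specific score matrix (rows = profile columns, cols = alphabet).
//
// Conventions (shared with the R brute-force oracle used in the tests):
//  - an alignment starts and ends with a residue matched to a column;
//  - skipping profile column p costs gapOpen[p] when the gap opens and
//    gapExtend[p] for each further skipped column;
//  - a sequence residue consumed between columns p and p+1 costs the mean
//    of the two flanking columns' gapOpen (gapExtend) values, the single
//    flanking column's value at the profile ends;
//  - between two consecutive matched columns the gap is either purely in
//    the profile or purely in the sequence (Gotoh states);
//  - the score is floored at 0 (empty local alignment);
//  - ties are resolved leftmost (smallest sequence start), then longest
//    (largest sequence end).
//
// seqCols holds 0-based column indices into M's columns; -1 marks a residue
// absent from the alphabet, which scores 0 against every column.
//
// Returns score plus 0-based half-open [start, end) sequence coordinates
// (both -1 for a degenerate, score-0 result).
// [[Rcpp::export]]
List profile_align_c(NumericMatrix M, NumericVector gapOpen,
                     NumericVector gapExtend, IntegerVector seqCols) {
  const int L = M.nrow();
  const int n = seqCols.size();
  const double NEG = -1e300;
  const int DEAD = INT_MAX;

  if (L < 1 || n < 1)
    return List::create(_["score"] = 0.0, _["start"] = -1, _["end"] = -1);

  // insertion penalties while the last matched column is c (0-based)
  std::vector<double> insOpen(L), insExt(L);
  for (int c = 0; c < L; ++c) {
    if (c < L - 1) {
      insOpen[c] = 0.5 * (gapOpen[c] + gapOpen[c + 1]);
      insExt[c]  = 0.5 * (gapExtend[c] + gapExtend[c + 1]);
    } else {
      insOpen[c] = gapOpen[c];
      insExt[c]  = gapExtend[c];
    }
  }

  // rolling rows over the sequence index; column index 0..L (0 = boundary)
  std::vector<double> Sprev(L + 1, NEG), Dprev(L + 1, NEG), Iprev(L + 1, NEG);
  std::vector<double> Scur(L + 1, NEG), Dcur(L + 1, NEG), Icur(L + 1, NEG);
  std::vector<int> SsPrev(L + 1, DEAD), DsPrev(L + 1, DEAD), IsPrev(L + 1, DEAD);
  std::vector<int> SsCur(L + 1, DEAD), DsCur(L + 1, DEAD), IsCur(L + 1, DEAD);

  double best = 0.0;
  int bestStart = -1, bestEnd = -1;

  for (int i = 1; i <= n; ++i) {
    Scur[0] = Dcur[0] = Icur[0] = NEG;
    SsCur[0] = DsCur[0] = IsCur[0] = DEAD;
    const int col = seqCols[i - 1];
    for (int p = 1; p <= L; ++p) {
      const double m = (col >= 0) ? M(p - 1, col) : 0.0;

      // match state: best predecessor among S/D/I at (i-1, p-1) or a fresh start
      double bv = 0.0;
      int bs = i - 1;  // fresh start consumes residue i (0-based start i-1)
      if (Sprev[p - 1] > bv || (Sprev[p - 1] == bv && SsPrev[p - 1] < bs)) {
        bv = Sprev[p - 1]; bs = SsPrev[p - 1];
      }
      if (Dprev[p - 1] > bv || (Dprev[p - 1] == bv && DsPrev[p - 1] < bs)) {
        bv = Dprev[p - 1]; bs = DsPrev[p - 1];
      }
      if (Iprev[p - 1] > bv || (Iprev[p - 1] == bv && IsPrev[p - 1] < bs)) {
        bv = Iprev[p - 1]; bs = IsPrev[p - 1];
      }
      double sval = bv + m;
      if (sval <= 0.0 || bs == DEAD) {
        // a non-positive prefix never helps a local alignment: cut here
        if (m > 0.0) { sval = m; bs = i - 1; }
        else { sval = NEG; bs = DEAD; }
      }
      Scur[p] = sval;
      SsCur[p] = bs;

      if (sval > best ||
          (sval == best && (bs < bestStart || (bs == bestStart && i > bestEnd)))) {
        if (sval > 0.0) { best = sval; bestStart = bs; bestEnd = i; }
      }

      // deletion state: column p skipped (sequence index stays at i)
      double dOpen = Scur[p - 1] - gapOpen[p - 1];
      double dExt  = Dcur[p - 1] - gapExtend[p - 1];
      if (SsCur[p - 1] == DEAD) dOpen = NEG;
      if (DsCur[p - 1] == DEAD) dExt = NEG;
      if (dOpen > dExt || (dOpen == dExt && SsCur[p - 1] <= DsCur[p - 1])) {
        Dcur[p] = dOpen; DsCur[p] = SsCur[p - 1];
      } else {
        Dcur[p] = dExt; DsCur[p] = DsCur[p - 1];
      }

      // insertion state: residue i consumed after last matched column p
      double iOpen = Sprev[p] - insOpen[p - 1];
      double iExt  = Iprev[p] - insExt[p - 1];
      if (SsPrev[p] == DEAD) iOpen = NEG;
      if (IsPrev[p] == DEAD) iExt = NEG;
      if (iOpen > iExt || (iOpen == iExt && SsPrev[p] <= IsPrev[p])) {
        Icur[p] = iOpen; IsCur[p] = SsPrev[p];
      } else {
        Icur[p] = iExt; IsCur[p] = IsPrev[p];
      }
    }
    std::swap(Sprev, Scur); std::swap(Dprev, Dcur); std::swap(Iprev, Icur);
    std::swap(SsPrev, SsCur); std::swap(DsPrev, DsCur); std::swap(IsPrev, IsCur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["start"] = -1, _["end"] = -1);
  return List::create(_["score"] = best, _["start"] = bestStart,
                      _["end"] = bestEnd);
}
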