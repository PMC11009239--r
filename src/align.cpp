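// Affine-gap pairwise alignment kernel (Gotoh) used by the scanner and the
// pairing/clustering stages. Scoring: match +1, mismatch -2, a gap of length
// L costs open + ext * L (defaults 3 + 2L, i.e. -5 for a length-1 gap and -2
// per further column). Identity = matches / alignment columns with terminal
// gap columns excluded (local alignments have none by construction).
//
// Score rows are rolled (two rows live at a time); backpointers are kept for
// the full matrix as packed 6-bit states so traceback can recover the match /
// mismatch / gap column counts exactly.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_dp")]]
List align_dp(std::string a, std::string b, bool local = false,
              double match = 1.0, double mismatch = -2.0,
              double gap_open = 3.0, double gap_ext = 2.0) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  const double gfirst = gap_open + gap_ext;

  std::vector<double> Hprev(m + 1), Hcur(m + 1), Fprev(m + 1), Fcur(m + 1);
  std::vector<double> Ecur(m + 1);
  // Packed pointers: bits 0-1 PH (0 diag, 1 from E, 2 from F, 3 stop),
  // bit 2 PE (1 = extend), bit 3 PF (1 = extend).
  std::vector<unsigned char> P((size_t)(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  Hprev[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Hprev[j] = local ? 0.0 : -(gap_open + gap_ext * j);
    Fprev[j] = NEG_INF;
    P[at(0, j)] = local ? 3 : 1;
  }
  Fprev[0] = NEG_INF;

  double best = local ? 0.0 : NEG_INF;
  int bi = local ? 0 : n, bj = local ? 0 : m;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = local ? 0.0 : -(gap_open + gap_ext * i);
    Ecur[0] = NEG_INF;
    Fcur[0] = local ? NEG_INF : -(gap_open + gap_ext * i);
    P[at(i, 0)] = local ? 3 : 2;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      unsigned char p = 0;
      double eo = Hcur[j - 1] - gfirst, ee = Ecur[j - 1] - gap_ext;
      double e = eo >= ee ? eo : ee;
      if (eo < ee) p |= 4;
      Ecur[j] = e;
      double fo = Hprev[j] - gfirst, fe = Fprev[j] - gap_ext;
      double f = fo >= fe ? fo : fe;
      if (fo < fe) p |= 8;
      Fcur[j] = f;
      double h = Hprev[j - 1] + ((ai == b[j - 1]) ? match : mismatch);
      unsigned char ph = 0;
      if (e > h) { h = e; ph = 1; }
      if (f > h) { h = f; ph = 2; }
      if (local && h < 0) { h = 0.0; ph = 3; }
      Hcur[j] = h;
      P[at(i, j)] = p | ph;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  if (!local) best = Hprev[m];

  // Traceback collecting column types: 0 = match, 1 = mismatch, 2 = gap.
  std::vector<unsigned char> cols;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    unsigned char p = P[at(i, j)];
    if (state == 0) {
      unsigned char ph = p & 3;
      if (local && ph == 3) break;
      if (i == 0 && j == 0) break;
      if (ph == 0) {
        cols.push_back(a[i - 1] == b[j - 1] ? 0 : 1);
        --i; --j;
      } else if (ph == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      cols.push_back(2);
      if (!(p & 4)) state = 0;
      --j;
    } else {
      cols.push_back(2);
      if (!(p & 8)) state = 0;
      --i;
    }
  }
  int qstart = i + 1, sstart = j + 1; // 1-based span starts

  // Exclude terminal gap columns from the identity denominator (global mode
  // with unequal lengths); cols is in reverse order, trim both ends.
  int lo = 0, hi = (int)cols.size();
  while (lo < hi && cols[lo] == 2) ++lo;
  while (hi > lo && cols[hi - 1] == 2) --hi;
  int matches = 0, columns = hi - lo;
  for (int k = lo; k < hi; ++k) if (cols[k] == 0) ++matches;

  return List::create(
    _["score"] = best,
    _["matches"] = matches,
    _["columns"] = columns,
    _["identity"] = columns > 0 ? 100.0 * matches / columns : 0.0,
    _["qstart"] = qstart, _["qend"] = bi,
    _["sstart"] = sstart, _["send"] = bj);
}
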