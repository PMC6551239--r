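#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (BLAST convention: a gap
// of length L costs gapOpen + L * gapExtend). Sequences are 0-based integer
// codes indexing rows/columns of the substitution matrix.
//
// The score pass keeps only two rolling rows (no traceback storage); the
// first best cell in row-major order wins, which makes results
// deterministic. Alignment starts are recovered by a second score pass over
// the reversed prefix rectangle ending at the best cell.

namespace {

struct SWEnd {
  int score, qi, sj;  // 1-based DP end cell
};

// forward score pass over q[0..m) x s[0..n)
SWEnd score_pass(const int* q, int m, const int* s, int n,
                 const int* M, int nrow, int go, int ge) {
  const int NEG = INT_MIN / 4;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<int> sjn(n);
  for (int j = 0; j < n; ++j) sjn[j] = s[j] * nrow;
  SWEnd best = {0, 0, 0};
  for (int i = 1; i <= m; ++i) {
    const int* Mq = M + q[i - 1];
    int Eij = NEG;
    int* hc = Hcur.data();
    int* fc = Fcur.data();
    const int* hp = Hprev.data();
    const int* fp = Fprev.data();
    for (int j = 1; j <= n; ++j) {
      int e = hc[j - 1] - go;
      const int eExt = Eij - ge;
      if (eExt > e) e = eExt;
      int f = hp[j] - go;
      const int fExt = fp[j] - ge;
      if (fExt > f) f = fExt;
      int h = hp[j - 1] + Mq[sjn[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      hc[j] = h;
      fc[j] = f;
      Eij = e;
      if (h > best.score) { best.score = h; best.qi = i; best.sj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    Hcur[0] = 0;
    Fcur[0] = NEG;
  }
  return best;
}

}  // namespace

// Score and end coordinates only: c(score, q_end, s_end), 0-based half-open
// end positions (i.e. the end cell). Score 0 means no positive alignment.
// [[Rcpp::export]]
IntegerVector cpp_sw_score(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                           int gapOpen, int gapExtend) {
  IntegerVector out(3);
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) return out;
  SWEnd b = score_pass(INTEGER(q), m, INTEGER(s), n, INTEGER(mat), mat.nrow(),
                       gapOpen + gapExtend, gapExtend);
  out[0] = b.score; out[1] = b.qi; out[2] = b.sj;
  return out;
}

// Full local alignment: c(score, q_start, q_end, s_start, s_end), 0-based
// half-open. Start coordinates come from a reversed score pass over the
// prefix rectangle ending at the best cell (the reversed optimal alignment
// attains the same score; its end is the original start).
// [[Rcpp::export]]
IntegerVector cpp_sw(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                     int gapOpen, int gapExtend) {
  IntegerVector out(5);
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) return out;
  const int* M = INTEGER(mat);
  const int nrow = mat.nrow();
  const int go = gapOpen + gapExtend, ge = gapExtend;
  SWEnd b = score_pass(INTEGER(q), m, INTEGER(s), n, M, nrow, go, ge);
  if (b.score <= 0) return out;
  std::vector<int> qr(b.qi), sr(b.sj);
  for (int i = 0; i < b.qi; ++i) qr[i] = q[b.qi - 1 - i];
  for (int j = 0; j < b.sj; ++j) sr[j] = s[b.sj - 1 - j];
  SWEnd r = score_pass(qr.data(), b.qi, sr.data(), b.sj, M, nrow, go, ge);
  out[0] = b.score;
  out[1] = b.qi - r.qi;  out[2] = b.qi;
  out[3] = b.sj - r.sj;  out[4] = b.sj;
  return out;
}
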