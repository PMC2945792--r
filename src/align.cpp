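#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Base coding: A=0, C=1, G=2, U=3.
// Pair classes: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.
static inline int pair_class(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 1 && b == 2) || (a == 2 && b == 1)) return 0;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;
  return 2;
}

static const double NEG = -1e12;

// Iterative masked local alignment with affine gaps between a short query
// (the reversed miRNA alignment region, so it reads along the UTR 5'->3')
// and a subject (UTR) sequence.  Pair scores at seed positions are scaled,
// and so are gap penalties touching the seed span (a gap consuming a seed
// query position, or a subject bulge flanked by one), keeping the seed
// duplex effectively contiguous.
// Gap costs: a run of k gaps costs gap_open + (k-1) * gap_extend.
// Each round reports the best local alignment with score >= cutoff, then
// masks its subject footprint and repeats, yielding score-maximal mutually
// non-overlapping hits (ties resolved toward the 5'-most subject end).
// [[Rcpp::export(name = ".sw_hits")]]
List sw_hits(IntegerVector query, IntegerVector subject,
             LogicalVector seed_pos,
             double match_score, double wobble_score, double mismatch_score,
             double gap_open, double gap_extend, double seed_scale,
             double score_cutoff, int max_hits) {
  const int m = query.size(), n = subject.size();
  std::vector<bool> masked(n, false);
  List hits;

  // DP matrices, (m+1) x (n+1); state M ends in a pair, Ix consumes query
  // only (miRNA base opposite a gap), Iy consumes subject only (UTR bulge).
  std::vector<std::vector<double> > M(m + 1, std::vector<double>(n + 1, 0.0)),
      Ix(m + 1, std::vector<double>(n + 1, NEG)),
      Iy(m + 1, std::vector<double>(n + 1, NEG));

  int round = 0;
  while (round++ < max_hits) {
    double best = NEG;
    int bi = -1, bj = -1;
    for (int i = 0; i <= m; ++i) { M[i][0] = 0.0; Ix[i][0] = NEG; Iy[i][0] = NEG; }
    for (int j = 0; j <= n; ++j) { M[0][j] = 0.0; Ix[0][j] = NEG; Iy[0][j] = NEG; }
    for (int i = 1; i <= m; ++i) {
      double gx = seed_pos[i - 1] ? seed_scale : 1.0;
      double gy = (seed_pos[i - 1] || (i < m && seed_pos[i])) ? seed_scale : 1.0;
      for (int j = 1; j <= n; ++j) {
        Ix[i][j] = std::max(M[i - 1][j] + gap_open * gx,
                            Ix[i - 1][j] + gap_extend * gx);
        if (masked[j - 1]) {
          M[i][j] = NEG; Iy[i][j] = NEG;
          continue;
        }
        Iy[i][j] = std::max(M[i][j - 1] + gap_open * gy,
                            Iy[i][j - 1] + gap_extend * gy);
        int pc = pair_class(query[i - 1], subject[j - 1]);
        double s = (pc == 0) ? match_score : (pc == 1) ? wobble_score : mismatch_score;
        if (seed_pos[i - 1]) s *= seed_scale;
        double prev = std::max(0.0, std::max(M[i - 1][j - 1],
                         std::max(Ix[i - 1][j - 1], Iy[i - 1][j - 1])));
        M[i][j] = prev + s;
        if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
      }
    }
    if (best < score_cutoff || bi < 0) break;

    // traceback from (bi, bj), state M
    IntegerVector qstate(m, 4);   // 0 WC, 1 GU, 2 mismatch, 3 gap, 4 unaligned
    IntegerVector qsub(m, -1);    // 0-based subject index paired with query pos
    int i = bi, j = bj, state = 0;
    int sub_end = bj, sub_start = bj;
    while (i > 0 || j > 0) {
      if (state == 0) {           // M: query i-1 paired with subject j-1
        if (i == 0 || j == 0) break;
        int pc = pair_class(query[i - 1], subject[j - 1]);
        qstate[i - 1] = pc;
        qsub[i - 1] = j - 1;
        sub_start = j - 1;
        double s = (pc == 0) ? match_score : (pc == 1) ? wobble_score : mismatch_score;
        if (seed_pos[i - 1]) s *= seed_scale;
        double prev = M[i][j] - s;
        --i; --j;
        if (prev < 1e-9) break;                               // local start
        if (std::abs(M[i][j] - prev) < 1e-9) state = 0;
        else if (std::abs(Ix[i][j] - prev) < 1e-9) state = 1;
        else if (std::abs(Iy[i][j] - prev) < 1e-9) state = 2;
        else break;
      } else if (state == 1) {    // Ix: query i-1 opposite a gap
        qstate[i - 1] = 3;
        double gx = seed_pos[i - 1] ? seed_scale : 1.0;
        if (std::abs(Ix[i][j] - (M[i - 1][j] + gap_open * gx)) < 1e-9) state = 0;
        else state = 1;
        --i;
      } else {                    // Iy: subject j-1 bulged
        sub_start = j - 1;
        double gy = (seed_pos[i - 1] || (i < m && seed_pos[i])) ? seed_scale : 1.0;
        if (std::abs(Iy[i][j] - (M[i][j - 1] + gap_open * gy)) < 1e-9) state = 0;
        else state = 2;
        --j;
      }
    }
    for (int k = sub_start; k < sub_end; ++k) masked[k] = true;
    hits.push_back(List::create(
        _["score"] = best,
        _["sub_start"] = sub_start,
        _["sub_end"] = sub_end,
        _["qstate"] = qstate,
        _["qsub"] = qsub));
  }
  return hits;
}
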