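#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// McCaskill-style partition function over nested secondary structures under
// a simplified base-pair energy model (one energy per pair type, no loop
// terms beyond a minimum hairpin length, pair span capped at L).
//
// Z(i,j) = Z(i+1,j) + sum_k w(i,k) Z(i+1,k-1) Z(k+1,j)
// with k - i > minloop and k - i <= L; blocked positions cannot pair.
//
// Pairable partners (and their Boltzmann weights) are precomputed per
// position; blocking a window is a branchless 0/1 mask on the partners.

static inline double pair_weight(int a, int b, double wGC, double wAU, double wGU) {
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return wGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return 0.0;
}

struct PairTable {
  int n;
  std::vector<std::vector<int> > partner;    // k > i, minloop < k-i <= L
  std::vector<std::vector<double> > weight;
};

static PairTable build_table(const IntegerVector &seq, int L, int minloop,
                             double wGC, double wAU, double wGU) {
  PairTable t;
  t.n = seq.size();
  t.partner.resize(t.n);
  t.weight.resize(t.n);
  for (int i = 0; i < t.n; ++i) {
    int kmax = std::min(t.n - 1, i + L);
    for (int k = i + minloop + 1; k <= kmax; ++k) {
      double w = pair_weight(seq[i], seq[k], wGC, wAU, wGU);
      if (w > 0.0) { t.partner[i].push_back(k); t.weight[i].push_back(w); }
    }
  }
  return t;
}

static double pf(const PairTable &t, const std::vector<double> &mask,
                 int minloop) {
  const int n = t.n;
  if (n == 0) return 1.0;
  std::vector<double> Z(n * n, 1.0);         // Z[i*n + j], 1 for empty/short
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double z = Z[(i + 1) * n + j];         // i unpaired (valid: len-1 >= 1)
      if (mask[i] != 0.0) {
        const std::vector<int> &ks = t.partner[i];
        const std::vector<double> &ws = t.weight[i];
        for (size_t q = 0; q < ks.size(); ++q) {
          const int k = ks[q];
          if (k > j) break;
          const double inner = (k - 1 >= i + 1) ? Z[(i + 1) * n + (k - 1)] : 1.0;
          const double outer = (k + 1 <= j) ? Z[(k + 1) * n + j] : 1.0;
          z += ws[q] * mask[k] * inner * outer;
        }
      }
      Z[i * n + j] = z;
    }
  }
  return Z[n - 1];                            // Z[0*n + (n-1)]
}

// Probability that each u-length window is fully unpaired in the Boltzmann
// ensemble: P(i) = Z[positions i..i+u-1 unpaired] / Z, for window starts
// i0..i1 (0-based, inclusive).
// [[Rcpp::export(name = ".pf_unpaired")]]
NumericVector pf_unpaired(IntegerVector seq, int u, int L, int minloop,
                          double e_gc, double e_au, double e_gu, double kT,
                          int i0, int i1) {
  const int n = seq.size();
  if (u > n) stop("u exceeds sequence length");
  if (i0 < 0 || i1 > n - u || i0 > i1) stop("invalid window range");
  const double wGC = std::exp(-e_gc / kT), wAU = std::exp(-e_au / kT),
               wGU = std::exp(-e_gu / kT);
  PairTable t = build_table(seq, L, minloop, wGC, wAU, wGU);
  std::vector<double> mask(n, 1.0);
  const double Zfull = pf(t, mask, minloop);
  NumericVector out(i1 - i0 + 1);
  for (int i = i0; i <= i1; ++i) {
    std::fill(mask.begin(), mask.end(), 1.0);
    for (int k = i; k < i + u; ++k) mask[k] = 0.0;
    out[i - i0] = pf(t, mask, minloop) / Zfull;
  }
  return out;
}
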