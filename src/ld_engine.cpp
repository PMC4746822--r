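// Fast path for scanning complete binary data: SNP columns are packed
// into 64-bit words so joint counts come from word-level population
// counts, the cumulative LD-sum table is filled banded (no window ever
// spans more than `band` SNPs), and the per-location border enumeration
// runs in place. Every floating-point expression mirrors the R
// reference path operation for operation, so the two paths agree
// bitwise and the plain-R workplan executor reproduces this scan
// exactly.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// [[Rcpp::export(name = ".ld_scan_engine")]]
NumericMatrix ld_scan_engine(IntegerMatrix geno, NumericVector positions,
                             NumericVector grid, double minwin,
                             double maxwin, int minsnps, double balance,
                             double eps) {
  const int n = geno.nrow();
  const int S = geno.ncol();
  const int nw = (n + 63) / 64;
  const bool use_balance = R_finite(balance);

  // band: widest window (in SNP count) any grid location can touch
  int band = 1;
  std::vector<int> wlo(grid.size()), whi(grid.size()), wsp(grid.size());
  for (int g = 0; g < grid.size(); ++g) {
    double lo = grid[g] - maxwin, hi = grid[g] + maxwin;
    int a = (int)(std::lower_bound(positions.begin(), positions.end(), lo) -
                  positions.begin());
    int b = (int)(std::upper_bound(positions.begin(), positions.end(), hi) -
                  positions.begin()) - 1;
    wlo[g] = a; whi[g] = b;
    wsp[g] = (int)(std::upper_bound(positions.begin(), positions.end(),
                                    grid[g]) - positions.begin()) - 1;
    if (b > a && b - a > band) band = b - a;
  }
  if (band > S - 1) band = S - 1;

  // pack SNP columns
  std::vector<uint64_t> bits((size_t)S * nw, 0);
  std::vector<double> c1(S);
  for (int j = 0; j < S; ++j) {
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (geno(i, j)) {
        bits[(size_t)j * nw + i / 64] |= 1ULL << (i % 64);
        ++cnt;
      }
    }
    c1[j] = cnt;
  }

  // banded cumulative sums: M[i][d] holds the table entry at (i, i - d)
  std::vector<std::vector<double>> M(S);
  const double dn = n;
  for (int i = 0; i < S; ++i) {
    int len = std::min(i, band) + 1;
    M[i].assign(len, 0.0);
    long double acc = 0.0;  // matches R's extended-precision cumsum
    const uint64_t* bi = &bits[(size_t)i * nw];
    const double p1 = c1[i] / dn;
    const double q1 = p1 * (1 - p1);
    for (int d = 1; d < len; ++d) {
      int j = i - d;
      const uint64_t* bj = &bits[(size_t)j * nw];
      int n11 = 0;
      for (int w = 0; w < nw; ++w) n11 += popcount64(bi[w] & bj[w]);
      const double p2 = c1[j] / dn;
      const double dd = n11 / dn - p1 * p2;
      const double den = q1 * (p2 * (1 - p2));
      double r2 = (dd * dd) / den;
      if (!R_finite(r2)) r2 = 0.0;
      acc += r2;
      M[i][d] = M[i - 1][d - 1] + (double)acc;
    }
  }
  auto Mget = [&](int i, int j) -> double {
    // entry (i, j), j <= i, i - j <= band (0-based window-local ok)
    return M[i][i - j];
  };

  NumericMatrix out(grid.size(), 5);  // omega, l, W, left, right
  for (int g = 0; g < grid.size(); ++g) {
    double pos = grid[g];
    out(g, 0) = 0.0;
    out(g, 1) = NA_REAL; out(g, 2) = NA_REAL;
    out(g, 3) = NA_REAL; out(g, 4) = NA_REAL;
    int lo = wlo[g], hi = whi[g], s = wsp[g];
    if (s < lo || s + 1 > hi) continue;          // need SNPs on both sides
    if (s - lo + 1 < 2 || hi - s < 2) continue;  // >= 2 per side
    // innermost candidate borders (mandatory core)
    int a_in = s, b_in = s + 1;
    while (a_in - 1 >= lo && positions[a_in - 1] > pos - minwin) --a_in;
    // a_in is now the outermost SNP with pos > pos - minwin, or s when
    // the core is empty (nearest left SNP)
    if (positions[a_in] <= pos - minwin) a_in = s;
    while (b_in + 1 <= hi && positions[b_in + 1] < pos + minwin) ++b_in;
    if (positions[b_in] >= pos + minwin) b_in = s + 1;
    int a_hi = std::min(a_in, s - 1);
    int b_lo = std::max(b_in, s + 2);
    if (a_hi < lo || b_lo > hi) continue;
    double best = -1.0;
    int bestW = 0, bestA = -1, bestB = -1;
    double bestL = 0, bestR = 0;
    for (int b = b_lo; b <= hi; ++b) {
      int r = b - s;
      double sumR = Mget(b, s + 1);
      for (int a = lo; a <= a_hi; ++a) {
        int l = s - a + 1;
        int W = l + r;
        if (W < minsnps) continue;
        if (use_balance && std::abs(l - r) > balance) continue;
        double sumL = Mget(s, a);
        double sumX = (Mget(b, a) - sumL) - sumR;
        double num = (sumL + sumR) /
          (l * (l - 1) / 2.0 + r * (r - 1) / 2.0);
        double den = std::max(sumX, eps) / ((double)l * (double)r);
        double om = num / den;
        bool take = om > best;
        if (!take && om == best) {
          take = (W < bestW) || (W == bestW && a < bestA);
        }
        if (take) {
          best = om; bestW = W; bestA = a; bestB = b;
          bestL = l; bestR = r;
        }
      }
    }
    if (bestA >= 0) {
      out(g, 0) = best;
      out(g, 1) = bestL;
      out(g, 2) = bestW;
      out(g, 3) = positions[bestA];
      out(g, 4) = positions[bestB];
    }
  }
  return out;
}
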