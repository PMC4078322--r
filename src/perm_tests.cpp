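#include <Rcpp.h>
using namespace Rcpp;

// Heterozygote counts of B random re-pairings of an allele pool (length 2n,
// integer allele codes). Each re-pairing is a fresh Fisher-Yates shuffle with
// consecutive elements paired, i.e. a uniform draw from the random-union-of-
// gametes null conditional on the observed allele counts.
// [[Rcpp::export]]
IntegerVector perm_het_counts_cpp(IntegerVector pool, int B) {
  const int m = pool.size();
  std::vector<int> v(pool.begin(), pool.end());
  IntegerVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = m - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(v[i], v[j]);
    }
    int het = 0;
    for (int i = 0; i < m; i += 2)
      if (v[i] != v[i + 1]) ++het;
    out[b] = het;
  }
  return out;
}

static double g_stat(const std::vector<int> &tab, const std::vector<double> &ra,
                     const std::vector<double> &rb, int Ka, int Kb, double N) {
  double g = 0.0;
  for (int i = 0; i < Ka; ++i)
    for (int j = 0; j < Kb; ++j) {
      int o = tab[i * Kb + j];
      if (o > 0) g += o * std::log(o * N / (ra[i] * rb[j]));
    }
  return 2.0 * g;
}

// Permutation null of the two-locus genotype G-statistic: classes at locus B
// are shuffled across individuals while locus A stays put. ga, gb are 1-based
// genotype class codes. Returns the B permuted statistics.
// [[Rcpp::export]]
NumericVector perm_g_stats_cpp(IntegerVector ga, IntegerVector gb, int Ka,
                               int Kb, int B) {
  const int n = ga.size();
  std::vector<int> b(gb.begin(), gb.end());
  std::vector<double> ra(Ka, 0.0), rb(Kb, 0.0);
  for (int i = 0; i < n; ++i) { ra[ga[i] - 1] += 1.0; rb[gb[i] - 1] += 1.0; }
  std::vector<int> tab(Ka * Kb);
  NumericVector out(B);
  for (int p = 0; p < B; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(b[i], b[j]);
    }
    std::fill(tab.begin(), tab.end(), 0);
    for (int i = 0; i < n; ++i) ++tab[(ga[i] - 1) * Kb + (b[i] - 1)];
    out[p] = g_stat(tab, ra, rb, Ka, Kb, (double)n);
  }
  return out;
}

// Observed G-statistic for the same contingency table.
// [[Rcpp::export]]
double g_stat_cpp(IntegerVector ga, IntegerVector gb, int Ka, int Kb) {
  const int n = ga.size();
  std::vector<double> ra(Ka, 0.0), rb(Kb, 0.0);
  std::vector<int> tab(Ka * Kb, 0);
  for (int i = 0; i < n; ++i) {
    ra[ga[i] - 1] += 1.0;
    rb[gb[i] - 1] += 1.0;
    ++tab[(ga[i] - 1) * Kb + (gb[i] - 1)];
  }
  return g_stat(tab, ra, rb, Ka, Kb, (double)n);
}
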