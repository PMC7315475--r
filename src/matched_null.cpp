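#include <Rcpp.h>
using namespace Rcpp;

// Null delta-PRS draws for DAF-matched SNP sets.
//
// pools:  per-bin integer vectors of candidate SNP indices (1-based into
//         d_der / d_anc); need: SNPs to draw per bin (without replacement
//         within a draw); d_der / d_anc: per-SNP count-scale mean dosage
//         differences under derived / ancestral effect polarization.
//
// Sampling uses a partial Fisher-Yates shuffle on a persistent working
// copy of each pool: after k swaps the pool is still a permutation, so no
// restore pass is needed between draws and each draw costs O(set size).
// Uses R's RNG, so results are governed by set.seed().
// [[Rcpp::export]]
NumericVector matched_null_draws_cpp(List pools, IntegerVector need,
                                     NumericVector d_der, NumericVector d_anc,
                                     double derived_fraction, int n_draws) {
  int n_bins = pools.size();
  std::vector< std::vector<int> > work(n_bins);
  for (int b = 0; b < n_bins; b++)
    work[b] = as< std::vector<int> >(pools[b]);

  NumericVector out(n_draws);
  for (int r = 0; r < n_draws; r++) {
    double acc = 0.0;
    for (int b = 0; b < n_bins; b++) {
      std::vector<int> &pool = work[b];
      int n = pool.size();
      int k = need[b];
      for (int j = 0; j < k; j++) {
        int pick = j + (int)(unif_rand() * (n - j));
        if (pick >= n) pick = n - 1;
        std::swap(pool[j], pool[pick]);
        int idx = pool[j] - 1;
        acc += (unif_rand() < derived_fraction) ? d_der[idx] : d_anc[idx];
      }
    }
    out[r] = acc;
  }
  return out;
}
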