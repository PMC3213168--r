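#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of the alignment-wide maximum weighted fragment score
// under column permutation. agree: pairs x sites 0/1 matrix; perms: sites x
// nperm matrix of 1-based column orders (generated with R's RNG for
// reproducibility); weights: per-pair score weight (permutation-invariant).
// penalty == 0 scores maximal runs of agreement (reset on mismatch);
// penalty > 0 scores BLAST-like maximal segments (match +1,
// mismatch -penalty, floor at 0). Each pair's best segment score is
// multiplied by its weight before taking the max over pairs.
// [[Rcpp::export(name = "perm_max_stat_cpp")]]
NumericVector perm_max_stat(IntegerMatrix agree, IntegerMatrix perms,
                            double penalty, NumericVector weights) {
  const int npair = agree.nrow();
  const int nsite = agree.ncol();
  const int nperm = perms.ncol();
  if (perms.nrow() != nsite) stop("permutation length mismatch");
  if (weights.size() != npair) stop("one weight per pair required");
  NumericVector out(nperm);
  for (int r = 0; r < nperm; ++r) {
    double permmax = 0.0;
    for (int p = 0; p < npair; ++p) {
      if (weights[p] <= 0.0) continue;
      double run = 0.0, best = 0.0;
      for (int j = 0; j < nsite; ++j) {
        const int col = perms(j, r) - 1;
        if (agree(p, col)) {
          run += 1.0;
          if (run > best) best = run;
        } else {
          run = (penalty == 0.0) ? 0.0 : run - penalty;
          if (run < 0.0) run = 0.0;
        }
      }
      const double sc = best * weights[p];
      if (sc > permmax) permmax = sc;
    }
    out[r] = permmax;
  }
  return out;
}
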