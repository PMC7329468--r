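#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation:
// fraction of permutations of y-ranks with |rho| >= |rho_obs|.
// Mid-ranks are accepted; enumeration is over distinct arrangements, which
// is equivalent to all n! because duplicated ranks have equal multiplicity.
// [[Rcpp::export]]
double spearman_perm_p_cpp(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  double mx = mean(rx), my = mean(ry);
  double sx = 0, sy = 0;
  std::vector<double> ax(n), ay(n);
  for (int i = 0; i < n; i++) {
    ax[i] = rx[i] - mx; ay[i] = ry[i] - my;
    sx += ax[i] * ax[i]; sy += ay[i] * ay[i];
  }
  double denom = std::sqrt(sx * sy);
  if (denom <= 0) stop("constant rank vector");
  double obs = 0;
  for (int i = 0; i < n; i++) obs += ax[i] * ay[i];
  double obs_abs = std::fabs(obs / denom);
  std::vector<double> perm(ay);
  std::sort(perm.begin(), perm.end());
  long total = 0, hits = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; i++) s += ax[i] * perm[i];
    if (std::fabs(s / denom) >= obs_abs - 1e-12) hits++;
    total++;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)hits / (double)total;
}
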