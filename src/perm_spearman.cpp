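#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation of two
// short vectors of (tie-averaged) ranks.  The correlation is a monotone
// function of S = sum(rx_i * ry_perm(i)) because the rank means and
// standard deviations are permutation-invariant; we therefore count
// arrangements with |S - c| >= |S_obs - c|, c = n * mean(rx) * mean(ry).
// std::next_permutation enumerates each distinct arrangement of the
// (possibly tied) ry values exactly once, and each distinct arrangement
// carries equal probability mass, so the count ratio is the exact p.
// [[Rcpp::export(name = ".perm_spearman_pvalue")]]
double perm_spearman_pvalue(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) stop("length mismatch");
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  const double centre = n * mx * my;
  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  const double t_obs = std::fabs(s_obs - centre);
  const double eps = 1e-9 * (std::fabs(centre) + 1.0);

  std::vector<double> perm(ry.begin(), ry.end());
  std::sort(perm.begin(), perm.end());
  long double n_total = 0, n_hit = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * perm[i];
    ++n_total;
    if (std::fabs(s - centre) >= t_obs - eps) ++n_hit;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return static_cast<double>(n_hit / n_total);
}
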