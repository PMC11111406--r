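#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation core: exhaustive scan over circular
// breakpoint pairs (i, j), 0 <= i < j <= m, arc = x[(i+1)..j] versus the
// complement, scored by the two-sample t statistic with pooled variance.

static inline double split_t(const std::vector<double>& S, double ss_total,
                             int m, int i, int j) {
  int n1 = j - i;
  int n2 = m - n1;
  double sum1 = S[j] - S[i];
  double m1 = sum1 / n1;
  double m2 = (S[m] - sum1) / n2;
  double diff = m1 - m2;
  if (std::abs(diff) < 1e-12) return 0.0;
  if (m <= 2) return 0.0;
  double within = ss_total - n1 * m1 * m1 - n2 * m2 * m2;
  if (within < 0) within = 0;
  double s2 = within / (m - 2);
  if (s2 <= 1e-24) return 1e12;  // perfect separation
  return std::abs(diff) / std::sqrt(s2 * (1.0 / n1 + 1.0 / n2));
}

// scan all pairs; if stop_at > 0, return early once a statistic >= stop_at
// is found (used inside the permutation loop)
static double max_stat(const std::vector<double>& x, int* bi, int* bj,
                       double stop_at) {
  int m = (int)x.size();
  std::vector<double> S(m + 1, 0.0);
  double ss = 0.0;
  for (int k = 0; k < m; ++k) {
    S[k + 1] = S[k] + x[k];
    ss += x[k] * x[k];
  }
  double best = -1.0;
  int besti = 0, bestj = 1;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j <= m; ++j) {
      if (i == 0 && j == m) continue;  // full circle: no split
      double t = split_t(S, ss, m, i, j);
      if (t > best) {
        best = t;
        besti = i; bestj = j;
        if (stop_at > 0 && best >= stop_at) {
          if (bi) *bi = besti;
          if (bj) *bj = bestj;
          return best;
        }
      }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

//' @name cbs_max_split
//' @title Best circular split of a ratio vector
//' @description Exhaustively maximizes the two-sample t statistic over all
//'   circular breakpoint pairs. Internal workhorse of [segment_cbs()].
//' @param x Numeric vector of per-bin ratios.
//' @return List with 0-based boundaries `i`, `j` (arc is `(i, j]`) and the
//'   statistic `t`.
//' @keywords internal
// [[Rcpp::export]]
List cbs_max_split(NumericVector x) {
  int m = x.size();
  if (m < 3) stop("need at least 3 bins");
  std::vector<double> v(x.begin(), x.end());
  int bi = 0, bj = 1;
  double t = max_stat(v, &bi, &bj, -1.0);
  return List::create(_["i"] = bi, _["j"] = bj, _["t"] = t);
}

//' @name cbs_perm_p
//' @title Permutation p-value for the best circular split
//' @description Permutes the bin values within the interval and recomputes
//'   the maximal split statistic, with early termination once the p-value
//'   can no longer fall at or below `alpha`. Uses R's RNG, so results are
//'   reproducible under `set.seed()`.
//' @param x Numeric vector of per-bin ratios.
//' @param t0 Observed maximal statistic.
//' @param nperm Number of permutations.
//' @param alpha Early-stopping significance level.
//' @return Permutation p-value `(1 + #exceedances) / (1 + #permutations)`;
//'   when stopped early the value is guaranteed to exceed `alpha`.
//' @keywords internal
// [[Rcpp::export]]
double cbs_perm_p(NumericVector x, double t0, int nperm, double alpha) {
  int m = x.size();
  std::vector<double> v(x.begin(), x.end());
  int exceed = 0;
  // stopping bound: p > alpha once exceed > alpha * (nperm + 1) - 1
  double bound = alpha * (nperm + 1) - 1.0;
  int done = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle with R's RNG
    for (int k = m - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(v[k], v[idx]);
    }
    double t = max_stat(v, nullptr, nullptr, t0);
    ++done;
    if (t >= t0) {
      ++exceed;
      if (exceed > bound) break;
    }
  }
  return (1.0 + exceed) / (1.0 + done);
}
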