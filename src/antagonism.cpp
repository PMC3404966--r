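#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fisher-Yates draw of a permutation of 0..n-1, consuming R's RNG stream
// exactly as base sample.int() does (rejection sampling kind), so that
// R-side oracles can replay every draw with set.seed() + sample.int().
static void draw_permutation(int n, std::vector<int> &scratch, std::vector<int> &out) {
  scratch.resize(n);
  out.resize(n);
  for (int i = 0; i < n; ++i) scratch[i] = i;
  int m = n;
  for (int i = 0; i < n; ++i) {
    int j = (int) R_unif_index(m);
    out[i] = scratch[j];
    scratch[j] = scratch[--m];
  }
}

// Antagonism statistic: sup over intercepts b of F_obs(b) - F_null(b),
// where F(b) is the fraction of sums strictly below b. The sup over real b
// equals the max over observed breakpoints v of
//   mean(obs <= v) - mean(null <= v)
// (between observed breakpoints F_obs is flat while F_null cannot decrease,
// so no other b can do better). `hist[j]` must hold the number of null sums
// in (obs_sorted[j-1], obs_sorted[j]]; null sums above max(obs) never enter.
// Ties in the max resolve to the smallest breakpoint.
static void stat_from_hist(const std::vector<double> &obs_sorted,
                           const std::vector<long long> &hist,
                           double n_null, double &A, double &bstar) {
  const int n = (int) obs_sorted.size();
  double best = R_NegInf, best_b = NA_REAL;
  long long cum = 0;
  for (int j = 0; j < n; ++j) {
    cum += hist[j];
    if (j + 1 < n && obs_sorted[j + 1] == obs_sorted[j]) continue;
    double diff = (double) (j + 1) / n - (double) cum / n_null;
    if (diff > best) { best = diff; best_b = obs_sorted[j]; }
  }
  A = best;
  bstar = best_b;
}

// first index j with obs_sorted[j] >= v, i.e. the histogram bin of v
static inline size_t bin_of(const std::vector<double> &obs_sorted, double v) {
  return std::lower_bound(obs_sorted.begin(), obs_sorted.end(), v) -
         obs_sorted.begin();
}

// [[Rcpp::export]]
List antag_stat_cpp(NumericVector obs_sums, NumericVector null_sums) {
  std::vector<double> obs(obs_sums.begin(), obs_sums.end());
  std::sort(obs.begin(), obs.end());
  std::vector<long long> hist(obs.size() + 1, 0);
  for (double v : null_sums) ++hist[bin_of(obs, v)];
  double A, bstar;
  stat_from_hist(obs, hist, (double) null_sums.size(), A, bstar);
  return List::create(_["coefficient"] = A, _["best_intercept"] = bstar);
}

// One antagonism coefficient: the observed pairing against S random
// re-pairings of y (value multisets preserved, association destroyed).
static void coef_one(const std::vector<double> &x, const std::vector<double> &y,
                     int S, std::vector<int> &scr, std::vector<int> &p,
                     std::vector<double> &obs, std::vector<long long> &hist,
                     double &A, double &bstar) {
  const int n = (int) x.size();
  obs.resize(n);
  for (int i = 0; i < n; ++i) obs[i] = x[i] + y[i];
  std::sort(obs.begin(), obs.end());
  hist.assign(n + 1, 0);
  for (int s = 0; s < S; ++s) {
    draw_permutation(n, scr, p);
    for (int i = 0; i < n; ++i) ++hist[bin_of(obs, x[i] + y[p[i]])];
  }
  stat_from_hist(obs, hist, (double) n * S, A, bstar);
}

// [[Rcpp::export]]
List antag_coef_cpp(NumericVector x, NumericVector y, int n_null_shuffles) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<int> scr, p;
  std::vector<double> obs;
  std::vector<long long> hist;
  double A, bstar;
  coef_one(xv, yv, n_null_shuffles, scr, p, obs, hist, A, bstar);
  return List::create(_["coefficient"] = A, _["best_intercept"] = bstar);
}

// Permutation p-value machinery. RNG consumption order (replayable in R as
// a sequence of sample.int(n) calls): S permutations for the observed
// coefficient's null, then per permutation round one re-pairing permutation
// followed by S permutations for that round's null.
// [[Rcpp::export]]
List antag_pvalue_cpp(NumericVector x, NumericVector y,
                      int n_permutations, int n_null_shuffles) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<int> scr, p, r;
  std::vector<double> obs, yperm(n);
  std::vector<long long> hist;
  double A_obs, b_obs, A_m, b_m;
  coef_one(xv, yv, n_null_shuffles, scr, p, obs, hist, A_obs, b_obs);
  int n_ge = 0;
  for (int m = 0; m < n_permutations; ++m) {
    draw_permutation(n, scr, r);
    for (int i = 0; i < n; ++i) yperm[i] = yv[r[i]];
    coef_one(xv, yperm, n_null_shuffles, scr, p, obs, hist, A_m, b_m);
    if (A_m >= A_obs) ++n_ge;
  }
  double pv = (1.0 + n_ge) / (1.0 + n_permutations);
  return List::create(_["coefficient"] = A_obs, _["best_intercept"] = b_obs,
                      _["pvalue"] = pv, _["n_greater_eq"] = n_ge);
}
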