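#include <Rcpp.h>
using namespace Rcpp;

// Profiled multinomial log-likelihoods of the ten diploid hypotheses for
// every row of a site-by-individual count matrix. Hypothesis order matches
// the R-side HYPOTHESES table: A/A C/C G/G T/T A/C A/G A/T C/G C/T G/T.
// Rows with zero depth come back as NA.
// [[Rcpp::export]]
List cpp_hyp_logliks(NumericMatrix N, double eps_max) {
  const int M = N.nrow();
  NumericMatrix L(M, 10), E(M, 10);
  const int hyp_a[10] = {0, 1, 2, 3, 0, 0, 0, 1, 1, 2};
  const int hyp_b[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
  for (int i = 0; i < M; ++i) {
    double n = 0, lcoef = 0;
    double c[4];
    for (int a = 0; a < 4; ++a) {
      c[a] = N(i, a);
      n += c[a];
    }
    if (n <= 0) {
      for (int h = 0; h < 10; ++h) { L(i, h) = NA_REAL; E(i, h) = NA_REAL; }
      continue;
    }
    lcoef = R::lgammafn(n + 1);
    for (int a = 0; a < 4; ++a) lcoef -= R::lgammafn(c[a] + 1);
    for (int h = 0; h < 10; ++h) {
      const int a = hyp_a[h], b = hyp_b[h];
      double eps, ll = lcoef;
      if (a == b) {
        const double ni = c[a];
        eps = 4.0 * (n - ni) / (3.0 * n);
        if (eps > eps_max) eps = eps_max;
        if (ni > 0) ll += ni * std::log(1.0 - 0.75 * eps);
        if (n - ni > 0) ll += (n - ni) * std::log(0.25 * eps);
      } else {
        const double nij = c[a] + c[b];
        eps = 2.0 * (n - nij) / n;
        if (eps > eps_max) eps = eps_max;
        if (nij > 0) ll += nij * std::log(0.5 - 0.25 * eps);
        if (n - nij > 0) ll += (n - nij) * std::log(0.25 * eps);
      }
      L(i, h) = ll;
      E(i, h) = eps;
    }
  }
  return List::create(_["loglik"] = L, _["epsilon"] = E);
}

// Ranked call core: per row, the best hypothesis (fixed-order tie-break
// A/A..G/T), its profiled epsilon and log-likelihood, and the runner-up
// log-likelihood. Rows with zero depth come back as NA / 0.
// [[Rcpp::export]]
List cpp_call_core(NumericMatrix N, double eps_max) {
  const int M = N.nrow();
  IntegerVector best(M);
  NumericVector l1(M), l2(M), eps1(M);
  const int hyp_a[10] = {0, 1, 2, 3, 0, 0, 0, 1, 1, 2};
  const int hyp_b[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
  for (int i = 0; i < M; ++i) {
    double n = 0;
    double c[4];
    for (int a = 0; a < 4; ++a) {
      c[a] = N(i, a);
      n += c[a];
    }
    if (n <= 0) {
      best[i] = NA_INTEGER;
      l1[i] = NA_REAL; l2[i] = NA_REAL; eps1[i] = NA_REAL;
      continue;
    }
    double lcoef = R::lgammafn(n + 1);
    for (int a = 0; a < 4; ++a) lcoef -= R::lgammafn(c[a] + 1);
    double top = -INFINITY, second = -INFINITY, top_eps = 0;
    int top_h = 0;
    for (int h = 0; h < 10; ++h) {
      const int a = hyp_a[h], b = hyp_b[h];
      double eps, ll = lcoef;
      if (a == b) {
        const double ni = c[a];
        eps = 4.0 * (n - ni) / (3.0 * n);
        if (eps > eps_max) eps = eps_max;
        if (ni > 0) ll += ni * std::log(1.0 - 0.75 * eps);
        if (n - ni > 0) ll += (n - ni) * std::log(0.25 * eps);
      } else {
        const double nij = c[a] + c[b];
        eps = 2.0 * (n - nij) / n;
        if (eps > eps_max) eps = eps_max;
        if (nij > 0) ll += nij * std::log(0.5 - 0.25 * eps);
        if (n - nij > 0) ll += (n - nij) * std::log(0.25 * eps);
      }
      if (ll > top) {
        second = top;
        top = ll; top_h = h; top_eps = eps;
      } else if (ll > second) {
        second = ll;
      }
    }
    best[i] = top_h + 1;
    l1[i] = top; l2[i] = second; eps1[i] = top_eps;
  }
  return List::create(_["best"] = best, _["l1"] = l1, _["l2"] = l2,
                      _["eps1"] = eps1);
}

// Counter-based substream RNG (splitmix64): each window/round gets its own
// stream from a 32-bit seed, so bootstrap results are independent of the
// order in which windows are processed.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// uniform index in [0, n) by 64x32-bit multiply-shift
static inline int rand_index(uint64_t &state, uint32_t n) {
  const uint32_t x = (uint32_t)(splitmix64(state) >> 32);
  return (int)(((uint64_t)x * n) >> 32);
}

// One window's bootstrap tail counts: for each replicate every contributing
// site draws a (value, weight) pair uniformly from the genome-wide pool and
// the kernel-weighted average is recomputed. Replicates equal to the
// observed value count toward both tails.
// [[Rcpp::export]]
IntegerVector cpp_window_boot(double obs, NumericVector kern,
                              NumericVector pool_v, NumericVector pool_w,
                              double reps, double seed) {
  const int m = kern.size();
  const uint32_t npool = (uint32_t)pool_v.size();
  const double *kp = kern.begin(), *vp = pool_v.begin(), *wp = pool_w.begin();
  uint64_t state = (uint64_t)seed;
  long long ge = 0, le = 0;
  const long long R_n = (long long)reps;
  for (long long r = 0; r < R_n; ++r) {
    double num = 0, den = 0;
    for (int s = 0; s < m; ++s) {
      const int i = rand_index(state, npool);
      const double kw = kp[s] * wp[i];
      num += kw * vp[i];
      den += kw;
    }
    const double val = num / den;
    if (val >= obs) ++ge;
    if (val <= obs) ++le;
  }
  return IntegerVector::create((int)std::min<long long>(ge, INT_MAX),
                               (int)std::min<long long>(le, INT_MAX));
}

// Windowed Tajima's D bootstrap: replicates redraw per-site
// (pi, SNP indicator, n_k) triples and recompute D. Undefined replicates
// (fewer than 2 SNPs, n below 3, or a zero variance term) count toward
// neither tail. Returns (ge, le, undefined).
// [[Rcpp::export]]
IntegerVector cpp_tajima_boot(double obs, int m, NumericVector pool_pi,
                              NumericVector pool_snp, NumericVector pool_nk,
                              double reps, double seed) {
  const uint32_t npool = (uint32_t)pool_pi.size();
  uint64_t state = (uint64_t)seed;
  long long ge = 0, le = 0, und = 0;
  for (double r = 0; r < reps; ++r) {
    double S = 0, pi_sum = 0, nk_sum = 0;
    for (int s = 0; s < m; ++s) {
      const int i = rand_index(state, npool);
      S += pool_snp[i];
      pi_sum += pool_pi[i];
      nk_sum += pool_nk[i];
    }
    const int n = (int)std::lround(nk_sum / m);
    if (S < 2 || n < 3) { ++und; continue; }
    double a1 = 0, a2 = 0;
    for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
    const double b1 = (n + 1.0) / (3.0 * (n - 1.0));
    const double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
    const double c1 = b1 - 1.0 / a1;
    const double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
    const double v = c1 / a1 * S + c2 / (a1 * a1 + a2) * S * (S - 1.0);
    if (v <= 0) { ++und; continue; }
    const double d = (pi_sum - S / a1) / std::sqrt(v);
    if (d >= obs) ++ge;
    if (d <= obs) ++le;
  }
  return IntegerVector::create((int)ge, (int)le, (int)und);
}
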