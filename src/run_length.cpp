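#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo run lengths of the lower-one-sided clipped EWMA chart.
//
// Each replicate draws residuals either i.i.d. with replacement from
// `pool` (bootstrap) or from the standard normal, shifts them downward by
// `delta`, iterates F_t = min(lam*v + (1-lam)*F_{t-1}, xi) from z0, and
// stops at the first t with F_t < LCL(t); runs reaching `horizon` without a
// signal are censored there. Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List rl_simulate_cpp(NumericVector pool, bool normal_stream, double lam,
                     double L, double xi, double z0, double mu_e,
                     double sigma_e, bool time_varying, double delta,
                     int horizon, int reps) {
  const int n = pool.size();
  IntegerVector rl(reps);
  LogicalVector signaled(reps);
  const double q = (1.0 - lam) * (1.0 - lam);
  const double base = lam / (2.0 - lam);
  const double asym = mu_e - L * sigma_e * std::sqrt(base);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    double F = z0;
    double qt = 1.0;       // (1 - lam)^(2t), updated each step
    bool settled = !time_varying;
    int t = 0;
    bool sig = false;
    while (t < horizon) {
      ++t;
      double v;
      if (normal_stream) {
        v = norm_rand();
      } else {
        int idx = (int)(unif_rand() * n);
        if (idx >= n) idx = n - 1;
        v = pool[idx];
      }
      v -= delta;
      F = lam * v + (1.0 - lam) * F;
      if (F > xi) F = xi;
      double lim;
      if (!settled) {
        qt *= q;
        if (qt < 1e-18) settled = true;
        lim = mu_e - L * sigma_e * std::sqrt(base * (1.0 - qt));
      } else {
        lim = asym;
      }
      if (F < lim) { sig = true; break; }
    }
    rl[r] = t;
    signaled[r] = sig;
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["run_length"] = rl, _["signaled"] = signaled);
}
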