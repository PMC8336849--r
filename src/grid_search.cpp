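#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive least-squares grid evaluation for the demand-gated one-unit
// model with activity coefficients fixed at 1 (total activity equals
// total abundance, so demand gating compares abundance directly).
//
// obs/obs_step: observed levels and the model step index each maps to
//   (sorted ascending, duplicates allowed; step 0 is the initial state).
// surv: one row per survival-rate candidate, columns d_0..d_{n-1}.
// pulse: candidate pulse levels, ascending.
// demand: one row per demand candidate, columns DA_t for t = 1..n_steps.
// init: one row per initial-age-distribution candidate, expressed as
//   multipliers of the pulse level (ages 0..n).
//
// Totals are accumulated in long double, matching R's sum(), so that a
// candidate equal to the generating parameters reproduces the simulated
// series bit-for-bit and attains SSE exactly zero.
//
// Enumeration order pulse -> survival -> demand -> init with strict
// improvement implements the documented tie-break (smaller pulse first,
// then the survival ordering supplied by the caller); the caller orders
// survival rows by preference.
// [[Rcpp::export]]
List grid_search_cpp(NumericVector obs, IntegerVector obs_step,
                     NumericMatrix surv, NumericVector pulse,
                     NumericMatrix demand, NumericMatrix init,
                     int n_steps, bool return_all = false) {
  const int m = obs.size();
  const int n_surv = surv.nrow();
  const int n_pulse = pulse.size();
  const int n_dem = demand.nrow();
  const int n_init = init.nrow();
  const int n_age1 = surv.ncol() + 1;
  if (demand.ncol() < n_steps) stop("demand rows shorter than horizon");
  if (init.ncol() != n_age1) stop("init rows must cover ages 0..n");

  double best_sse = R_PosInf;
  int bi_p = NA_INTEGER, bi_s = NA_INTEGER, bi_d = NA_INTEGER,
      bi_i = NA_INTEGER;
  NumericVector all_sse;
  if (return_all) {
    double total = (double)n_pulse * n_surv * n_dem * n_init;
    if (total > 5e7) stop("grid too large for return_all");
    all_sse = NumericVector((int)total);
  }
  std::vector<double> b(n_age1);
  R_xlen_t flat = 0;

  for (int ip = 0; ip < n_pulse; ++ip) {
    const double p = pulse[ip];
    for (int is = 0; is < n_surv; ++is) {
      for (int id = 0; id < n_dem; ++id) {
        for (int ii = 0; ii < n_init; ++ii, ++flat) {
          long double tb = 0.0L;
          for (int x = 0; x < n_age1; ++x) {
            b[x] = init(ii, x) * p;
            tb += b[x];
          }
          double prev_tb = (double)tb;
          double sse = 0.0;
          int j = 0;
          while (j < m && obs_step[j] == 0) {
            const double e = prev_tb - obs[j];
            sse += e * e;
            ++j;
          }
          for (int t = 1; t <= n_steps; ++t) {
            for (int x = n_age1 - 1; x >= 1; --x) {
              b[x] = b[x - 1] * surv(is, x - 1);
            }
            b[0] = 0.0;
            if (prev_tb < demand(id, t - 1)) b[0] = p;
            long double acc = 0.0L;
            for (int x = 0; x < n_age1; ++x) acc += b[x];
            prev_tb = (double)acc;
            while (j < m && obs_step[j] == t) {
              const double e = prev_tb - obs[j];
              sse += e * e;
              ++j;
            }
            if (!return_all && sse > best_sse) {
              // skip remaining observations: cannot beat the incumbent
              j = m;
              break;
            }
          }
          if (return_all) all_sse[flat] = (j < m) ? NA_REAL : sse;
          if (j >= m && sse < best_sse) {
            best_sse = sse;
            bi_p = ip + 1; bi_s = is + 1; bi_d = id + 1; bi_i = ii + 1;
          }
        }
      }
    }
  }
  List out = List::create(
    _["sse"] = best_sse, _["i_pulse"] = bi_p, _["i_surv"] = bi_s,
    _["i_demand"] = bi_d, _["i_init"] = bi_i,
    _["n_evaluated"] = (double)n_pulse * n_surv * n_dem * n_init);
  if (return_all) out["all_sse"] = all_sse;
  return out;
}
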