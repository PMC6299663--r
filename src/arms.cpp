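// Adaptive rejection Metropolis sampling (ARMS) on a bounded interval.
//
// The proposal envelope is the piecewise function
//   h_i(x) = max{ l_{i,i+1}(x), min{ l_{i-1,i}(x), l_{i+1,i+2}(x) } }
// on [x_i, x_{i+1}], where l_{jk} is the chord of the log-target through
// abscissae j and k.  An undefined chord is replaced by its defined partner
// inside max/min; when every chord in the combination is undefined the
// segment value is the constant 0.  exp(h) is a piecewise exponential
// density that is sampled by inverse CDF per linear piece.  Rejected
// proposals are added to the abscissa set (envelope refinement) and a final
// Metropolis correction makes the draw exact even when the envelope does
// not dominate the target.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() at the R
// level makes every draw reproducible.

#include "ncrm_arms.h"

using namespace Rcpp;

// ---- R-facing wrappers (used by the exported R API and the tests) --------

struct RFunTarget {
  Function f;
  double operator()(double x) const { return as<double>(f(x)); }
};

// [[Rcpp::export(name = ".cpp_build_envelope")]]
List cpp_build_envelope(NumericVector abscissae, NumericVector log_values,
                        double lower, double upper) {
  std::vector<double> x(abscissae.begin(), abscissae.end());
  std::vector<double> hx(log_values.begin(), log_values.end());
  ncrm::Envelope env = ncrm::build_envelope(x, hx, lower, upper);
  return List::create(_["breaks"] = wrap(env.brk), _["slope"] = wrap(env.slope),
                      _["intercept"] = wrap(env.icpt),
                      _["log_mass"] = wrap(env.logmass),
                      _["log_omega"] = env.log_omega);
}

static ncrm::Envelope env_from_list(List e) {
  ncrm::Envelope env;
  NumericVector brk = e["breaks"], sl = e["slope"], ic = e["intercept"],
                lm = e["log_mass"];
  env.brk.assign(brk.begin(), brk.end());
  env.slope.assign(sl.begin(), sl.end());
  env.icpt.assign(ic.begin(), ic.end());
  env.logmass.assign(lm.begin(), lm.end());
  env.log_omega = as<double>(e["log_omega"]);
  return env;
}

// [[Rcpp::export(name = ".cpp_envelope_eval")]]
NumericVector cpp_envelope_eval(List env, NumericVector x) {
  ncrm::Envelope e = env_from_list(env);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = e.eval(x[i]);
  return out;
}

// [[Rcpp::export(name = ".cpp_sample_envelope")]]
NumericVector cpp_sample_envelope(List env, int n) {
  ncrm::Envelope e = env_from_list(env);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ncrm::sample_envelope(e);
  return out;
}

// [[Rcpp::export(name = ".cpp_arms_draw")]]
double cpp_arms_draw(Function log_target, double lower, double upper,
                     double previous, int n0_init, int max_rejects) {
  RFunTarget f{log_target};
  return ncrm::arms_draw_core(f, lower, upper, previous, n0_init, max_rejects);
}
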