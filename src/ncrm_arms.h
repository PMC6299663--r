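#ifndef NCRM_ARMS_H
#define NCRM_ARMS_H

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace ncrm {

struct Line {
  double slope, icpt;
  bool defined;
  Line() : slope(0.0), icpt(0.0), defined(false) {}
  Line(double s, double c) : slope(s), icpt(c), defined(true) {}
  double at(double x) const { return slope * x + icpt; }
};

inline Line chord(double xa, double ha, double xb, double hb) {
  double s = (hb - ha) / (xb - xa);
  return Line(s, ha - s * xa);
}

// Pointwise value of max{A, min{B, C}} under the undefined-chord
// conventions; 0 when everything is undefined.
inline double combine_at(const Line &A, const Line &B, const Line &C,
                         double x) {
  double inner = 0.0;
  bool has_inner = false;
  if (B.defined && C.defined) {
    inner = std::min(B.at(x), C.at(x));
    has_inner = true;
  } else if (B.defined) {
    inner = B.at(x);
    has_inner = true;
  } else if (C.defined) {
    inner = C.at(x);
    has_inner = true;
  }
  if (A.defined && has_inner) return std::max(A.at(x), inner);
  if (A.defined) return A.at(x);
  if (has_inner) return inner;
  return 0.0;
}

// log of the integral of exp(c + s x) over [u, v]
inline double seg_logmass(double s, double c, double u, double v) {
  double t = s * (v - u);
  if (std::fabs(t) < 1e-10)
    return c + s * u + 0.5 * t + std::log(v - u);
  if (t > 0.0)
    return c + s * v + std::log1p(-std::exp(-t)) - std::log(s);
  return c + s * u + std::log1p(-std::exp(t)) - std::log(-s);
}

struct Envelope {
  std::vector<double> brk;            // m+1 breakpoints spanning [lower, upper]
  std::vector<double> slope, icpt;    // m linear pieces
  std::vector<double> logmass;        // m piece log-integrals
  double log_omega;                   // log total mass

  double eval(double x) const {
    // right-open pieces; clamp to the support
    std::size_t m = slope.size();
    if (x <= brk.front()) return slope[0] * brk.front() + icpt[0];
    if (x >= brk.back()) return slope[m - 1] * brk.back() + icpt[m - 1];
    std::size_t i =
        std::upper_bound(brk.begin(), brk.end(), x) - brk.begin() - 1;
    if (i >= m) i = m - 1;
    return slope[i] * x + icpt[i];
  }
};

// Build the envelope from sorted abscissae (interior to [lower, upper]) and
// their log-target values.  Segments between consecutive breakpoints are
// subdivided at chord intersections so each stored piece is exactly linear.
inline Envelope build_envelope(const std::vector<double> &x,
                               const std::vector<double> &hx, double lower,
                               double upper) {
  int n = (int)x.size();
  Envelope env;
  // chords between consecutive abscissae: chords[k] through (x[k], x[k+1])
  std::vector<Line> chords(std::max(n - 1, 0));
  for (int k = 0; k + 1 < n; ++k)
    chords[k] = chord(x[k], hx[k], x[k + 1], hx[k + 1]);

  // base segments: [lower, x0], [x0, x1], ..., [x_{n-1}, upper]
  for (int seg = 0; seg <= n; ++seg) {
    double L = (seg == 0) ? lower : x[seg - 1];
    double R = (seg == n) ? upper : x[seg];
    if (R - L <= 0.0) continue;
    Line A, B, C;
    if (seg >= 1 && seg <= n - 1) A = chords[seg - 1];   // l_{i,i+1}
    if (seg >= 2) B = chords[seg - 2];                   // l_{i-1,i}
    if (seg <= n - 2) C = chords[seg];                   // l_{i+1,i+2}

    // subdivide at pairwise intersections of the defined chords
    std::vector<double> cuts;
    cuts.push_back(L);
    const Line *lines[3] = {&A, &B, &C};
    for (int a = 0; a < 3; ++a)
      for (int b2 = a + 1; b2 < 3; ++b2) {
        if (!lines[a]->defined || !lines[b2]->defined) continue;
        double ds = lines[a]->slope - lines[b2]->slope;
        if (std::fabs(ds) < 1e-300) continue;
        double xi = (lines[b2]->icpt - lines[a]->icpt) / ds;
        if (xi > L && xi < R) cuts.push_back(xi);
      }
    cuts.push_back(R);
    std::sort(cuts.begin(), cuts.end());
    for (std::size_t j = 0; j + 1 < cuts.size(); ++j) {
      double u = cuts[j], v = cuts[j + 1];
      if (v - u <= 0.0) continue;
      double hu = combine_at(A, B, C, u), hv = combine_at(A, B, C, v);
      double s = (hv - hu) / (v - u);
      double c = hu - s * u;
      env.brk.push_back(u);
      env.slope.push_back(s);
      env.icpt.push_back(c);
      env.logmass.push_back(seg_logmass(s, c, u, v));
    }
  }
  env.brk.push_back(upper);

  // log-sum-exp of the piece masses
  double mx = *std::max_element(env.logmass.begin(), env.logmass.end());
  double acc = 0.0;
  for (double lm : env.logmass) acc += std::exp(lm - mx);
  env.log_omega = mx + std::log(acc);
  if (!R_finite(env.log_omega))
    stop("degenerate ARMS envelope (zero or non-finite total mass)");
  return env;
}

// one draw from the piecewise exponential density exp(hull)/omega
inline double sample_envelope(const Envelope &env) {
  std::size_t m = env.slope.size();
  double u = unif_rand();
  double cum = 0.0;
  std::size_t pick = m - 1;
  for (std::size_t i = 0; i < m; ++i) {
    cum += std::exp(env.logmass[i] - env.log_omega);
    if (u <= cum) {
      pick = i;
      break;
    }
  }
  double a = env.brk[pick], b = env.brk[pick + 1];
  double s = env.slope[pick];
  double t = s * (b - a);
  double w = unif_rand();
  if (std::fabs(t) < 1e-10) return a + w * (b - a);
  if (t > 0.0) return b + std::log(w + (1.0 - w) * std::exp(-t)) / s;
  return a + std::log1p(w * std::expm1(t)) / s;
}

// One ARMS transition for an arbitrary callable log-target.
template <class F>
double arms_draw_core(F log_target, double lower, double upper, double previous,
                      int n0_init, int max_rejects) {
  std::vector<double> xs, hs;
  xs.reserve(n0_init + max_rejects);
  hs.reserve(n0_init + max_rejects);
  for (int k = 1; k <= n0_init; ++k) {
    double xv = lower + (upper - lower) * (double)k / (double)(n0_init + 1);
    double hv = log_target(xv);
    if (!R_finite(hv))
      stop("non-finite log-target at an initial ARMS abscissa");
    xs.push_back(xv);
    hs.push_back(hv);
  }

  for (int rejects = 0; rejects <= max_rejects; ++rejects) {
    Envelope env = build_envelope(xs, hs, lower, upper);
    double xstar = sample_envelope(env);
    double lp = log_target(xstar);
    double lh = env.eval(xstar);
    double u = unif_rand();
    if (std::log(u) > lp - lh) {
      // rejected: refine the envelope with the rejected point and retry
      if (R_finite(lp)) {
        std::size_t pos =
            std::upper_bound(xs.begin(), xs.end(), xstar) - xs.begin();
        xs.insert(xs.begin() + pos, xstar);
        hs.insert(hs.begin() + pos, lp);
      }
      continue;
    }
    // Metropolis correction (exact even for non-log-concave targets)
    double lp_prev = log_target(previous);
    double lh_prev = env.eval(previous);
    double lnum = lp + std::min(lp_prev, lh_prev);
    double lden = lp_prev + std::min(lp, lh);
    double log_acc = std::min(0.0, lnum - lden);
    if (std::log(unif_rand()) > log_acc) return previous;
    return xstar;
  }
  stop("ARMS exceeded max_rejects envelope refinements");
  return previous;  // not reached
}

}  // namespace ncrm


#endif  // NCRM_ARMS_H
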