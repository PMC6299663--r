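// ARMS-within-Gibbs sampler for the Dirichlet-process dose-toxicity model.
//
// State: ordered toxicity probabilities p_1 < ... < p_S for the S tried
// doses (p_0 = 0, p_{S+1} = 1), DP precision alpha, and base-distribution
// parameters (mu, sigma) on discrete grids.  Per sweep:
//   - alpha: independence Metropolis with a U(1,20) proposal against the
//     conditional kernel Gamma(alpha)/prod Gamma(gamma_i) *
//     prod (dp_i)^{gamma_i-1} * alpha^{a-1} e^{-b alpha};
//   - (mu, sigma): exact categorical draw over the product grid from the
//     same Dirichlet kernel with gamma recomputed per grid pair;
//   - each p_i: one ARMS transition on (p_{i-1}, p_{i+1}) targeting
//     p^y (1-p)^{n-y} (p - p_{i-1})^{gamma_i - 1} (p_{i+1} - p)^{gamma_{i+1}-1}.
//
// gamma_i = alpha * w_i with w_i the base-CDF increments over the dose
// partition; w_{S+1} = 1 - F0(d_S) absorbs all untried upper doses.

#include "ncrm_arms.h"

using namespace Rcpp;

namespace {

// base-CDF increments w_1..w_{S+1} for doses d (length S) at (mu, sigma)
std::vector<double> cdf_increments(const std::vector<double> &d, double mu,
                                   double sigma) {
  std::size_t S = d.size();
  std::vector<double> w(S + 1);
  double prev = 0.0;
  for (std::size_t k = 0; k < S; ++k) {
    double Fk = R::pnorm((d[k] - mu) / sigma, 0.0, 1.0, 1, 0);
    w[k] = Fk - prev;
    prev = Fk;
  }
  w[S] = 1.0 - prev;
  // clamp away from exact zero so gamma_i > 0 always holds
  for (double &wi : w) wi = std::max(wi, 1e-300);
  return w;
}

// log Dirichlet kernel sum_i (gamma_i - 1) log(dp_i) with gamma = alpha * w
double log_dirich_kernel(const std::vector<double> &logdp,
                         const std::vector<double> &w, double alpha) {
  double out = 0.0;
  for (std::size_t i = 0; i < w.size(); ++i)
    out += (alpha * w[i] - 1.0) * logdp[i];
  return out;
}

double sum_lgamma_gamma(const std::vector<double> &w, double alpha) {
  double out = 0.0;
  for (double wi : w) out += R::lgammafn(alpha * wi);
  return out;
}

// Full conditional of p_i reparameterised by the logit of its position in
// the support interval: p = plo + (phi - plo) * sigmoid(t).  The Jacobian
// raises the interval exponents gamma - 1 to gamma, so the boundary
// singularities of the Dirichlet kernel (gamma < 1) disappear and both
// tails of the transformed density decay exactly exponentially — which a
// piecewise-exponential ARMS envelope represents faithfully, including the
// large mass the DP prior places on near-ties of adjacent probabilities.
struct TCondTarget {
  double y, nmy, gi, gip1, plo, phi;
  double operator()(double t) const {
    double lw = std::log(phi - plo);
    double d1 = lw - R::log1pexp(-t);  // log(p - plo)
    double d2 = lw - R::log1pexp(t);   // log(phi - p)
    double p = plo + (phi - plo) / (1.0 + std::exp(-t));
    double lp = (plo <= 0.0) ? d1 : std::log(p);
    double l1mp = (phi >= 1.0) ? d2 : std::log1p(-p);
    return y * lp + nmy * l1mp + gi * d1 + gip1 * d2;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_run_gibbs")]]
List cpp_run_gibbs(IntegerVector n, IntegerVector y, NumericVector doses,
                   double alpha_init, bool alpha_fixed, double a, double b,
                   NumericVector mu_grid, NumericVector sigma_grid,
                   bool eta_fixed, NumericVector p_init, int n_burnin,
                   int n_keep, int n0_init, int max_rejects, double eps) {
  int S = n.size();
  std::vector<double> d(doses.begin(), doses.end());
  std::vector<double> p(p_init.begin(), p_init.end());
  int Gm = mu_grid.size(), Gs = sigma_grid.size();

  double alpha = alpha_init;
  int mu_idx = Gm / 2, sg_idx = Gs / 2;  // grid centres as initial values
  double mu = mu_grid[mu_idx], sigma = sigma_grid[sg_idx];

  // base-CDF increments per (mu, sigma) grid pair, computed once
  std::vector<std::vector<double> > W((std::size_t)Gm * Gs);
  for (int i = 0; i < Gm; ++i)
    for (int j = 0; j < Gs; ++j)
      W[(std::size_t)i * Gs + j] = cdf_increments(d, mu_grid[i], sigma_grid[j]);
  const std::vector<double> *w = &W[(std::size_t)mu_idx * Gs + sg_idx];

  NumericMatrix p_draws(n_keep, S);
  NumericVector alpha_draws(n_keep), mu_draws(n_keep), sigma_draws(n_keep);

  std::vector<double> logdp(S + 1);
  std::vector<double> log_wts((std::size_t)Gm * Gs);

  int n_iter = n_burnin + n_keep;
  for (int it = 0; it < n_iter; ++it) {
    // increments of the current p (with padding 0 and 1)
    double prev = 0.0;
    for (int i = 0; i < S; ++i) {
      logdp[i] = std::log(std::max(p[i] - prev, eps));
      prev = p[i];
    }
    logdp[S] = std::log(std::max(1.0 - prev, eps));

    // --- alpha: independence Metropolis, proposal U(1, 20) ---------------
    if (!alpha_fixed) {
      double alpha_star = 1.0 + 19.0 * unif_rand();
      double lk_star = R::lgammafn(alpha_star) - sum_lgamma_gamma(*w, alpha_star) +
                       log_dirich_kernel(logdp, *w, alpha_star) +
                       (a - 1.0) * std::log(alpha_star) - b * alpha_star;
      double lk_cur = R::lgammafn(alpha) - sum_lgamma_gamma(*w, alpha) +
                      log_dirich_kernel(logdp, *w, alpha) +
                      (a - 1.0) * std::log(alpha) - b * alpha;
      if (std::log(unif_rand()) <= std::min(0.0, lk_star - lk_cur))
        alpha = alpha_star;
    }

    // --- (mu, sigma): exact categorical over the product grid ------------
    if (!eta_fixed) {
      double mx = R_NegInf;
      for (std::size_t g = 0; g < W.size(); ++g) {
        double lw = -sum_lgamma_gamma(W[g], alpha) +
                    log_dirich_kernel(logdp, W[g], alpha);
        log_wts[g] = lw;
        if (lw > mx) mx = lw;
      }
      double tot = 0.0;
      for (std::size_t g = 0; g < W.size(); ++g) {
        log_wts[g] = std::exp(log_wts[g] - mx);
        tot += log_wts[g];
      }
      double u = unif_rand() * tot, cum = 0.0;
      std::size_t pick = W.size() - 1;
      for (std::size_t g = 0; g < W.size(); ++g) {
        cum += log_wts[g];
        if (u <= cum) {
          pick = g;
          break;
        }
      }
      mu_idx = (int)(pick / Gs);
      sg_idx = (int)(pick % Gs);
      mu = mu_grid[mu_idx];
      sigma = sigma_grid[sg_idx];
      w = &W[pick];
    }

    // --- p_i | rest via one ARMS transition each (logit position) --------
    for (int i = 0; i < S; ++i) {
      double plo = (i == 0) ? 0.0 : p[i - 1];
      double phi = (i == S - 1) ? 1.0 : p[i + 1];
      double width = phi - plo;
      double yi = (double)y[i], nmyi = (double)(n[i] - y[i]);
      double gi = alpha * (*w)[i], gip1 = alpha * (*w)[i + 1];
      TCondTarget tgt{yi, nmyi, gi, gip1, plo, phi};
      // Support wide enough that the mass beyond it is negligible: the
      // transformed tails decay at rates (left) gamma_i [+ y_i if p_{i-1}
      // is 0] and (right) gamma_{i+1} [+ (n_i-y_i) if p_{i+1} is 1], so
      // +-45/rate truncates ~e^{-45} relative mass.  The interval is also
      // anchored at the current point and at the observed toxicity rate so
      // a data-dominated mode near an interval edge stays covered.
      double rate_l = gi + ((plo <= 0.0) ? yi : 0.0);
      double rate_r = gip1 + ((phi >= 1.0) ? nmyi : 0.0);
      double frac = (p[i] - plo) / width;
      frac = std::min(std::max(frac, 1e-300), 1.0 - 1e-16);
      double tcur = std::log(frac / (1.0 - frac));
      double tlo = std::min(-45.0 / rate_l, tcur - 30.0);
      double thi = std::max(45.0 / rate_r, tcur + 30.0);
      if (n[i] > 0) {
        double fr_data = (yi / (double)n[i] - plo) / width;
        if (fr_data > 0.0 && fr_data < 1.0) {
          double tdata = std::log(fr_data / (1.0 - fr_data));
          tlo = std::min(tlo, tdata - 30.0);
          thi = std::max(thi, tdata + 30.0);
        }
      }
      tlo = std::max(tlo, -1e7);
      thi = std::min(thi, 1e7);
      tcur = std::min(std::max(tcur, tlo + 1e-8), thi - 1e-8);
      double tnew = ncrm::arms_draw_core(tgt, tlo, thi, tcur, n0_init,
                                         max_rejects);
      double pnew = plo + width / (1.0 + std::exp(-tnew));
      // censor at machine resolution; ordering stays strict
      if (pnew <= plo) pnew = std::nextafter(plo, 1.0);
      if (pnew >= phi) pnew = std::nextafter(phi, 0.0);
      p[i] = pnew;
    }

    if (it >= n_burnin) {
      int q = it - n_burnin;
      for (int i = 0; i < S; ++i) p_draws(q, i) = p[i];
      alpha_draws[q] = alpha;
      mu_draws[q] = mu;
      sigma_draws[q] = sigma;
    }
  }

  return List::create(_["p"] = p_draws, _["alpha"] = alpha_draws,
                      _["mu"] = mu_draws, _["sigma"] = sigma_draws);
}
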