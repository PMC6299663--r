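---
title: "Nonparametric Bayesian dose finding with a Dirichlet-process prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric Bayesian dose finding with a Dirichlet-process prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrm)
```

## The problem

A single-agent phase I trial assigns small cohorts of patients to one of
$K$ pre-specified dose levels $d_1 < \dots < d_K$ and counts dose-limiting
toxicities (DLTs). The goal is the maximum tolerated dose (MTD): the dose
whose toxicity probability is closest to a target $\theta$ (0.3
throughout the built-in scenarios). The classical continual reassessment
method (CRM) assumes a one-parameter curve $F(d_k;\beta)$; when that curve
is misspecified the design can stall below the MTD or escalate unsafely.
`ncrm` instead treats the dose-toxicity curve as an unknown nondecreasing
function and places a Dirichlet process (DP) prior on it, so the only
structural assumption is monotonicity.

## The model

With $p_k = F(d_k)$ and per-dose counts $(n_k, y_k)$,

$$y_k \mid p_k \sim \mathrm{Bin}(n_k, p_k), \qquad
  F \mid \alpha, \mu, \sigma \sim \mathrm{DP}\big(\alpha\, F_0(\cdot \mid
  \mu, \sigma)\big),$$

where $F_0(x) = \Phi\{(x-\mu)/\sigma\}$ is the prior central curve and the
precision $\alpha$ measures how tightly $F$ concentrates around $F_0$.
Over the partition induced by the $S$ tried doses (untried upper doses are
absorbed into the residual increment $1 - p_S$), the increments of
$(p_1, \dots, p_S, 1)$ are Dirichlet with weights
$\gamma_i = \alpha\{F_0(d_i) - F_0(d_{i-1})\}$, giving the prior kernel
$\prod_i (p_i - p_{i-1})^{\gamma_i - 1}$. Two immediate consequences are
used as test oracles throughout the package: $E[p_k] = F_0(d_k)$ exactly
for every $\alpha$, and for $S = 1$ the posterior is
$\mathrm{Beta}(y_1 + \gamma_1,\; n_1 - y_1 + \gamma_2)$ in closed form.

$(\mu, \sigma)$ are chosen so the median of $F_0$ sits at the prior MTD
guess ($F_0(d_\nu) = \theta$). When they are treated as unknown they get
discrete uniform priors on equally spaced grids over
$[\mu_0 \pm r_\mu]$ and $[\sigma_0 \pm r_\sigma]$ (ten points per axis by
default; non-positive $\sigma$ grid points are dropped), and $\alpha$ gets
a Gamma(shape $a$, rate $b$) hyperprior — the shape/rate convention is
forced by the $\alpha^{a-1}e^{-b\alpha}$ factor in its full conditional.

## Posterior computation

The joint posterior of $(p, \alpha, \mu, \sigma)$ is explored with a Gibbs
sweep:

* **$\alpha$** — independence Metropolis with a $U(1, 20)$ proposal
  against its conditional kernel
  $\Gamma(\alpha)/\prod_i\Gamma(\gamma_i)\cdot\prod_i \Delta p_i^{\gamma_i-1}
  \cdot \alpha^{a-1}e^{-b\alpha}$. With a uniform independence proposal no
  proposal-density correction is needed, but the chain consequently lives
  in $[1, 20]$; this is documented rather than "fixed", and the fixed-
  $\alpha$ mode skips the step entirely.
* **$(\mu, \sigma)$** — both priors are discrete on small grids, so the
  draw is an exact categorical sample over the product grid (normalised in
  log space). Drawing jointly rather than $\mu$ then $\sigma$ has the same
  stationary distribution and a simpler correctness argument; a sequential
  option is retained (`gibbs_update_mu_sigma(..., joint = FALSE)`).
* **each $p_i$** — one adaptive rejection Metropolis sampling (ARMS)
  transition on its full conditional, supported on $(p_{i-1}, p_{i+1})$.
  The envelope is the classical piecewise-linear hull built from chords of
  the log target, $h_i = \max\{l_{i,i+1}, \min\{l_{i-1,i},
  l_{i+1,i+2}\}\}$, sampled as a piecewise exponential and refined with
  every rejected proposal; a final Metropolis correction keeps the draw
  exact even where the hull does not dominate.

### Numerical choices

The Dirichlet weights at realistic precisions are small
($\gamma_i \approx 0.03$ for low doses at $\alpha = 5$), so the
conditional of $p_i$ has integrable singularities at both interval ends
and places a large share of its mass on near-ties
$p_i - p_{i-1} < 10^{-10}$ — the discreteness of the DP showing through.
A bounded piecewise-exponential envelope on the probability scale cannot
reach that mass (we measured a factor-two bias in low-dose prior means
before addressing this). The implementation therefore runs the ARMS
transition on the logit of the position of $p_i$ within its support
interval: the Jacobian raises both exponents by one, removing the
singularities, and the transformed tails decay exactly exponentially, so
the envelope matches them asymptotically. The support in the transformed
scale extends $45/\mathrm{rate}$ into each tail (truncating about
$e^{-45}$ of mass) and is additionally anchored at the current state and
the observed toxicity rate; draws beyond machine resolution are censored
to the nearest representable neighbour, which preserves every posterior
summary the design consumes. Kernel evaluations clamp log-increments at
$\varepsilon = 10^{-10}$; all mass computations are done in log space with
log-sum-exp.

Sampler defaults follow the study conditions: 1000 retained draws after
700 burn-in iterations per refit, five initial envelope abscissae, and
independent refits after every cohort (no chain carry-over), initialised
at the scenario skeleton restricted to the tried doses. All randomness
flows through R's RNG, so a seed makes entire simulated trials
bit-reproducible.

## The two-stage design

Stage I treats cohort 1 at $d_1$ and escalates one level per toxicity-free
cohort. At the first toxicity the design switches to stage II: the next
cohort repeats the current dose, and after every subsequent cohort the
posterior is refit and $\Pr(p_k < \theta)$ at the current dose is compared
with thresholds $c_e$ (escalate above it) and $c_d$ (de-escalate below
it), moving at most one level and staying inside $[d_1, d_K]$. We read the
published escalation rules' final branch as "stay at the current dose"
(its printed subscript $K$ is a typo — the boundary case at $d_K$ is
already covered by the escalation rule), and $\Pr(\hat p_k < \theta)$ as
the posterior probability $\Pr(p_k < \theta)$, the only reading that
yields a probability comparable with a threshold. If no toxicity is ever
observed the trial completes stage I at $d_K$ and MTD selection still runs
at the end. At $N$ patients the tried dose with posterior mean toxicity
closest to $\theta$ is selected (ties to the lower dose).

The thresholds are design parameters chosen by simulation, and published
operating characteristics rarely print them. `calibrate_thresholds()`
makes that choice reproducible: a grid search over threshold pairs
(escalation candidates $0.50, \dots, 0.90$; de-escalation candidates
$0.40, \dots, 0.90$) subject to $c_e + c_d > 1$, maximising the
probability of selecting the scenario's target dose over pilot
replicates. The de-escalation grid deliberately extends below 0.5:
when the target dose's true toxicity sits at $\theta$ and the base curve
puts $F_0 \approx \theta$ there, the posterior $\Pr(p_k < \theta)$ at the
MTD hovers near 0.5, so any $c_d \ge 0.5$ forces perpetual de-escalation
from the correct dose. Calibration pilots on the steadily-increasing
scenario (at both small and large fixed precision) show correct-selection
is flat across admissible pairs; the defaults $c_e = 0.70$, $c_d = 0.35$
were fixed once from those pilots — they reproduce the small-$\alpha$
allocation and selection profile across the built-in scenarios — and then
left alone.

## CRM comparators

Two one-parameter CRMs are included. The empiric (power) model is
$p_k(\beta) = p_{0k}^{\exp(\beta)}$ on the skeleton $p_{0k}$ — the
standard reading of a "power model on doses $1..8$", which is the only one
yielding probabilities. The one-parameter logistic model uses standardised
doses $x_k = \mathrm{logit}(p_{0k}) - a_0$ with fixed intercept $a_0 = 3$,
so $\beta = 1$ recovers the skeleton; raw dose labels with $a_0 = 3$ would
put every dose near toxicity 1 at the prior mean. The prior
$\beta \sim N(0, 1.34)$ treats 1.34 as a variance (the convention of the
reference CRM software). $\hat\beta$ is the posterior mean computed by
trapezoidal quadrature on $[-10, 10]$ with 4001 nodes (stable to
$<10^{-6}$ under node doubling; verified against a $10^5$-node brute-force
grid). Skeletons come from the indifference-interval recursion anchored at
$p_{0\nu} = \theta$, with the per-scenario half-widths
$\delta = 0.05, 0.075, 0.03, 0.04, 0.07, 0.05$.

Comparator trials start at $d_1$ and move one level at a time toward the
model recommendation $\arg\min_k |p_k(\hat\beta) - \theta|$. The
publication is silent on the comparators' start-up; the shared one-step
rule keeps the comparison fair and every simulated trial — either engine —
satisfies the same mechanics (exactly $N$ patients, one-level moves),
which the test suite asserts.

## What the simulator emulates — and what it does not

`builtin_scenarios()` ships the six study scenarios (true curves,
skeletons, base-curve parameters, target doses). Outcomes are independent
Bernoulli draws at the assigned dose's true toxicity; replicated trials
use per-trial seeds drawn once from a master seed, so operating
characteristics are reproducible and order-insensitive. The simulator does
not model accrual time, within-patient correlation, late-onset toxicity,
or early stopping for excessive toxicity (the study conditions simulate
without a stopping rule, noting a real trial would stop); passing tests
therefore say nothing about those aspects of real trials.

Full-fidelity runs use 1000 trials with 700/1000 MCMC per refit. The test
suite and the bundled acceptance script run a scaled-down mode — 150–300
trials with 300 burn-in / 400 retained draws — whose Monte-Carlo error on
selection probabilities is about $\sqrt{p(1-p)/200} \le 0.035$; the
problem sizes are stated next to each reported number.

## A note on selection sharpness at the target

When a scenario places a dose's true toxicity exactly at $\theta$ (dose 5
of the first built-in scenario), the neighbouring sub-MTD dose is
selected in roughly 15% of simulated trials at $N = 60$, for every
threshold pair we examined and at full MCMC fidelity. This is binomial
noise, not a sampler or design defect: with ~35 patients at the MTD the
empirical toxicity rate there ends above ~0.40 often enough that the
posterior mean at the under-dosed neighbour (itself pulled up by the
monotone coupling) wins the closest-to-target rule by a small margin.
Reported selection probabilities near 1 for such scenarios should be
read with this in mind: a posterior whose data-weak coordinates remain
at their initial values (a risk for boundary-singular samplers in the
raw probability parameterisation — see the numerical-choices section)
anchors the MTD estimate at the skeleton's target and makes selection
look sharper than the data support. The over-toxic scenarios (5 and 6)
do not have this ambiguity and the design selects the lowest dose
essentially always.

## Known limitations

* The $\alpha$ chain cannot leave $[1, 20]$; Gamma hyperpriors with
  substantial mass outside that interval are effectively truncated.
* Near-tie increments below $10^{-10}$ are visible to the $p$ updates but
  entered into the $\alpha$ and $(\mu, \sigma)$ kernels at the clamp
  value, a regularisation that matters only when hyperparameters are
  unknown *and* the posterior concentrates on ties.
* Only the normal-CDF base family is implemented, behind `base_cdf()` so
  another CDF could be swapped in; uniform or empirical-Bayes bases are
  sometimes mentioned in this literature but never exercised here.
* No product-of-beta prior, no two-agent extension, no toxicity/efficacy
  (phase I/II) joint modelling.
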