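---
title: "Superstatistical models and amortized neural Bayesian filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superstatistical models and amortized neural Bayesian filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(superstat)
```

## The model family

Most mechanistic models of behavior treat their parameters as fixed for the
duration of an experiment. `superstat` instead treats them as a latent time
series: a *low-level* observation model generates one data point per time
step from the current parameter row $\theta_t$, while a *high-level*
transition model with static parameters $\eta$ moves $\theta_t$ across
steps,

$$\theta_t = \mathcal{T}(\theta_{0:t-1}, \eta, \xi_t), \qquad
  x_t = \mathcal{G}(x_{1:t-1}, \theta_t, z_t),$$

with $\theta_0$ drawn from its prior. This superposition of two stochastic
processes on different time scales is the superstatistics view of
non-stationary data. The estimation target is the *filtering posterior*
$p(\theta_t, \eta \mid x_{1:t})$ at every prefix length $t$ — the belief
about the current dynamic state and the static transition parameters given
the data so far.

Two observation models are built in:

* **Poisson counts** with rate $\lambda$ (events per step). This is the
  classic benchmark setting of annual accident counts: the rate is allowed
  to drift as a Gaussian random walk on a bounded range.
* **The diffusion decision model (DDM)**: within a trial, evidence $x$
  accumulates as $dx = v\,dt + \sqrt{dt}\,z$, $z \sim \mathcal{N}(0,1)$,
  from a starting point $a/2$ between absorbing boundaries at $0$ and $a$;
  the response time adds a non-decision constant $\tau$. Parameters are the
  drift rate(s) $v$ (evidence/s, optionally one per condition), boundary
  separation $a$, and $\tau$ (s).

Transition models: `static`, Gaussian `random_walk`
($\theta_t = \theta_{t-1} + \sigma \odot \xi_t$), vector autoregression
(`var`), a Gaussian process (`gp`) with squared-exponential kernel
$k(t,t') = \sigma^2 \exp(-(t-t')^2 / 2\ell^2)$ over the time grid
normalized to $[0,1]$ (so length-scales do not depend on $T$),
`regime_switch` (uniform jumps at pre-declared times), and `itv`
(memoryless inter-trial variability). Note the kernel is over *time
indices*; its amplitude and length-scales are the static parameters.

### Support handling

Gaussian transitions are only well-defined on unconstrained spaces, so the
DDM's positive parameters $a$ and $\tau$ evolve on the log scale; the
observation model receives the back-transformed values, and hard support
bounds (e.g. $a \in [0.05, 6]$) are enforced by clamping on the transformed
scale. The Poisson rate is the one deliberate exception: the lattice filter
that serves as the exact oracle propagates a Gaussian kernel in $\lambda$
units on $[0, 15]$, so the generator uses a natural-scale walk clamped to
the same range — otherwise the oracle would be a *misspecified* reference
for the neural method, and the two could never be compared cleanly.

GP trajectories are pinned to their initial value: the unconditional SE
draw is conditioned on a zero fluctuation at $t = 0$, so row 0 of every
trajectory equals the prior draw $\theta_0$ and multi-horizon prediction
can seed a fresh GP at a posterior draw of the current state.

### Default priors

$\lambda_0 \sim \mathrm{Exp}(0.5)$ and random-walk scale
$\sigma \sim \mathrm{Beta}(1, 25)$ for the Poisson benchmark (the
informative priors of that literature). For the DDM,
$v \sim \mathcal{N}(0, 2.5)$ per condition, $a \sim \Gamma(4, 3)$,
$\tau \sim \Gamma(1.5, 5)$, and per-parameter walk scales
$\sigma_k \sim \mathrm{Beta}(1, 25)$ acting on the transformed scale. GP
amplitudes use $\Gamma(1.5, 5)$ and length-scales $\Gamma(5, 10)$ (mass on
0.2–1 on the normalized grid, i.e. smooth but not flat trajectories); VAR
intercepts $\mathcal{N}(0, 0.5)$, diagonal AR weights
$\mathrm{U}(0.5, 0.95)$ (stable regimes). These are declared per model and
overridable through the YAML declaration file; the DDM values are field-
plausible defaults rather than canonical constants.

## First-passage simulation

DDM trials are simulated by Euler–Maruyama with step `dt` (default 1 ms)
plus a within-step Brownian-bridge crossing check: between endpoints inside
the corridor, the continuous path crossed the upper boundary with
probability $\exp(-2(a - x_t)(a - x_{t+1})/dt)$. Plain discrete monitoring
overestimates first-passage times by $O(\sqrt{dt})$ — about 0.02 s at
`dt = 1e-3`, several Monte-Carlo standard errors at $10^4$ trials — while
the bridge-corrected simulator matches the closed-form choice probability
$1/(1 + e^{-va})$ and mean decision time $(a/2v)\tanh(va/2)$ within MC
error, and halving `dt` moves nothing beyond MC noise. Trials that fail to
absorb by `t_max` (10 s default) are flagged, kept, and excluded from
likelihood-based analyses; silently resampling them would bias the tails.
The analytic Wiener first-passage density (small-time/large-time series
with truncation bounds chosen for ≤ 1e-6 absolute error) is included purely
as a cross-checking oracle for the simulator.

Training simulations use a coarser `dt = 2.5e-3`: with the bridge
correction the residual discretization error is far below the posterior
uncertainty the network learns, and simulation is the dominant training
cost.

## Grid filtering (the low-dimensional oracle)

For the Poisson + random-walk model the joint filtering posterior is
computed exactly-to-resolution: a $\lambda$ lattice per $\sigma$ lattice
point, alternating Gaussian-kernel prediction (truncated at the lattice
edges and renormalized — reflection would distort mass near 0) and Bayes
updates in log space with max-shift normalization. The $\sigma$ posterior
at time $t$ weights each $\sigma$'s accumulated point-wise evidence;
reported means/SDs of $\lambda_t$ marginalize over it. Defaults are
200 × 40 points (a desk-scale compromise; the historical benchmark's
4000-point resolution is a preset, and doubling the resolution moves the
final posterior mean by under 0.1%). With $\sigma = 0$ the filter
reproduces the conjugate Gamma posterior to better than 0.5% at 200 points
— the module's primary correctness anchor.

## The amortized neural filter

No deep-learning framework is assumed: the approximator is a single-layer
LSTM (hidden width 128 by default in the field; 64 here, where it already
saturates the desk-scale benchmarks) written with hand-derived
backpropagation through time on top of `RcppArmadillo`, plus a conditional
Gaussian posterior head. The head targets the ancestral factorization

$$q(\theta_t, \eta \mid x_{1:t}) = q(\eta \mid h_t)\,
  q(\theta_t \mid h_t, \eta),$$

where $h_t$ is the LSTM state after consuming $x_{1:t}$ (so the state is
causal by construction). Both factors are diagonal Gaussians in
*standardized, transformed* parameter space — log scale for positive
parameters, scaled logit for bounded static parameters — so back-
transformed draws always respect supports, and the head can represent
skewed (log-normal-shaped) posteriors on the natural scale. A coupling-flow
head would add expressiveness for multi-modal posteriors; the filtering
posteriors of the models shipped here are unimodal, every validation
statistic used is a mean/SD/rank functional, and a hand-backpropagated flow
would have added substantial defect risk, so the Gaussian head is the
implemented choice and a known limitation.

Training minimizes the Monte-Carlo estimate of
$\mathbb{E}\,[-\sum_{t=1}^{T} \log q(\theta_t, \eta \mid x_{1:t})]$ over
simulated records $(\eta, \theta_{0:T}, x_{1:T})$ — online (fresh
simulations per batch) or offline (a fixed store). Inputs (counts, or
log-RT plus signed choice plus one-hot condition) and targets are
standardized with constants frozen from a pilot simulation (2000 records
for Poisson, 300 for the DDM — moment estimates are stable there and DDM
simulation dominates cost); the constants travel inside every checkpoint,
which also stores weights, architecture, model declaration, and transforms.
Optimization: Adam with cosine learning-rate decay (2e-3 → 1e-4), global
gradient-norm clipping at 5, forget-gate bias initialized to 1. Log-SDs
are clamped to $[-7, 7]$. Per-batch series lengths are drawn uniformly
from a configured range, so one network accepts any length inside it.
Backpropagation is verified against finite differences in the test suite.

Desk-scale training budgets used throughout the tests and the acceptance
script: 2000 batches of 32 (T = 110) for the Poisson network, 3000 batches
of 32 (T ∈ [100, 400]) for the DDM network — minutes on one CPU, after
which filtering any number of series costs seconds (`amortized_filter` is
one forward pass plus head sampling at every prefix).

## Validation toolbox

* **SBC**: ranks of true parameters among posterior draws across simulated
  records must be uniform; assessed by a KS test on jittered normalized
  ranks plus an exact Beta order-statistic ECDF band (Bonferroni over
  evaluation points). The exact conjugate sampler passes; a +0.5-shifted
  sampler is rejected — the positive and negative controls for the
  machinery itself.
* **Recovery**: per-parameter median absolute error over time, median
  posterior SD over time with MAD band, and truth-vs-posterior-mean
  correlations at chosen time points.
* **Retrodiction**: re-simulate the observed span from per-$t$ posterior
  draws; median and equal-tailed 95% band, optionally smoothed.
* **Multi-horizon prediction**: propagate aligned $(\theta_{t_0}, \eta)$
  draws through fresh transition trajectories and simulate future
  observables.
* **MMD**: unbiased U-statistic with Gaussian kernel and median-heuristic
  bandwidth (recorded in the output attributes); verified against a brute-
  force double loop.
* **SMA**: trailing moving average with prefix means, so output length
  equals input length.

## What the generators emulate — and what passing tests do not show

The synthetic generators reproduce the structure of the benchmark settings:
a 110-step count series with a slowly drifting rate; 100-observation static
DDM series; 400-step DDM series under four scenarios (static, inter-trial
variability, random walk, regime switching with jumps at t = 100, 200,
300); multi-condition GP-DDM series. They do not emulate features of real
behavioral data such as fast-guess contaminants, post-error slowing,
session/block boundaries, or any misspecification of the DDM itself, so
green tests certify computational faithfulness and recovery *within the
model family*, not adequacy for any particular empirical data set.

## Numerical and design notes

* Interpretation choices on ambiguous aggregate checks: the multi-horizon
  coverage check counts a replicate as covered when at least 95% of its
  smoothed held-out points fall inside the 95% band, and at least 90% of
  replicates must be covered (pointwise coverage of 100 positively
  correlated points makes strict all-points containment a much harsher
  event than the nominal level suggests).
* On data simulated from a *static* DDM, the posterior-mean trajectory of
  the dynamic model still fluctuates: with a walk-scale prior
  $\mathrm{Beta}(1,25)$, the *exact* lattice filter in the analogous
  Poisson setting shows a median over-time SD of the posterior mean around
  0.4 of the marginal posterior SD. That fluctuation is a property of the
  correct Bayesian answer under a drift-allowing prior, not an artifact of
  the approximation; the trained network sits at the same level, and its
  posterior SD still contracts by roughly half between t = 5 and t = 100.
  A stricter "no pseudo-dynamics" bar is only reachable with a much tighter
  drift-scale prior.
* Seed handling: every simulation record derives transition-noise and
  observation-noise substreams from its seed, so observation noise is
  reproducible independently of trajectory noise and records are
  bit-identical under a stored seed.
* The regime-switch jump bounds default to a plausible transformed-scale
  box (v ∈ [−6, 6], a ∈ [0.5, 3], τ ∈ [0.1, 1] s); switch times default to
  100/200/300 for T = 400.
* Degenerate inputs: zero amplitudes/scales reduce every transition to the
  static case exactly; `n = 0` posterior draws yield empty, well-formed
  containers; empty series and malformed files are rejected with row-level
  diagnostics.

## Known limitations

Diagonal Gaussian head (no multi-modality); no hierarchical multi-subject
structure; no fat-tailed transition models; no model comparison across
transition models; grids beyond two low-level dimensions are out of scope
by design (that curse of dimensionality is the reason the neural path
exists). Early-trial estimates depend strongly on the prior and should be
read with caution — burn-in trials are the practical remedy.
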