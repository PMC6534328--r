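---
title: "Clusters-of-Samples models of Mode and Mean estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clusters-of-Samples models of Mode and Mean estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosens)
```

## The problem

When an observer watches a long stream of one-dimensional samples — say 70
vertical lines flashed at different horizontal positions — and is then
asked for the *Mode* (where the lines were densest) and the *Mean* (their
average position), the reports show systematic, condition-dependent
errors. `cosens` implements a family of observer models for this task and
the machinery to simulate, fit and compare them.

The central hypothesis is a compressed representation: rather than
remembering the samples, the observer groups them on the fly into clusters
and retains only each cluster's centroid $c_k$ and relative weight
$w_k = n_k / N$, the set $\{(c_k, w_k)\}_{k=1}^K$ — the
**Clusters-of-Samples (CoS)** representation.

## The models

### Clustering stage (ddCRP)

Clustering is a distance-dependent Chinese Restaurant Process used purely
as a stochastic clustering algorithm: each sample $j$ joins exactly one
other sample $l$ with probability

$$P_{\text{join}}(j, l) \propto \exp(-d_{jl}^2 / \gamma), \qquad l \ne j,$$

and clusters are the connected components of the join graph. The scale
$\gamma$ (cm²) is the model's key free parameter: small $\gamma$ joins
only immediate neighbours and fragments the sample set; large $\gamma$
lets join chains span whole density bumps, so clusters align with the
mixture components of the stimulus. Because self-joins are excluded (with
70 samples the stay-alone probability of the general process is
negligible and is set to zero), every cluster has at least two members.
The process is stochastic, so a single stimulus induces a *distribution*
over representations; it is approximated by a Monte-Carlo ensemble of
$R$ independent clusterings (1000 by default).

Two properties anchor the implementation and are enforced by tests:

* **Mean conservation.** For any partition,
  $\sum_k c_k w_k$ equals the sample mean at machine precision — the
  clustering itself cannot bias Mean estimates.
* **Exactness at small n.** For $n \le 8$ the package enumerates all
  $(n-1)^n$ join vectors (`enumerate_partitions()`), and the sampler's
  partition distribution matches this oracle in total variation.

### Mode read-out

The Mode report is the centroid $C^*$ of the heaviest cluster (exact
weight ties broken uniformly at random), passed through a linear response
stage with Gaussian noise,
$Y = \beta_0 + \beta_1 C^* + \mathcal{N}(0, \sigma_\text{mode}^2)$.
The response density is the Monte-Carlo mixture over the ensemble's
per-draw $C^*_j$, evaluated with log-sum-exp. The linear stage captures
the regression-to-the-mean typical of magnitude estimation; it is shared
by every model in the package, so model comparison hinges on the internal
estimate, not on the response stage.

### Shared representation and the Mean read-out

Both reports on a trial are assumed to derive from the *same* clustering.
Having observed the Mode response, the posterior probability that draw
$j$ was the representation in use is
$P_{\text{set}}(j) \propto \mathcal{N}(y_\text{mode};\, C^*_j,\,
\sigma_\text{mode}^2)$. As printed in the source equations the comparison
uses the raw $C^*_j$, not $\beta_0 + \beta_1 C^*_j$; the package follows
the printed form (the transformed alternative would be a one-line change
in `set_posterior()` but is deliberately not exposed, to keep the fitted
models comparable).

The Mean report is a weighted centroid average
$M^* = \sum_k c_k \theta_k$ with subjective weights

$$\theta_k \propto \frac{w_k^{\alpha}}
  {\sum_j w_j \exp\!\big(-(c_j - c_k)^2 / 2\sigma_{LI}^2\big)}.$$

The power transform ($\alpha$) produces probability distortion —
$\alpha < 1$ overweights small clusters; the shunting denominator
implements lateral inhibition with Gaussian spatial falloff
($\sigma_{LI}$, cm) — clusters with close, heavy neighbours are
down-weighted. With $\alpha = 1$ and $\sigma_{LI} \to \infty$,
$\theta = w$ and the Mean read-out is exactly the sample mean. The Mean
likelihood mixes $M^*_j$ over $P_{\text{set}}$. Lesion switches
(`cos_lesions()`) drop either transform, or replace $P_{\text{set}}$ by a
uniform mixture ("w/o Prior"), giving the model-lesion battery.

### Baselines

* **Subjective weighting (SW):** the same transforms applied directly to
  the $N$ samples without clustering; since raw sample weights are equal,
  only lateral inhibition survives. Samples in dense regions are
  down-weighted, which biases the weighted mean away from heavy clumps —
  enough to mimic skewness-dependent Mean errors, making SW the critical
  control for whether clustering itself earns its keep.
* **Ideal observer (IO):** a Dirichlet-process mixture of equal-precision
  Gaussians with uniform base measure on $[-20, 20]$ cm,
  $\tau \sim \Gamma(1, \beta_\tau)$, $\beta_\tau \sim \Gamma(1,1)$, and
  concentration $\alpha \sim \Gamma(\alpha_c, 1)$. Inference is Gibbs
  sampling with the auxiliary-component scheme (m = 3 auxiliary tables)
  for the non-conjugate base, truncated-normal updates for cluster means,
  gamma updates for $\tau$ and $\beta_\tau$, and the beta-augmentation
  update for $\alpha$. The observer reports the posterior average of the
  per-draw mixture mean and mode. The specific non-conjugate variant and
  the concentration update are implementation choices; the source only
  names the sampler family.
* **Moment regressions:** $Y = \beta_0 + \sum_j \beta_j Z_j + \epsilon$
  over subsets of {true mode, true mean, true skewness} (GT, MoMe, MeSk,
  MoSk, MoMeSk). Variance is never a predictor because all stimuli share
  one SD. Predictors are used raw (cm; skewness dimensionless) so that
  $\beta_1 \approx 1$ reads as an unbiased identity response. Their MLE
  is ordinary least squares with the biased variance estimate, so these
  fits are closed-form.

## Stimuli

A trial's 70 samples come from a mixture of 3 or 4 beta-shaped components
on contiguous unit intervals $[0,1], [1,2], \dots$ (equal widths, joined
ends). Shapes $(\alpha,\beta) \in \{(3.1,1.1), (2.9,2.9), (1.1,3.1)\}$
give negatively-skewed, symmetric and positively-skewed components of
equal variance (component SD $\approx 0.19$ of its width); weights are
permutations of $(0.2, 0.3, 0.5)$ or $(0.1, 0.2, 0.3, 0.4)$. Samples are
rescaled to the design's exact target SD (7.27 / 7.20 / 7.55 cm for
E1 / E2 / E3) and shifted by a jitter drawn uniformly over the largest
interval keeping the mean within ±3.8 cm and all samples within ±20 cm;
if no jitter is feasible the trial is redrawn. Scaling and jitter are
affine, so sample skewness is untouched.

Two generator choices deserve emphasis:

* **Exact component counts.** Component $i$ contributes exactly
  $\mathrm{round}(70\,\phi_i)$ samples (14/21/35 for weights 2/3/5)
  rather than a multinomial draw. With multinomial counts the
  cluster-size histogram could not show sharp local maxima exactly at
  14/21/35 — per-trial counts would smear them over ±3 — whereas those
  sharp peaks are precisely the reported signature of component-aligned
  clusterings. Stratified allocation reproduces it and makes the
  per-condition structure identical across trials.
* **Jitter law.** Only the admissible ranges are specified upstream; the
  uniform law over the feasible interval is this package's choice.

The "true" statistics a response is scored against are those of the 70
samples actually shown: the arithmetic mean, the population skewness
$m_3 / m_2^{3/2}$, and the mode defined as the highest peak of a
diffusion kernel density estimate (Botev's fixed-point bandwidth,
computed via DCT on a $2^{12}$-point grid over $[-20, 20]$ cm; grid
argmax ties resolve to the lowest coordinate). The diffusion estimator is
implemented in the package and was verified against an independent port
of the reference algorithm to nine decimal places of bandwidth.

## Fitting and model comparison

All models are fitted per subject by maximum likelihood. Deterministic
response parameters use a bounded Nelder-Mead simplex (a sine-transform
onto box constraints) from Latin-hypercube multistarts; the stochastic
parameters — $\gamma$ for CoS, $\alpha_c$ for IO — are grid-searched
(ranges 0.02–2.00 and 0.10–3.00), with the inner fit re-optimised at each
grid point and warm starts carried along the grid. Default bounds:
$\beta_0 \in [-10, 10]$ cm, $\beta_1 \in [0, 3]$,
$\sigma \in [10^{-3}, 20]$ cm (the floor keeps noise-free simulations
finite), $\alpha \in [0.05, 5]$, $\sigma_{LI} \in [0.1, 50]$ cm.
Ensembles and DPMM posteriors depend only on (stimulus, grid value,
seed), so they are cached once and shared across subjects and tasks;
every cache key includes the seed, making refits bit-reproducible.

Goodness of fit is AICc, $2\,\mathrm{NLL} + 2k + 2k(k+1)/(n-k-1)$ with
$n$ the subject's trial count; free-parameter counts are CoS 4 (mode) / 5
(mean), SW 4, IO 4 / 3, moment models $q+2$. Group-level comparison uses
random-effects Bayesian model selection with $-\mathrm{AICc}/2$ as the
log-evidence approximation (the method family accepts any evidence
approximation; none is named upstream): variational Dirichlet updates,
exceedance probabilities by posterior sampling ($10^5$ draws), and
protected exceedance probabilities
$\mathrm{PXP} = (1-\mathrm{BOR})\,\mathrm{EP} + \mathrm{BOR}/K$.

## What the simulations emulate — and what they do not

The synthetic cohorts (`simulate_cohort()`) share one sample set across
subjects, shuffle nothing that matters to fitting, and draw each
subject's parameters around the package defaults — $\gamma = 0.5$ cm²,
$\alpha = 0.7$, $\sigma_{LI} = 4$ cm, $\beta_0 = 0$, $\beta_1 = 1$,
$\sigma_\text{mode} = 2$ cm, $\sigma_\text{mean} = 1.5$ cm, ±10%
multiplicative jitter (±0.5 cm on $\beta_0$). The response-parameter
values describe a mildly-regressing, moderately noisy observer typical of
position estimation; $\gamma = 0.5$ sits mid-grid, and $\alpha < 1$ with
a few-cm $\sigma_{LI}$ produces the qualitative error signatures
(Mode error ordered by local skewness, Mean error increasing with global
skewness, and the 253 > 352 non-monotonicity). These are the package's
chosen study conditions, fixed once.

Passing recovery tests show that *under these conditions* the fitting
machinery identifies the generating model and parameters. They do not
show that human data follow the CoS model: real observers contribute
sequential-presentation effects, lapses, motor noise that is not
Gaussian, and trial-order dependencies that the generator deliberately
omits.

## Numerical choices

* Join probabilities are computed with max-subtracted exponents, so
  $\gamma \to 0$ never underflows; duplicate positions are legal and
  join each other with maximal probability.
* The Mode-task likelihood and the $P_{\text{set}}$ mixture use
  log-sum-exp throughout; posterior weights are floored at $10^{-300}$
  before logging.
* DPMM mixture modes are read off a 0.01-cm grid (ties to the lowest
  coordinate); sub-grid refinement is pointless next to posterior spread.
* Degenerate inputs fail loudly: fewer than 2 samples or all-identical
  positions (KDE), samples outside the base support (DPMM),
  non-positive $\sigma$ or $\gamma$, unknown design or model ids.
* Exact weight ties in the Mode read-out are broken uniformly at random
  from the run's RNG stream (unbiased; upstream sources are silent).

## Problem sizes used by the shipped tests

The test-suite and the acceptance script scale the study down to keep a
complete run comfortable on one CPU, as a deliberate design choice of
the package's own validation: recovery cohorts of 6–8 subjects on the
full 162-trial E1 design, $R = 200$ clusterings per ensemble, a 10-point
$\gamma$ grid and a 3-point $\alpha_c$ grid, ideal-observer chains of
2 × 250–300 iterations, and error-signature cohorts of 16 subjects
without fitting. At these sizes model recovery is clear-cut (the
generating CoS model wins both tasks with protected exceedance
probabilities near 1), and parameter recovery lands within a grid step
($\gamma$) or a few percent (response parameters).

## Known limitations

* The DPMM's posterior-average density is systematically a little
  sharper-peaked than the diffusion KDE of the same samples (L1 distance
  ≈ 0.15–0.2 on 3-beta stimuli): a handful of shared-precision Gaussians
  versus a 70-kernel smoother. For calibration, a Silverman-bandwidth KDE
  of the same samples sits about twice as far (L1 ≈ 0.35) from the
  diffusion KDE, so the ideal observer tracks the empirical density
  closely in relative terms.
* Orientation designs (S1) are treated on a linear 0–180° scale centred
  at 90° with the E1 target SD; no circular statistics are used, which is
  adequate only because the stimuli span less than a half-circle.
* The ddCRP is a clustering algorithm here, not a prior: no posterior
  inference over partitions given responses beyond the one-dimensional
  $P_{\text{set}}$ reweighting.
* The Mode-task intercept shows a small positive finite-sample ML bias
  (about +0.12 cm, ~6% of the response noise, at 162 trials) when fitting
  the Monte-Carlo mixture likelihood to data generated from a single
  shared clustering per trial. It is stable across ensemble sizes
  (R = 200 vs 1000) and grids, and is well inside one asymptotic standard
  error of the per-subject estimate, but worth knowing when interpreting
  fitted intercepts.
* Group BMS assumes exchangeable subjects and uses an AICc-based evidence
  approximation; fixed-effects Bayes factors, BIC and cross-validation
  are out of scope.
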