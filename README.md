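# cosens

Observer models for **ensemble perception of summary statistics**: how
people watching a stream of one-dimensional samples (e.g. 70 vertical
lines flashed at different horizontal positions) report the **Mode** and
the **Mean** of what they saw — and why those reports err systematically
with the skewness of the sample distribution.

The package is written for computational cognitive modellers who want to
simulate these experiments, fit the competing observer models to response
data, and run parameter- and model-recovery studies.

## The models

The core model is the **Clusters-of-Samples (CoS)** observer. Samples are
grouped by a distance-dependent Chinese Restaurant Process (ddCRP): each
sample *j* joins one other sample *l* with probability

    P(j joins l) ∝ exp(−d²ⱼₗ / γ),

and clusters are the connected components of the join graph. Only the
cluster centroids and relative weights {(cₖ, wₖ)} are retained. The Mode
report is the centroid of the heaviest cluster C\*; the Mean report is a
weighted centroid average Σₖ cₖ θₖ with subjective weights

    θₖ ∝ wₖ^α / Σⱼ wⱼ exp(−(cⱼ − cₖ)² / 2σ²_LI)

(power-transform probability distortion plus lateral inhibition). Both
reports pass through a linear response stage with Gaussian noise,
Y = β₀ + β₁X\* + N(0, σ²). The two tasks share one clustering per trial:
the Mode response induces a posterior over the Monte-Carlo clusterings
that the Mean likelihood mixes over.

Baselines: a **subjective-weighting** model (same transforms, no
clustering), a **DPMM ideal observer** (Dirichlet-process mixture of
equal-precision Gaussians, Gibbs-sampled), and **moment regressions** on
the true mode/mean/skewness. Fitting is per-subject maximum likelihood
(grid search over γ or α_c, bounded simplex for the rest), compared by
AICc and group-level random-effects Bayesian model selection with
protected exceedance probabilities (PXP).

## Worked example

Simulate a small cohort of CoS observers on the 162-trial 3-beta-mixture
design and fit the CoS model back:

```r
library(cosens)

design  <- build_design("E1", rng_seed = 1)     # 162 trials, SD 7.27 cm
stimuli <- sample_stimuli(design, rng_seed = 2) # 70 samples per trial

resp <- simulate_responses(
  stimuli, gamma = 0.5,
  mode_params = response_params(0, 1, 2),    # beta0, beta1, sigma_mode
  mean_params = response_params(0, 1, 1.5),
  alpha = 0.7, sigma_li = 4, rng_seed = 7)

cache <- ensemble_cache(
  stimuli, gammas = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2),
  R = 200, rng_seed = 3)
fit <- fit_cos_mode(resp$y_mode, cache, n_starts = 3, rng_seed = 11)
round(fit$params, 3)
#>      gamma      beta0      beta1 sigma_mode
#>      1.500     -0.099      0.934      1.996
round(fit$aicc, 4)
#> [1] 810.3592
```

The response stage is recovered sharply — β₀ ≈ −0.1 cm, β₁ ≈ 0.93 and a
noise estimate of 2.0 cm against the generating (0, 1, 2). The clustering
scale is a different story: for a *single* subject the γ profile is
nearly flat above ~0.35 (the minimised negative log-likelihood changes by
only ~2 nats between γ = 0.5 and 2), so the grid argmax here lands at
1.5 rather than the generating 0.5. Across a cohort the modal fitted γ
does sit on the generating value — that is exactly what the recovery
suite in `tests/testthat/test-acceptance.R` checks. The AICc (810.36
over 162 trials, 4 free parameters) is what model comparison sums and
differences across subjects; `compare_models()` turns a cohort's fit
table into summed ΔAICc and PXP.

Simulated cohorts reproduce the behavioural signatures of this task
family: Mode errors ordered by the skewness of the mixture components,
Mode errors non-monotonic in global skewness (condition 253 overshoots
352), Mean errors increasing with global skewness, and cluster-size
histograms peaking at the component sample counts 14/21/35
(`error_summary()`, `cluster_size_histogram()`).

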