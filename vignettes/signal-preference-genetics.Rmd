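---
title: "Quantitative genetics of signal-preference covariation with sigpref"
author: "sigpref authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of signal-preference covariation with sigpref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigpref)
```

## The problem

Sexual signals and the mate preferences for them often coevolve. The
simplest within-population engine for that coevolution is a genetic
correlation between the male signal trait and the female preference for it:
once assortative mating couples the two, selection on either drags the
other along. Whether such correlations exist, and how large the underlying
genetic variation is relative to species differences, is an empirical
question that full-sibling, split-family rearing experiments can answer.

`sigpref` implements the complete analysis chain for such an experiment in
plant-feeding treehoppers whose mate recognition runs on plant-borne
vibrational signals. Males are recorded for the dominant frequency (Hz) of
their advertisement signal; females are assayed with playback stimuli that
sweep frequency across the species range, and the number of duetting
responses at each stimulus frequency traces out a *preference function*
whose argmax is the female's *peak preference*. Both traits are sex-limited:
no individual carries both, so the signal-preference genetic correlation is
only estimable through relatives — here, full-sib families split across
rearing plants.

## Design and simulated world

A full-sib family is one once-mated female's brood, split across two
rearing plants per sex ("replicates"), which separates family (genetic +
maternal) variance from rearing-environment variance. Because families are
full sibs, the "additive" component mixes additive and nonadditive
variance; we keep the conventional V_A label but it is a family-genetic
component (see Limitations).

`simulate_experiment()` generates this world with known architecture:

* family effects drawn from a 2x2 between-family covariance matrix `G`
  over (signal frequency, peak preference); under full-sib coding
  V_A = 2 diag(G) and the family-level correlation r = G12 / sqrt(G11 G22);
* replicate effects per (family, sex, plant), variance `V_rep` per trait;
* within-family individual deviations, variance `V_within` (for a coherent
  world `V_within >= diag(G)`, the Mendelian half of V_A);
* male observed signal = latent value + measurement noise averaged over a
  configurable number of recorded signals (default 3; experiments differ
  in how many signals are recorded per male, so this is a free knob);
* female playback responses: counts at 19 stimulus frequencies (species
  mean +/- 2, 4, 6, 8, 10, 15, 20, 30, 40 Hz), negative binomial around a
  Gaussian-shaped curve centred at the latent peak.

Defaults state a world calibrated to the *Ptelea*-living species:
mean signal 338 Hz; signal V_A = 64.2 Hz^2 (h^2 = 0.5, CV_A = 2.37),
preference V_A = 80.8 Hz^2 (h^2 = 0.20, CV_A = 2.66), family-level
correlation -0.14; median ~10 females and ~14 males per family. The
preference width default (18 Hz SD, per-female SD 4) makes responses fall
below ~10% of the peak at the grid edges, the typical shape of these
preference functions; the response-count distribution (negative binomial,
dispersion 0.05, reducing to Poisson at 0) and the lognormal
response-level spread (0.3) are constrained only by unimodality and
overdispersion, which is all the data demand. All draws flow from one seed in a
fixed, documented stream order, so identical configurations are
byte-identical.

The inclusion filter retains families with at least two individuals per
sex per replicate cell (both sexes for correlation-stage analyses, the
focal sex for heritability-stage analyses).

## Preference functions

Each female's trials are fit with a natural cubic smoothing spline
(`stats::smooth.spline`, knots at the distinct stimulus values). The
smoothing parameter is chosen by generalized cross-validation minimized
over a documented log-spaced grid of 41 smoothing parameters spanning
`1e-8` to `1e2`, ties broken
toward heavier smoothing, so constant data yield maximal smoothing and the
procedure is deterministic. The peak preference is the argmax of the
fitted curve on a 0.1 Hz dense grid restricted to the tested stimulus
range (no extrapolated maxima); exact ties go to the lowest frequency.
Flat curves (range below 1e-6 response units) are flagged and excluded
downstream; boundary peaks are flagged but kept (configurable), since dropping them
would discard real extreme-preference females.

A measured limitation: with noiseless data the spline recovers latent
peaks exactly (to the 0.1 Hz grid) wherever stimuli are 2 Hz apart
(species mean +/- 10 Hz); at 5 Hz spacing recovery is within ~0.2 Hz, and
in the 10 Hz-spaced tails interpolation error can reach ~3 Hz. No
smoothing-spline fit can beat the information in the grid, so tests and
acceptance checks state recovery over the densely sampled core.

## The mixed-model engine

All ANOVA-based stages share one engine. Each model term receives an
*effect space*: the column space of its indicator matrix swept of the
intercept and of every effect it contains (containment is detected
numerically, so nesting coded through unique labels is handled without
declarations). A term's partial (Type-III style) sum of squares is the
increment of its effect space after all others; on balanced designs this
reproduces classical ANOVA to 1e-8 (tested). Expected-mean-square
coefficients are computed by synthesis on the realized design
(`tr(Q_T Z_U Z_U') / df_T`), so unbalance from the inclusion filter is
handled; components from mean squares use method of moments (floored at
zero), while REML components come from `lme4` behind the same interface.

Denominators for F tests are synthesized: the engine solves for the
combination of random-term and residual mean squares whose expectation
matches the numerator's EMS minus its own component, with Satterthwaite
fractional degrees of freedom `(sum c_i MS_i)^2 / sum (c_i MS_i)^2 / df_i`.
Fixed-term mean squares are never used in denominators. Non-positive
synthesized denominators are floored at 1e-12 with a warning. On balanced
designs where a single mean square suffices, the combination collapses to
it exactly.

## Testing for genetic variation in preference-function shape

`fit_preference_variation()` models raw response counts on the Gaussian
scale (the convention in this literature) with family, replicate-in-family,
individual-in-replicate random intercepts, fixed linear and quadratic
stimulus regressors (mean-centred before squaring, making every F
statistic invariant to shifting the stimulus axis), and random family x
linear and family x quadratic interactions. The key test is family x
quadratic: family differences in the curvilinear aspect of the preference
function.

Two measured caveats, documented rather than hidden. Analysing
overdispersed counts on the Gaussian scale means the key test is only
calibrated against its own Gaussian null: with identical preference
functions and negative-binomial noise the test is strongly conservative
(stimulus-dependent count variance deflates the quadratic contrast), while
per-female *multiplicative* response-level spread inflates it (amplitude
heterogeneity is curvature heterogeneity, and the model carries only an
individual intercept). The calibration suite therefore simulates the
Gaussian null; a green calibration establishes that the F machinery is
correct, not that counts are Gaussian.

## The animal model

`fit_animal_model()` implements a Gibbs sampler for the Gaussian animal
model over the full-sib pseudo-pedigree (one invented, unrelated sire-dam
pair per family; `build_pseudo_pedigree()` and `additive_relationship()`
expose the pedigree and its A matrix, A = 0.5 between sibs, 0 across
families). Under exactly this pedigree the additive values decompose as
a_i = g_family + m_individual with Var = V_A/2 each; the samplers work in
that representation, which keeps every full conditional scalar or 2x2 and
runs full-length chains (1,000,000 iterations, 500,000 burn-in, thin 500
— `mcmc_config(preset = "full")`) in seconds. The desk preset
(50,000 / 25,000 / 25) is the default for simulation studies; on the same
data the two agree within the posterior spread.

Priors split the observed phenotypic variance of each trait equally among
the additive, replicate and residual components (taken as the sample
variance of the trait), with low degrees of
belief: scaled inverse chi-squared with nu = 1.002 per univariate
component, inverse Wishart with df = 2.002 for the 2x2 genetic covariance.
The test suite probes robustness to the split ratios. In the bivariate
model the residual covariance is fixed at exactly zero — each individual
carries one trait, so no residual cross-trait information exists — and the
genetic covariance is free; r_G = G12 / sqrt(G11 G22) per retained draw,
so |r_G| <= 1 and h^2 in [0, 1] hold sample-wise by construction.

Reporting follows the conventions of the standard animal-model MCMC
software: point estimates are kernel-density modes with the bandwidth
shrunk to 0.1x the display bandwidth; intervals are 95%
highest-posterior-density (shortest) windows, leftmost on ties (quantile
intervals are available from the raw samples). Lag-1 autocorrelation of retained samples is reported and
flagged above 0.1 rather than silently accepted. CV_A = 100 sqrt(V_A) /
trait mean, with the point value computed from the V_A point estimate and
the observed mean.

## The reaction-norm dissection

`reaction_norm_tests()` stacks female peaks and male signal means into one
response with a sex indicator, fits family, replicate and family x sex as
random and sex as fixed, and reports four tests:

* **family over a synthesized denominator** (the "SAS model"): tests
  r > 0 beyond genotype-level mismatch;
* **family over the residual MS** (the "Scheffe model"): do some families
  remain distinct averaged across sexes? This test does not assume equal
  variances across sexes; a Levene-style check is reported alongside,
  purely descriptively;
* **family x sex**: genotype-level signal-preference mismatch (r < 1);
* **sex** (over its synthesized denominator): population-level
  signal-preference mismatch, which speaks to the expected form of sexual
  selection.

Replicate is nested within family *and* sex by default (adults were
re-housed by sex onto separate plants); with that nesting the exact EMS
match for the family denominator collapses onto the interaction and
residual mean squares, while the `nesting = "family"` knob reproduces the
classical three-mean-square synthesis (replicate + interaction +
residual). Whenever the synthesized denominator is at least the residual
MS, SAS-model significance must imply Scheffe significance; the function
asserts this on every run.

`classify_scenario()` maps the four significance calls plus the per-sex
between-family variances onto the canonical taxonomy of
signal-preference variation regimes (`A`-`H`; see
`?scenario_architecture` for the generating presets). Because four tests
are consulted jointly, significance is called at alpha/4 (Bonferroni) by
default. The only picture-pair the tests cannot separate — mismatch with
both traits variable versus mismatch with an invariant preference — is
resolved by the preference/signal between-family variance ratio
(threshold 0.2), and genuinely conflicting patterns return
`"indeterminate"` rather than a forced label. Two structural facts shape
the presets: "pure crossing" is a Scheffe-null only when the
family-average variance is exactly zero (r = -1 with equal variances), and
replicate variance, which inflates the family MS over the residual, is
switched off so that classification reflects architecture alone.

## Comparative span

`span_fraction()` reports the among-family range of family means as a
fraction of the gap between the focal species mean and the most similar
sympatric species (resolved as the background species minimizing the
absolute signal-frequency difference). The shipped background table is
explicitly an approximate, partly synthetic stand-in (only the ~165 and
~315 Hz anchors are documented); supply real species means for real use.

## Numerical and engineering choices

* Random draws in the Gibbs samplers use an internal xoshiro256+ stream
  with Box-Muller normals, seeded from R's RNG: `set.seed()` fixes chains
  exactly, and the samplers avoid R's slower inversion-based normal
  generator at these chain lengths.
* Singular designs (a term confounded with the others) are an explicit
  error naming the term; constant responses yield all-zero components
  rather than errors.
* `ems_engine()` separates design-dependent projections from the response,
  so simulation studies (the calibration and power checks in the test
  suite) reuse one engine across thousands of simulated responses.

## What the tests establish — and what they do not

The suite calibrates type-I error of the five key F tests under Gaussian
nulls, verifies parameter recovery of the animal model (h^2 within 0.15 in
at least 90% of replicate fits at h^2 = 0, 0.2 and 0.5; 95% HPD coverage
of r at -0.8, 0 and 0.8), and verifies the scenario classifier against its
generating presets. None of this establishes that real treehopper counts
are Gaussian, that real preference functions are Gaussian-shaped, or that
nonadditive variance is absent; the generator emulates the design, not the
animal, and no particular historical dataset is a reproduction target.

## Known limitations

* Full-sib design: the "genetic" components mix additive, dominance and
  maternal variance; no additive/dominance decomposition is attempted.
* Counts are analysed on the Gaussian scale throughout; no generalized
  mixed models.
* Peak recovery is grid-limited in the sparse stimulus tails.
* On unbalanced data the partial SS are the data-metric analogue of
  sigma-restricted Type III, not a clone of any one commercial
  implementation.
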