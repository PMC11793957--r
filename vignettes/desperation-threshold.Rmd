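---
title: "Desperation thresholds and risk taking: model, generator and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desperation thresholds and risk taking: model, generator and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thresholdrisk)
```

## The model

The package is built around a single idea from risk-sensitive foraging
theory (the "small bird in winter" problem), transposed to household
finances: people try to keep their resources above a level that secures
their basic needs — a *desperation threshold*. Utility rises steeply
around that level, stays comparatively flat below it (once basic needs
are lost there is little left to lose), and grows gently and linearly
above it. We parameterise this as

```
U(r) = plogis(u) + s * u * [u > 0],   u = (r - threshold) / scale
```

with `threshold` the resource level of basic needs (0 by default: we
measure resources relative to needs), `scale` the width of the threshold
region in euros (default 100), and `s` the linear slope above the
threshold (default 1/50). The logistic term makes utility convex below
the threshold and concave just above it; the indicator-gated linear term
takes over far above.

The behavioural consequence is read off the **certainty equivalent** (CE)
of a reference gamble — by default a 50% chance of €800, the gamble used
in the elicitation battery. The CE at resources `r` is the sure amount
`c` with `U(r + c)` equal to the gamble's expected utility; monotonicity
makes the root unique in `[0, 800]`, and `certainty_equivalent()` finds
it by bisection to €0.01. An agent whose CE exceeds the gamble's expected
value (€400) is taking risk; below it, avoiding risk. Two predictions
follow:

* **P1 (V-shape).** The CE falls from well above €400 deep below the
  threshold to a minimum just above it, then relaxes back to €400 as
  resources grow. `regime_switch_point()` locates the single crossing of
  €400 at about −€383 under the defaults, i.e. roughly the point where
  winning €400 for sure lands the agent exactly at the threshold. The
  euro scaling of the sigmoid (one unit = €100) is the choice that places
  this switch near −€400 and maps the €100–€700 ladder onto 1–7 sigmoid
  units; it is a configurable reconstruction, not an estimated quantity.
* **P2 (dispersion).** If resources are observed with a lot of noise
  (s.d. €500) and CEs with a little (s.d. €50), the sharp V becomes a
  triangular scatter (`simulate_noisy_scatter()`): low measured resources
  mix people just above the threshold (risk avoiders) with people just
  below it (risk takers), so the *variance* of risk taking is largest at
  the bottom of the resource distribution even when the V itself is
  washed out.

The ladder version of the prediction, `predicted_bet_count()`, counts how
many of the seven sure amounts the gamble is strictly preferred to; with
a consistent agent this is just the position of the CE in the ladder. A
trembling hand — each binary choice flipped independently with a small
probability — converts the deterministic cutoff into the noisy batteries
a survey actually collects.

## The synthetic panel generator

`generate_panel()` produces a panel with the schema of a monthly
cost-of-living survey: 472 adults (France/UK mix), up to 12 waves,
household income and unavoidable costs in euros, three 0–100 subjective
insecurity items, a seven-item gamble battery, a seven-item delay
battery, and a five-level financial-strain answer. The generator is the
package's test bed: it encodes the mechanism the analyses are meant to
detect, so detection can be verified under known truth.

Design choices, each a first-class configuration knob in
`panel_config()`:

* **Income** is lognormal with median €3000 and mean ≈ €3437, split into
  a persistent participant level and wave-level noise. A lognormal
  matching those two moments implies an s.d. of about €1900, somewhat
  below the survey's €2117; we prioritised the mean/median pair.
* **Costs** are a Beta-distributed participant-specific fraction of
  income (mean 0.45) with multiplicative lognormal wave noise whose upper
  tail produces the rare months in which costs exceed income.
* **Thresholds** are Normal(€500, €300) across participants, in euros of
  monthly disposable income. With the income process above this puts
  roughly 6–8% of observations below their owner's threshold — a low
  tail thick enough for the V to be detectable, thin enough to be
  realistic for these populations.
* **Bet counts** are the model's prediction at disposable income minus
  the individual threshold, plus a persistent participant shift
  (s.d. 1.0), a wave shift (s.d. 0.85), small fixed effects of age
  (−0.085 per s.d.) and gender (−0.19 for women), a constant −0.45
  aligning the mean count with the surveyed ≈ 2.3, rounding, and a 1.2%
  trembling hand (which also produces ≈ 6% inconsistent batteries). The
  persistent/wave split is calibrated so the bet count's intra-class
  correlation is ≈ 0.48.
* **Subjective items** share one latent insecurity (a logistic transform
  of distance to threshold plus persistent and wave-level perception
  noise) plus independent per-item noise (s.d. 15 points), calibrated to
  a Cronbach's alpha ≈ 0.87. Because most participants sit well above
  their threshold, the items pile up near zero — the right skew the
  square-root transform in `preprocess_panel()` is there to tame.
* **Missingness** is missing-at-random with participant-specific
  response probabilities (Beta with mean 0.8375), targeting ≈ 10 of 12
  completed waves with realistic over-dispersion. No real dropout
  mechanism is modelled.
* **Time discounting** is an independent trait that steepens by +2
  immediate choices in below-threshold months, giving the asymmetric
  pattern (steep discounting elevated among the deprived, flat
  discounting not) without feeding back into the risk analyses.

What the generator does *not* emulate: country-specific income
distributions, non-random dropout, savings and wealth stocks, item-level
response styles, or any correlation between comprehension and resources.
Passing tests therefore show that the analyses detect (and do not
hallucinate) the threshold mechanism under this data-generating process —
not that real survey data contain it.

## The confirmatory analyses

Variables are derived exactly as a survey analysis would:
`objective_resources = log2(income + 1) − log2(costs + 1)` (0 = income
just covers costs, 1 = twice costs), and
`subjective_resources = sqrt(300 − sum of the three items)`.

**V-shape (analysis 1).** Two complementary tests of P1, both Gaussian
random-intercept models with fixed effects of standardized age and
gender, fitted by maximum likelihood (not REML) so that AICs, deviances
and likelihood-ratio tests are comparable across fixed-effect
structures:

* `compare_polynomials()` fits orthogonal-polynomial degrees 1..k and
  asks whether any curvature beats the linear model by AIC/LRT.
* `fit_segmented_mixed()` fits the broken-stick model
  `y = b0 + b1 (r − cp)[r ≤ cp] + b2 (r − cp)[r > cp] + controls`, with
  the two lines constrained to meet at the changepoint, at every
  candidate changepoint, and keeps the minimum-deviance fit together
  with the full deviance profile. The default candidate set is a
  percentile grid (step 0.5, i.e. 199 candidates; `grid = "observed"`
  fits every unique value) with at least 20 observations required on
  each side; deviance ties break to the smaller changepoint. Slope
  inference is by two-sided Wald tests conditional on the selected
  changepoint — there is deliberately no correction for the changepoint
  search, which mirrors the analysis the package reproduces and is a
  known anti-conservative limitation. Successive candidates warm-start
  from the previous variance estimates, which makes the profile loop
  roughly linear-model cheap.

A count outcome (0–7) modelled as Gaussian is itself a faithful design
choice: the analyses this package implements treat the bet count as a
continuous response, and so do we; ordinal or Poisson mixed models are
out of scope.

**Dispersion (analysis 2).** P2 is tested three ways, and the three
p-values are Holm–Bonferroni corrected as one family
(`p2_family_tests()`): a two-sided variance-ratio F test between the
"very difficult" financial-strain group and everyone else; and
squared-residual regressions on each resource measure — stage one an OLS
fit *without* random effects (so between-person variance is not absorbed
into intercepts), stage two a standardized regression of the squared
residuals on resources. `variance_sweep()` visualises the same effect as
the below/above variance ratio for every percentile threshold from the
1st to the 50th (per-threshold p-values are reported raw, with a Holm
column alongside, since the corresponding published figure's correction
convention is unstated). `within_person_stability()` aggregates to one
observation per participant (≥ 2 waves) and regresses over-time variance
on mean resources. Group tests pool observations across waves;
participant-level aggregation is available by aggregating before calling
them.

**Descriptives.** `classify_extremes()` labels 0 bets "avoider" and ≥ 5
"taker" (five bets implies accepting a gamble worth less than the sure
amount on offer); `extreme_prevalence_table()` compares both prevalences
in the bottom/top 5% of each resource measure against the rest of the
sample with 2×2 Pearson chi-squared tests (no continuity correction) and
variance F tests; tails are cut over observations, not participants,
matching pooled-observation counts. `mean_resources_by_count()` pools
counts 6–7 into one bin. `discounting_contrast()` repeats the table for
the delay battery, and `consistency_by_resources()` checks that answer
consistency is uncorrelated with resources.

## Numerical choices and degenerate inputs

* CE bisection: tolerance €0.01 on `[0, win]`; bracketing is guaranteed
  by monotone utility, and a non-bracketing call is an internal error.
* Regime classification on a CE curve uses a neutral band of ten times
  the solver tolerance, so deep-linear-regime points classify as neutral
  rather than flickering by ±0.01.
* Changepoint admissibility: `min_side = 20` observations per segment by
  default; an inadmissible fixed changepoint is an error, inadmissible
  grid candidates are dropped.
* Zero-variance responses are refused by the model fitters; zero-variance
  groups by the F test; a zero-variance consistency flag yields `NA` with
  a warning; constant responses short-circuit the squared-residual
  regression to a zero slope.
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; equal seeds give bit-identical output.

## Problem sizes used in the test suite

The suite verifies parameter recovery with 50 replicates of the
strong-V scenario at the survey's scale (472 participants × 10 waves,
changepoint at the 20th percentile, slopes −1.5 and +0.15), using a
2-percentile-step candidate grid — comfortably finer than the ±5
percentile recovery band being verified. False-positive control uses 50
linear-truth replicates at 200 × 5 and 500 small null replicates for the
dispersion family; unit tests run on 80–350-participant panels. These
sizes are the package's choices for a thorough-but-routine check; all of
them can be scaled up through the same functions.

## Known limitations

* The changepoint's sampling uncertainty is not quantified (no profile
  CI, no bootstrap), and slope tests condition on the selected
  changepoint.
* The Gaussian treatment of a bounded count compresses variance near the
  0 and 7 edges; the generator's clamping does the same, so
  recovered slopes near the edges are attenuated relative to the latent
  truth.
* The generator's missingness is ignorable by construction; analyses on
  data with informative dropout would need reweighting the package does
  not provide.
* Purchasing-power conversion between currencies is out of scope: the
  generator and analyses work in euros throughout.
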