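---
title: "Methods: cohort-adaptive MET skipping and expression calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-adaptive MET skipping and expression calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcall)
```

## The calling model

`metcall` classifies NSCLC samples from a targeted digital expression panel
carrying a MET wild-type probe, a METΔex14 junction probe (exon 13–exon 15),
three housekeeping genes and synthetic controls. The procedure is
deliberately simple and fully cohort-adaptive:

1. **Evaluability.** A sample is analyzable only if the geometric mean of
   its raw housekeeping counts is at least 100. The geomean is zero whenever
   any housekeeping count is zero, so such lanes always fail. The rule is
   applied to raw counts, before normalization, because it judges whether
   the lane contains enough intact RNA to normalize at all.
2. **Two-step normalization.** Counts are first scaled per sample by the
   cohort mean of positive-control geomeans over the sample's own
   positive-control geomean (lane/hybridization efficiency), then again by
   the analogous housekeeping factor computed on step-1-scaled counts (RNA
   input and quality). Both cohort references average over QC-passing
   samples only, so failing lanes do not perturb the scale. Because both
   factors multiply every probe of a sample, within-sample ratios — in
   particular the Δex14/wt ratio — are invariant under normalization; the
   property suite verifies this at 1e-12.
3. **Skipping call.** The statistic is log2 of normalized Δex14 counts over
   normalized wt counts. Positivity is strictly above the cohort mean plus
   2 sample SDs of this log-ratio. A sample with zero raw Δex14 counts has
   no defined ratio and is directly negative.
4. **Expression tiers.** logMET is log2 of the normalized wt counts.
   Moderately elevated means logMET ≥ cohort mean + 1 SD, very high means
   ≥ mean + 2 SD, estimated over all evaluable samples.

The key distributional assumption — verified by `distribution_diagnostics()`
on every fit — is that log-ratios are *bimodal* (a skipping-negative bulk
driven by background counts on the junction probe, far below a positive
mode near log2 of the skipped fraction odds) while logMET is *unimodal*
with a high tail, so that mean + k·SD thresholds are meaningful outlier
rules rather than mode separators.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `hk_geomean_min` | 100 | counts | evaluability floor on raw housekeeping geomean |
| `log_base` | 2 | — | reporting scale only; calls are base-invariant (property-tested) |
| `lr_k` | 2 | cohort SD | skipping positivity threshold |
| `lm_k_mod`, `lm_k_high` | 1, 2 | cohort SD | expression tier boundaries |
| `detect_mode` | `raw_zero` | — | a raw Δex14 count of 0 is directly negative; `background` additionally requires exceeding the sample's negative-control mean + 2 SD |
| `strict_gt` | `TRUE` | — | log-ratio positivity is strict ">"; tiers use "≥" at both boundaries |

Conventions that a threshold rule must pin down, and the choices made here:
the SD is the sample SD (n − 1); the log-ratio mean/SD is computed over
samples with a *defined* ratio (undefined ratios cannot enter a mean; the
count used, `n_used_lr`, is reported so the choice is auditable) and
includes any positives in that set (the cutoff describes "the sample
cohort", not the negatives alone); tier cutoffs are computed over all
evaluable samples, baseline and progression alike; normalization references
are pooled over the whole cohort rather than per cartridge (per-run
factoring can be emulated by fitting runs separately and freezing cutoffs).
Positivity at exactly the cutoff value is negative for skipping (strict)
and upper-tier for expression (≥): the two conventions are documented,
config-exposed, and boundary-tested. Cutoffs are re-estimated for every
analyzed cohort; `predict()` applies a fitted cohort's cutoffs *and* its
normalization references frozen, which is the supported mode for small
prospective batches where self-estimated cutoffs would be unstable.

## Distribution diagnostics

Normality of logMET is tested with the Kolmogorov–Smirnov statistic using
the Lilliefors correction for estimated parameters (`nortest::lillie.test`;
the output flags this). Bimodality is assessed with a two-component
equal-variance Gaussian mixture, fitted by EM with a deterministic
initialization: one-dimensional Lloyd k-means started from a split at the
median, then at most 100 EM iterations at tolerance 1e-8. Determinism
matters more here than global optimality — diagnostics attached to a fit
must be reproducible byte-for-byte. With equal variances the two weighted
component densities cross exactly once, giving a closed-form
misclassification boundary.

The bimodality verdict requires both (a) a log-likelihood improvement over
a single Gaussian of more than 0.25 nats *per observation* and (b) component
means separated by more than 2 shared SDs. The margin is per observation
because the raw log-likelihood difference scales with n; 0.25 nats/obs
(a likelihood factor of ~1.3 per observation) was calibrated once on the
four canonical shapes this package must distinguish: a pure Gaussian
(~0.001 nats/obs), a unimodal cohort with a 3.5% high tail (~0.10–0.17),
a 3% separated skipping mode (~0.32–0.42), and a 97:3 two-cluster toy case
(~0.45). A 3.5% component four cohort-SDs out is *detectable* by the
mixture (separation ≈ 4.5 shared SDs), so the separation criterion alone
cannot distinguish a high tail from genuine bimodality; the margin
criterion carries that distinction. Degenerate (zero-variance) input
returns the verdict `"degenerate"` rather than statistics.

## The synthetic cohort generator

No patient-level data ship with the package; `simulate_cohort()` generates
cohorts with the structure the caller assumes, plus ground-truth labels, so
recovery is checkable by construction. Per sample:

- a latent log-expression z is drawn from a three-component mixture:
  normal N(0, σ₀), moderately elevated N(1.5, 0.25) and very-high
  N(4.0, 0.25), all in **cohort log-SD units**. σ₀ is solved in closed form
  so that the evaluable cohort's latent log-SD is exactly 1; configurations
  where the elevated components alone exceed the unit SD (e.g. one
  very-high sample in a cohort of six) are rejected as infeasible before
  sampling. Anchoring the shifts to the cohort SD keeps them commensurate
  with the mean + k·SD cutoffs that will be applied downstream.
- total MET mean is 8000·exp(z) counts. Skipping-positive samples keep this
  total but reallocate a fraction (default 0.5) to the Δex14 probe —
  matching the observed mutual exclusivity between skipping and very-high
  expression; all other samples put the Δex14 probe at negative-control
  background (mean 2 counts, so roughly one evaluable sample in six draws a
  zero and is auto-negative).
- housekeeping means are 1500, positive controls a two-fold titration from
  5000; a lane scalar exp(N(0, 0.2)) multiplies every probe. QC-failing
  samples have housekeeping and endogenous means scaled by 0.02 (degraded
  RNA) while positive controls are untouched — they are synthetic
  spike-ins, which is also why the corrupt-lane error (zero positive
  control geomean in a QC-passing sample) is a distinct failure mode.
- every count is negative binomial with var = μ + 0.1·μ² (0 gives Poisson).
  FFPE-derived digital counts are overdispersed; 0.1 is a conventional
  panel-scale dispersion.

All randomness flows from a single seed with a fixed stream order (group
shuffle, latent z, lane scalars, counts probe-by-probe in codeset order);
re-running a config is bit-identical. The default configuration reproduces
a 474-sample screening cohort: 52 QC failures, 13 skipping-positive, 15
very-high, 36 moderately elevated.

What the generator does *not* emulate: FFPE degradation chemistry beyond a
global count scale-down, stromal/immune MET expression, probe-specific
cross-hybridization, cartridge batch structure, or a calibrated copy-number
to mRNA mapping (very-high samples are a shifted log-normal component, not
explicit copy-number arithmetic). Passing recovery tests therefore shows
the *procedure* is correct and stable under realistic count noise, not that
real cohorts will separate as cleanly.

One honest caveat quantified by the simulator: with a 3.5% very-high
component at +4 cohort SDs, the recomputed mean + 2 SD threshold lands
~2.7 within-bulk SDs above the bulk mean, so on average just under one
normal-component sample per cohort crosses it. Very-high *sensitivity* is
essentially perfect (one missed sample in hundreds of simulated cohorts)
and specificity exceeds 0.998, but exact very-high counts fluctuate by ±1
around the planted 15 across seeds — which is why the test suite asserts
aggregate sensitivity/specificity across ten cohorts rather than a
per-cohort count of exactly 15, and asserts exact recovery only for
skipping labels, whose two modes are ~8 log2-units apart.

`simulate_spikein()` provides the in-silico analogue of cell-line dilution
series: probe means are convex mixtures of a wild-type diluent and a
MET-dependent cell model (a skipping line with amplified, predominantly
Δex14 MET, or an amplified high-expressor), yielding monotone log-ratio
dose curves with a closed-form plateau at log2(f/(1−f)). These are
sensitivity curves for the caller, not predictions of tissue-level limits
of detection.

## Concordance statistics

Agreement between paired binary calls uses percent agreement with the
Wilson score interval (the score interval reproduces published intervals
for small-n repeatability comparisons exactly at 95%, e.g. 28/29 →
82.8–99.4; Clopper–Pearson is available by config), Cohen's kappa from the
standard marginal formula with the usual qualitative bands (≤0.20 slight to
>0.80 almost perfect), and sensitivity/specificity treating the declared
reference assay as truth, with the orientation recorded. Unknown calls are
dropped pairwise per comparison and the dropped count reported, which is
why different assay comparisons have different denominators. Kappa
uncertainty intervals and weighted/multi-rater variants are out of scope.
Group comparisons of logMET across driver alterations use the two-sided
Mann–Whitney U test with no multiplicity adjustment by default (matching
how such screening comparisons are conventionally reported); any
`p.adjust` method can be switched on.

## Problem sizes and runtime

The test suite simulates cohorts of 40–474 samples and checks the
full-composition recovery across ten seeds; the complete suite runs in a
few seconds on one CPU. `scripts/acceptance.R` performs one full 474-sample
simulation plus fit per run. EM diagnostics are O(n) per iteration and
converge in well under 100 iterations on all tested shapes.

## Known limitations

- Self-referential cutoffs are only as stable as the cohort is large and
  representative; for small batches use frozen cutoffs via `predict()`.
- The `raw_zero` detectability rule is literal: a single stray junction
  count makes a ratio defined (though almost always far below threshold).
  The `background` mode is stricter but changes `n_used_lr`.
- The two-step normalization recipe follows the standard vendor convention
  (positive-control scaling, then housekeeping-content scaling, each to the
  cohort mean of per-sample geomeans). The calls are insensitive to the
  reference constant, but normalized values exported for other uses carry
  that convention.
- Tiers and calls are per-cohort relative quantities; they are not
  comparable across cohorts unless one cohort's cutoffs are frozen and
  applied to the other.
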