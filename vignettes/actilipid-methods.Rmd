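---
title: "Operational definitions and models behind actilipid"
author: "actilipid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational definitions and models behind actilipid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actilipid)
```

# Scope

`actilipid` implements the computational core of a mouse mood-episode
study design: long-term wheel-running actigraphy is screened for
mania-like **hyperactivity bouts** (HABs) and depression-like
**hypoactivity episodes**, circadian disturbance is quantified with a
**delayed-activity index**, and a companion brain **lipidomics table** is
analysed for differential lipids gated jointly on statistical and
substantive significance, with class and fatty-acid enrichment,
ordination (PCA, OPLS-DA) and clustering. A synthetic-data module
generates both kinds of inputs with known ground truth, so every stage of
the pipeline is verifiable end to end without animal recordings.

This vignette records the models, the operational constants and their
defaults, and the design decisions taken where several reasonable
formalizations exist. It states no empirical result that the package's
test suite and `scripts/acceptance.R` do not themselves compute.

# Actigraphy model

An `ActivitySeries` holds one animal's wheel-revolution counts in
fixed-width bins (6 min by default) over whole days, aligned to
Zeitgeber time: bin 1 starts at lights-on (ZT0), the light phase spans
ZT0–ZT12 under the default 12:12 schedule, and the dark (active) phase
ZT12–ZT24. Missing bins are explicit `NA`s, never zeros. Bins are
half-open `[t, t + bin)` and the day boundary is at lights-on.

## Hyperactivity bouts

A HAB is operationally a stretch of running *far above the animal's own
norm* — high enough to be a statistical outlier of its activity
distribution — lasting at least 6 hours (the floor is inclusive).
Detection parameters, all exposed in `detectHABs()`:

| parameter | default | meaning |
|---|---|---|
| `windowHours` | 6 h | width of the screening window |
| `fenceMultiplier` | 1.5 | IQR multiplier of the outlier fence |
| `mergeGapHours` | 1 h | largest gap bridged between elevated runs |
| `minDurationHours` | 6 h | episode duration floor (inclusive) |
| `refineHours` | 1 h | width of the boundary-refinement window |
| `maxMissingFrac` | 0.2 | missing fraction above which a window is uncallable |

The reference distribution is the animal's own rolling 6-h window sums
over the whole recording; the fence is `Q3 + 1.5 * IQR`, the familiar
box-plot whisker convention. Because a 6-h window overlapping a bout by
only a fraction can already exceed the fence, window-level calls alone
would systematically overhang the true bout by several hours; we
therefore refine boundaries inside each candidate extent with a short
(1-h) rolling sum compared against the fence rescaled to that width.
This keeps boundary error at the scale of the refinement window, which
the recovery tests quantify as a median Jaccard overlap above 0.9 for
5-fold-amplitude bouts. Runs shorter than the floor are discarded, which
is what rejects brief (for example 3-h) bursts however intense. The
score, `(max window sum − fence)/IQR`, is a unit-free exceedance; both
the fence and the score are quantile-based, so detection is invariant to
rescaling counts by a positive constant (e.g. different wheel
circumferences).

## Hypoactivity episodes

A depression-like episode is at least 14 consecutive days (inclusive)
whose smoothed daily totals fall below a fraction of the animal's
baseline. Daily totals are smoothed with a 3-day centered moving
average; the baseline is the median daily total, re-estimated once after
initial flagging with flagged days excluded; the score is the mean
fractional deficit.

The threshold is `(1 − delta) * baseline` with **`delta = 0.3`** — days
below 70% of baseline are candidate episode days. The choice is
deliberate: episodes of interest reduce running by about half, and a
detector thresholded exactly at a 50% deficit would sit on top of the
very signal it is meant to call, flagging marginal days by coin-flip and
breaking the consecutive-day run requirement. Placing the threshold at a
30% deficit leaves ordinary day-to-day variation (a few percent of the
daily total at these count levels) far above it and halved activity far
below it, so both boundary days and interior days classify stably. The
smoothing, threshold and duration floor are all configurable.

## Delayed-activity index

The index quantifies circadian phase delay as the fraction of a day's
running that occurs in the early light phase — ZT0 to ZT6 by default
(`morningHours = 6`) — when a nocturnal animal should be at rest. Per-day
fractions are averaged over the requested window; days without any
activity are excluded, and a window with no activity at all is flagged
`NA` rather than zero. An alternative mode uses the whole light phase,
for sensitivity analysis. The index is bounded in [0, 1] by
construction. Episode frequencies are normalized to a six-month window
as `count × 183 / observed days`.

# Statistical core

Group comparisons follow the convention of pairing every p-value with a
standardized effect size: Cohen's *d* (pooled SD, df-weighted) for
t-tests, *r* = |Z|/√N for rank tests, classical η² (SS_effect/SS_total)
for ANOVA, and φ for 2×2 Fisher tests. Magnitude labels use the strict
thresholds d > 0.01/0.2/0.5/0.8 (very small/small/medium/large),
r and φ > 0.1/0.3/0.5, η² > 0.01/0.06/0.14.

Decisions where conventions diverge:

* **t-test variant**: Welch by default (no equal-variance assumption);
  Student's pooled test by flag.
* **Paired contrasts** use the Wilcoxon signed-rank test, the standard
  paired analogue of the U test.
* **Exactness**: the U and signed-rank tests are exact by full
  enumeration when the sample is small (N ≤ 12 and tie-free) and use a
  tie-corrected normal approximation (without continuity correction)
  otherwise; *r* is always derived from the tie-corrected Z so the
  effect size is comparable across branches. Fisher's two-sided p is
  the sum of hypergeometric point probabilities at or below the
  observed table's. All three are validated against independent
  brute-force enumerations over every input with N ≤ 10.
* **Sidedness**: two-sided throughout; a direction must be requested
  explicitly.
* **η² is classical**, not partial, so values over all effects plus the
  residual sum to one in balanced designs; the two-way decomposition
  uses sequential sums of squares.
* **Crossover designs** (two groups, two periods) are analysed as
  `value ~ treatment + period + Error(subject)`, the treatment F-test
  coming from the within-subject stratum; subjects missing a period are
  excluded with a warning.
* **Multiplicity**: Benjamini-Hochberg or Bonferroni via
  `stats::p.adjust`, preserving input order.

Null calibration is checked by simulation at sizes where each test is in
its asymptotic (or effectively continuous) regime — t at n = 8/8, U at
20/20, signed-rank at 40 pairs, Fisher on 150-per-group binomial
margins, Kruskal-Wallis at 3 × 15 — because at very small samples the
discrete exact tests cannot attain the nominal 5% level (an exact U test
at 6/6, for instance, is conservative by construction). The acceptance
script reports all of these rates at 10,000 replicates.

# Lipidomics model

A `LipidTable` is a `SummarizedExperiment` of non-negative abundances
(lipids × samples) with per-lipid class and acyl-chain annotations and
per-sample factors. Analysis choices:

* **Preprocessing**: per-lipid `log2(x + pseudocount)` with the
  pseudocount set to half the lipid's smallest positive abundance
  (raw-scale analysis by flag). Multivariate methods additionally
  mean-center and autoscale to unit variance by default (Pareto scaling
  selectable) — with hundreds of lipids spanning orders of magnitude,
  unscaled analyses are dominated by the most abundant classes.
* **Differential gate**: a lipid is *selected* when raw `p < 0.05` AND
  `|d| > 0.8` — statistically significant with a large effect size.
  BH-adjusted p-values are reported alongside but do not enter the
  default gate. Note an arithmetic fact the vignette makes explicit: at
  n = 8 per group, `p < 0.05` already implies `|d| > 1.07`, so the
  effect-size criterion is only a genuine additional filter at larger
  samples (from roughly n = 16 per group; at n = 25 it cuts the null
  selection rate from ~5% to well under 1%). The package's calibration
  checks therefore characterize the gate's null behaviour at both n = 8
  and n = 25 per group.
* **Enrichment**: one 2×2 Fisher test per lipid class and per fatty
  acid, with the background being all testable lipids of that
  comparison. Fatty-acid membership is lipid-level set membership over
  distinct chains: a lipid with two 16:0 chains counts once for 16:0,
  and a di-acyl lipid belongs to both of its chains. φ is reported
  signed (positive = over-representation), and BH adjustment is applied
  across categories within each analysis; conventional figure-style
  summaries show the raw Fisher p.
* **Clustering**: Euclidean distance on preprocessed profiles with Ward
  (`ward.D2`) linkage, both configurable; dendrograms export to Newick.
* **OPLS-DA**: one predictive component after removing `nOrthogonal`
  label-orthogonal components by O-PLS deflation. Orthogonal scores are
  exactly uncorrelated with the (centered) label by construction, and
  with zero orthogonal components the model reduces to single-component
  PLS-DA. Lipids are ranked by absolute predictive loading and the top
  `ceiling(fraction × n)` flagged — 1% of 464 lipids is 5. Model
  validity is assessed by a label-permutation test on predictive R²Y.
* **Distance ANOVA**: the two-factor analysis of Euclidean distances
  between lipid profiles is run as a PERMANOVA (`vegan::adonis2`, terms
  sequential, R² reported in the η² column) by default. A
  distance-to-grand-centroid variant feeding the ordinary two-way ANOVA
  is provided (`method = "centroid"`), but note it is structurally
  insensitive to a symmetric two-group shift — both groups end up
  equidistant from the overall centroid — which is why it is not the
  default.

# Synthetic data

`simulateActivity()` emits negative-binomial counts per bin (wheel
counts are overdispersed; Poisson by flag) around a phase-dependent mean:
a square wave by default — 20 expected revolutions per 6-min dark bin
vs 3 per light bin, negative-binomial size 8 — or a smooth cosine ramp,
under which the detectors are also tested. The defaults describe a
strongly nocturnal animal (dark-phase share of daily activity
well above 80%) at realistic count levels for a running wheel.

Injected **HABs** (6–24 h) set the expected rate to
`amplitude × dark rate` for every bin of the bout, regardless of phase:
the defining phenomenology of these bouts is sustained, rest-phase
running, and a bout modelled as a mere multiple of the resting-phase
rate would not be hyperactivity at all. Injected **hypoactivity
episodes** (≥ 14 days) multiply expected activity by `amplitude` (0.5 by
default) and move a fraction (`lightRedistribution = 0.35`) of what
remains into ZT0–ZT6, so both the frequency analysis and the
delayed-activity contrast have ground truth. Overlapping same-kind specs
are rejected. Everything is deterministic under a fixed seed.

`simulateLipidomics()` draws log-normal abundances for 464 lipids over
26 classes and 29 acyl chains (largest-remainder allocation of a
realistic brain-panel composition; both pools replaceable), with
within-group SD σ = 0.5 on the log2 scale. Effects are specified as
target (class, fatty acid, or explicit lipid set) plus a standardized
difference *d*: targeted lipids are shifted by `d × σ` between groups,
so injected effect sizes are known exactly. `writeFixtureBundle()`
materializes activity and lipid fixtures with a JSON manifest of seeds
and ground truth; regeneration from the same configurations is
byte-identical.

What the generator does *not* emulate — and hence what passing tests do
not establish about real recordings: ultradian structure and wheel
mechanics, age trends in episode frequency, gradual episode onset,
correlated noise across lipids (lipids are conditionally independent
given the group), batch effects and missingness patterns of LC-MS/MS
quantification. The validation closes the loop simulate → detect →
estimate under the stated conditions; transfer to real data relies on
the operational definitions, not on these tests.

# Validation problem sizes

The test suite and `scripts/acceptance.R` use: a 100-animal simulated
cohort (183 days each; 40 animals × 2 HABs, 30 animals × 1 hypoactivity
episode at 50% reduction, 30 null animals) for detector operating
characteristics; 10 animals for the delayed-activity paired contrast;
10,000 replicates per test for null calibration; 200 seeds per target
for effect-size recovery (d ∈ {0.8, 1.5, 2.5} at n = 8/8); 500/2,000
replicates for crossover power and size; and a 464-lipid table with 5
planted discriminants for the OPLS-DA top-1% construction check.

# Known limitations

* The episode definitions are operational reconstructions with
  documented constants, not a re-derivation of any particular
  laboratory's unpublished supplementary procedure; all constants are
  surfaced as parameters.
* The hypoactivity baseline assumes most of the recording is euthymic;
  an animal depressed for most of the window would drag the median
  baseline down.
* OPLS-DA is implemented for a binary class and one predictive
  component (the discriminant use case); multi-class designs are out of
  scope.
* PERMANOVA R² depends on term order (sequential sums of squares), as
  does the two-way ANOVA decomposition in unbalanced designs.
* The t-based differential analysis treats lipids independently; lipids
  within a class are correlated in real data, which raw p-values ignore
  (the enrichment layer partially recovers class-level structure).

# Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulateActivity(
  nDays = 120,
  episodes = list(habSpec(onsetDay = 30, onsetHour = 14,
                          durationHours = 12, amplitude = 5),
                  deSpec(onsetDay = 70, durationDays = 21,
                         amplitude = 0.5)),
  seed = 1)
detectHABs(sim$series)
detectHypoactivityEpisodes(sim$series)
delayedActivityIndex(sim$series, days = 70:90)

lip <- simulateLipidomics(
  effects = list(list(target = "class:PC", d = 2)), seed = 1)
rep <- runLipidArm(lip$table)
rep$summary
```
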