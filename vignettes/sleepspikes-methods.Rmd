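---
title: "Methods: state scoring, jitter bands, and twitch-locked unit classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state scoring, jitter bands, and twitch-locked unit classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepspikes)
```

`sleepspikes` analyses extracellular unit activity recorded together with
EMG in sleeping infant rodents. The scientific question it serves is
whether a structure receives a *corollary discharge* (CD) of the motor
command that produces a myoclonic twitch: a copy of the command, arriving
at non-motor structures at essentially zero latency with respect to
movement onset. The operational signature is a sharp peak in the
perievent histogram within ±10 ms of twitch onset — too late to be
premotor drive, too early to be sensory reafference — and the package's
job is to detect that signature with honest error control, separate it
from twitch-preceding (motor) and twitch-following (reafferent) activity,
and support group comparisons of histogram shape.

This vignette documents the model assumptions, the tunable parameters,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## 1. Behavioural-state scoring

**Model.** Infant sleep–wake behaviour is scored from nuchal EMG alone.
Three states tile the record: active wake (AW; high tonic muscle
activity), behavioural quiescence (BQ; low tone, no twitching), active
sleep (AS; atonia punctuated by myoclonic twitches).

**Procedure.** The raw trace is full-wave rectified and smoothed with a
causal first-order exponential filter, `rectify_smooth()`. The scoring
threshold is the arithmetic midpoint between the mean amplitude of high
muscle tone and of atonia, each estimated from five representative 1-s
segments (`estimate_threshold()`); segment selection is automatic
(highest- and lowest-mean transient-free windows) with a manual override
for exact reproduction of a human analyst's choices. Supra-threshold runs
of at least `min_bout` become AW; sub-threshold runs of at least
`min_bout` become sleep; shorter runs merge into the preceding qualifying
state, so a 60-ms twitch transient never fragments a sleep bout and a
brief dip never fragments wake. A leading short run joins the first
qualifying run, since it has no predecessor. Each sleep run is split at
its first twitch: BQ before, AS after; a twitch-free sleep run is all BQ.

**Twitch detection.** Twitches are detected inside sleep as excursions of
the rectified-smoothed trace reaching at least `k = 3` times the mean
atonia baseline. The baseline is estimated robustly: an initial median
over sleep samples, then the mean of samples not exceeding twice that
median (excluding the transients themselves from their own baseline). The
reported onset is, by default, the start of the rising transient — from
the criterion crossing the detector walks back to the last sample at or
below the atonia median — rather than the crossing itself; the crossing
of `3 x` baseline sits most of the way up the rise, and the rise start is
the moment the movement began. A `crossing` mode is available. Detections
closer than `refractory = 200 ms` are merged (first one kept).

**Key parameters.**

| parameter | default | units | role |
|---|---|---|---|
| `smooth_tau` | 0.001 | s | EMG envelope smoothing constant |
| `twitch_multiplier` | 3 | — | twitch criterion, × atonia baseline |
| `min_bout` | 1 | s | minimum scorable state bout |
| `refractory` | 0.2 | s | minimum twitch separation per muscle |

The 1-ms smoothing constant barely delays the envelope (the filter
reaches 63 % of a step in one sample at 1 kHz), which is what lets state
boundaries be recovered to one sample on clean data. The refractory
default reflects the discrete, well-separated character of myoclonic
twitches; the literature reports no minimum separation, so it is a
configuration choice, not a measured constant.

## 2. State-dependent firing

Per-bout firing rates (`bout_rates()`) are spike counts over half-open
bouts divided by bout duration. Bouts whose rate lies beyond
`outlier_sd = 3` SD of that state's bout-rate distribution are excluded
once (mean and SD computed before exclusion; the rule is deliberately not
iterated). Note that 3 SD is a weak filter at small bout counts — with
five bouts even a 100-fold outlier can survive — which the test suite
documents explicitly.

`classify_state()` runs the three pairwise Wilcoxon matched-pairs
signed-ranks tests. Bouts are paired by sleep–wake cycle index (the i-th
AS bout with the i-th AW bout, truncating to the shorter list): within a
session, adjacent cycles share slow confounds (electrode drift, brain
temperature), and cycle pairing is the natural matched design; an
unpaired Mann–Whitney fallback exists. The exact signed-rank null is used
up to n = 25 pairs, the normal approximation above. The decision table
requires significance only for the comparisons it names — "AS-on"
means AS above AW *and* AS above BQ, with no requirement on AW vs BQ.
Patterns the four-way taxonomy cannot express (e.g. only AS > BQ
significant) are labelled `unclassified` rather than forced; fewer than
`min_paired_bouts = 5` pairs yields `indeterminate`. Alpha defaults to
0.05 per test, uncorrected, with an optional Bonferroni flag: the three
tests ask one coherent question, and the taxonomy's joint requirements
already damp false positives.

## 3. Perievent histograms and the interval-jitter null

`build_psth()` counts spike–event lags in half-open bins over a window
centred on the trigger; 0 is always a bin edge, so the ±10-ms window is
exactly the bins covering [−10, 0) and [0, 10) ms at 5- or 10-ms widths.
Events whose windows overhang the session edges still contribute
(truncation at 1-s windows is negligible when events number in the
hundreds; the count of such events is recorded).

**Surrogates.** The null hypothesis is that spike timing carries no
event-locked structure finer than the jitter timescale. Interval jitter
(`jitter_surrogates()`) partitions the session into contiguous
`delta = 500 ms` cells and redraws each event uniformly within its own
cell, independently per surrogate, preserving the event count per cell
exactly — coarse rate co-modulation (state cycling, slow drift) survives,
fine-timescale locking is destroyed. The partition variant is the default
because preserved cell counts make the conditional null exact; a centred
per-event jitter would not preserve local rate exactly.

**Simultaneous bands.** With ~100 bins per histogram, per-bin quantile
bands would need a multiplicity correction of about two orders of
magnitude; with S = 1000 surrogates, per-bin *rank* resolution is only
1/S, so no per-bin order statistic — not even the per-bin maximum — can
deliver a family-wise 1 % band across 100 bins (the chance that a
null-consistent histogram strictly exceeds the per-bin maximum of 1000
surrogates somewhere among 100 near-continuous bins is itself about
10 %). `simultaneous_bands()` therefore calibrates on a *single
continuous statistic*: each bin is studentized by the mean and SD of the
exchangeable pool (surrogates plus the observed histogram), each pool
member is reduced to its maximum absolute studentized deviation across
the analyzed bins, and the band height `t*` is that statistic's
permutation critical value at depth `floor(alpha * (S + 1))`. The band is
`mean ± t* × SD` per bin; a breach anywhere implies the observed maximum
deviation exceeds `t*`, an event of probability at most
`floor(alpha (S+1))/(S+1) ≤ alpha` by exchangeability. Per-bin SDs are
floored at half a count so constant bins stay finite; the lower band is
clipped at zero (counts are non-negative), which can only remove
rejections. Upper and lower breaches share the same alpha budget, so the
"any bin escapes" rate quoted everywhere in the package is family-wise.
The test suite verifies this calibration empirically on independent
Poisson event/spike pairs.

**Classification.** `classify_response()` flags each latency window —
premotor (−500, −10) ms, CD (−10, +10) ms, reafferent (+10, +500) ms —
if at least one of its bins lies above the upper band; one breaching bin
suffices, since the band already controls the any-bin error. Bins below
the lower band are recorded separately as suppression. The *primary*
window is the one holding the largest breaching bin, which is how a unit
with a broad kernel spilling into a neighbouring window is still labelled
by the location of its dominant peak. When several muscles yield
significant histograms, `select_strongest_muscle()` keeps the muscle with
the highest PSTH peak rate (ties: total in-window count, then fixed
muscle order — deterministic and recorded).

**Pooling.** `pool_units()` sums per-unit histograms (each unit triggered
on its own events) and re-runs the jitter test by jittering each unit's
events independently and summing surrogate histograms. Per-unit jittering
is the faithful choice: the pooled null should preserve each session's
own coarse rate structure, which jittering a concatenated event list
would not.

**Alpha conventions.** Twitch-triggered analyses of IO/LRN units use
`alpha = 0.01`; midbrain and pooled two-group analyses use
`alpha = 0.05`. These follow the conventions of the literature this
analysis serves and live in `analysis_config`, not in code.

## 4. The two-group (saline vs apamin) battery

`compare_groups()` runs, in order: per-pup AS time and twitch rate
(Mann–Whitney); per-unit AS firing rate (Mann–Whitney, 3 SD exclusion);
per-unit peak-normalized histograms averaged per group; per-unit jitter
significance with χ² tests on the proportions of significant and of
sharp-±10-ms units; pooled significant-unit histograms per group (bands
at α = 0.05, exponential smoothing with τ = 10 ms); and per-unit
area-under-the-curve in the ±10 ms and 20–200 ms windows (Mann–Whitney
per window, 3 SD exclusion). χ² is Pearson's with 1 df and *no*
continuity correction — the uncorrected statistic is what this
literature prints, and the suite pins that down by checking that the
Yates-corrected value differs. AUC uses per-event-normalized counts by
default so groups with different twitch counts are comparable; a
raw-count mode exists because the convention is ambiguous in print.
Degenerate steps (a group with one unit, a proportion table with an empty
margin) are skipped with a logged reason rather than forced.

## 5. The synthetic-session generator

The generator (`simulate_session()`) emulates exactly the statistical
structure the analysis assumes:

* **States** cycle AW → BQ → AS with exponential bout durations above a
  floor (defaults: means 20/10/60 s, floor 5 s). Memorylessness is the
  simplest defensible bout model; the floor exists because the scorer
  cannot represent sub-`min_bout` bouts, so a generator emitting them
  would make exact recovery impossible by construction, not by defect.
  With no twitches configured, would-be AS is relabelled BQ — active
  sleep is *defined* by twitching.
* **EMG** is generated directly on the rectified-envelope scale
  (`rectified = TRUE`): state-dependent mean level (atonia 1, wake 5,
  arbitrary units) plus Gaussian noise, with half-sine twitch transients
  (60 ms, peak 6× the atonia mean) during AS. The analysis only ever
  consumes the rectified-smoothed trace, so a signed carrier would add
  nothing — and a noise-free envelope enables exactness tests that a
  stochastic carrier could never pass. The transient peak multiple must
  exceed the detection multiple (6 > 3), making injected twitches
  detectable by construction. The first twitch of each sleep bout is
  placed exactly at the AS onset, because the scoring rule *defines* AS
  as starting at the first twitch; twitches keep 160 ms clear of bout
  ends so transients never straddle state boundaries.
* **Units** are inhomogeneous Poisson: a per-state base rate plus
  event-locked Gaussian rate kernels and an optional post-event plateau.
  Spikes are drawn by superposition of independent Poisson components
  (state base + per-event kernel counts + plateau counts), which is
  exactly the inhomogeneous process with the summed rate as long as all
  gains are non-negative — the constructor enforces that, so no clipping
  ever occurs. Archetype defaults: `cd` (centre 0, SD 4 ms, gain 80 Hz),
  `motor` (−30 ms, 20 ms, 15 Hz), `sensory` (+30 ms, 12 ms, 25 Hz),
  `apamin_cd` (= cd plus a 2-Hz plateau over +20…+200 ms), chosen to
  reproduce the qualitative histogram shapes of the CD, motor,
  reafferent and SK-blocked regimes at realistic infant-IO firing rates
  (a few Hz). Twitch rates default to 30/min of AS; the literature does
  not report per-muscle twitch rates for this preparation, so this is a
  placeholder of realistic order, not a measured value.

**What passing tests show — and don't.** The generator shares the
analysis's own structural assumptions (exponential bouts, half-sine
transients, Gaussian kernels, Poisson spiking). Tests against it
establish internal correctness: that each stage recovers what the
generative model planted, at the stated error rates. They do not
establish robustness to non-Poisson spiking (bursting, refractoriness),
EMG artifacts, electrode drift, state transitions that are not
step-like, or scorer disagreement about ambiguous bouts. Real-data use
should treat the scoring threshold and segment selection as the main
human-sensitive steps; the manual-segment override exists for exactly
that reason.

## 6. Numerical and degenerate-input choices

* All intervals are half-open `[start, end)`; the session clock starts at
  0; interchange files carry seconds with six fractional digits.
* State-boundary times are computed as `index / rate` (never
  `index × (1/rate)`) so boundaries agree bit-for-bit with sample times.
* A PSTH over zero events is an error, not a zero histogram — a silent
  zero would poison the rate view downstream.
* `area_under_curve()` refuses windows not aligned to bin edges, naming
  the misaligned bound.
* Smoothing kernels are normalized to unit mass; edge truncation is the
  only mass loss and stays within 1 % for interior-concentrated
  histograms.
* Band SDs are floored at 0.5 counts; the lower band is clipped at 0.
* Exact ties in muscle selection and peak location break
  deterministically (recorded order, earliest bin).
* Every randomized routine takes a seed; the group battery seeds once
  from `analysis_config$rng_seed` and is byte-reproducible.

## 7. Problem sizes used in the shipped studies

The package's own calibration and recovery studies (test suite and
`scripts/acceptance.R`) use: 500 null replicates of 600-s sessions
(events 0.5/s, spikes 5/s) for family-wise error calibration at
S = 1000 surrogates; 100 seeded runs per archetype with ~2200 twitches
each for latency-window recovery; two noise-free 400-s sessions for
scoring exactness; and 50 cohort replicates of 18 pups × 2 units (500-s
sessions) for the two-group histogram-shape study. These sizes give the
binomial margins quoted in the tests while keeping a full run on one CPU
in the minutes range.

## 8. Known limitations

* The scorer assumes a bimodal EMG amplitude distribution; preparations
  with graded tone need manual segments.
* Interval jitter conditions on cell counts; events with strong
  sub-cell temporal structure (e.g. rhythmic twitching faster than
  2 Hz) would narrow the effective null and the bands with it.
* The signed-rank pairing by cycle index assumes bouts of the two states
  alternate regularly; long recordings with missing states reduce to the
  shorter list.
* The max-deviation band is two-sided by construction; a strictly
  one-sided band (upper only) would be slightly tighter for
  excitation-only questions.
* Suppression (lower-band breaches) is flagged but plays no role in the
  shipped classification taxonomy.
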