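---
title: "Methods: population activity, unit classification and synapse morphometry in epicortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population activity, unit classification and synapse morphometry in epicortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicortex)
```

## What the package models

Human neocortical slices kept in vitro can generate *spontaneous population
activity* (SPA): recurring synchronous population bursts visible as local
field potential gradient (LFPg) transients with elevated multiunit activity
(MUA) and cell firing, recurring at roughly 1 Hz. epicortex implements the
analysis stack for such experiments: network-level SPA metrics across
pharmacological epochs (control, the NMDA-receptor antagonist APV, the
AMPA/kainate antagonist NBQX added on top, washout), rule-based single-unit
classification, firing and burst metrics, SPA-locked modulation of single
units, crosscorrelogram connectivity, automated cell counting in stained
sections, and the statistics used for electron-microscopic (EM) synapse
morphometry.

Because raw clinical recordings cannot be redistributed, the package ships a
ground-truthed synthetic generator that reproduces the statistical structure
each stage assumes. Every detector and estimator in the package is validated
against that known truth in the test suite.

## Data model

Five S4 classes carry the data:

* `UnitSet` — sorted spike trains, mean waveforms (microvolt, 20 kHz by
  default) and the laminar channel of each unit. Spike times are strictly
  increasing per unit and live in `[0, duration]`.
* `SPAEventSet` — event times of one SPA (each event's LFPg peak is its time
  zero), its layer label, and optional per-event LFPg/MUA trace windows on a
  common millisecond time base.
* `EpochSet` — non-overlapping labelled pharmacological intervals plus the
  excluded gaps, so annotated time is conserved exactly.
* `LayerMap` — channels 1–8 supragranular, 9–13 granular, 14–23
  infragranular, with per-recording overrides (electrode depth is corrected
  per patient).
* `CrossCorrelogram` — 1-ms-binned lag histogram over ±40 ms with its
  baseline statistics.

All on-disk formats are delimited text with headers; times are written as
decimal seconds with six fractional digits, so a write/read round trip is
exact to 1 µs. Windows are expressed in milliseconds in every API and
converted at the boundary.

## Epoching

Annotated bath blocks are trimmed by a guard interval at both ends
(rejecting transitions between pharmacological states) and capped at 300 s
from the trimmed start. The guard default is 30 s: transition kinetics of
bath-applied antagonists in an interface chamber are on the order of tens of
seconds, and the value is exposed (`segmentEpochs(guard_s=)`) because no
canonical transition length exists. Blocks shorter than the cap yield a
flagged short epoch rather than silently vanishing. SPA events falling in
excluded gaps are dropped by the epoch filters downstream; callers who want
them can widen the epochs.

## Unit classification

The decision tree uses the action-potential width at half of its maximal
amplitude (halfmax) on the mean waveform, the autocorrelogram (ACG; 1-ms
bins, 50-ms window), and the mean firing rate:

1. halfmax > 0.4 ms → principal cell (PC). Within PCs: **IB-PC**
   (intrinsically bursting) if the ACG global peak lies at 3–10 ms, is
   "high", and the post-peak bins decay exponentially with a short time
   constant; **RS-PC** (regular spiking) if the peak is beyond 10 ms or no
   prominent peak exists but firing is sustained; otherwise **UF-PC**
   (unclear firing).
2. halfmax < 0.2 ms → **IN** (interneuron). Width is the primary criterion;
   an atypically fast ACG is recorded as a flag, not used to override.
3. 0.2 ms ≤ halfmax ≤ 0.4 ms → **UC** (unclassified). The printed boundary
   wording puts 0.2 and 0.4 themselves in UC.

The qualitative ACG descriptors have no published numeric values, so they
are `ruleSet()` parameters with these defaults: a peak is *high* when it
reaches 2× the mean of the 30–50 ms tail **and** holds at least 10 spike
pairs; *fast exponential decay* means a fitted time constant ≤ 20 ms
(log-linear fit over the 20 ms after the peak); *sustained firing* means
≥ 0.5 Hz. The absolute-count floor matters: in sparse trains the tail mean
approaches zero and a pure ratio rule would promote single-pair noise bins
to "peaks". Halfmax width is measured on the dominant phase (the extremum
of larger absolute value) with linear interpolation between samples, which
makes it invariant to amplitude scaling and sign flips.

## Firing metrics

A burst is at least 3 spikes within a 20-ms window. The window wording
admits two readings (anchored window vs ISI chain); the implementation uses
a greedy left-to-right maximal-window scan — at spike *i* take the largest
*j* with *t(j) − t(i)* ≤ 20 ms, emit `[i, j]` if it holds ≥ 3 spikes, and
continue after it — matching the marking of burst start/end indices. A
spike exactly at the window edge is inside. An independent reference
implementation (`detectBurstsExhaustive`, window enumeration plus
left-to-right disjoint selection) is exported and equivalence-tested on
1,000 random trains. The burstiness index is the fraction of the epoch's
spikes inside bursts (a burst belongs to the epoch containing its first
spike); the ISI coefficient of variation uses the n−1 sample SD and is
reported missing below 3 spikes.

## SPA metrics and modulation

Event-triggered LFPg/MUA averages are baseline-corrected by subtracting the
mean over −150 to −50 ms; the amplitude is the maximum absolute deviation
within ±50 ms (whether the published amplitudes are peak-to-baseline or
peak-to-trough is not stated; peak absolute deviation is used and the
window is exposed). Recurrence frequency is events over epoch duration.
Epoch contrasts are paired across SPAs and gated by the D'Agostino–Pearson
normality test (paired *t* when normality holds or the sample is too small
for the test to be defined, Wilcoxon signed-rank otherwise) — mirroring the
parametric/non-parametric routing used throughout this literature.

Per-unit SPA modulation counts spikes in the baseline window [−150, −50) ms
and the peri-event window [−50, +50) ms (half-open, time zero inside peri;
the two windows tile [−150, +50) exactly). The unnamed paired
non-parametric test is taken to be the Wilcoxon signed-rank on per-event
count pairs. A unit is *increased* when the test is significant at α = 0.05
**and** the peri rate is at least 1.5× the baseline rate; *decreased*
symmetrically at ≤ 2/3; otherwise *unchanged*. Units silent at baseline but
firing peri-event have an infinite relative change; they are reported as
such and kept out of group means.

The Granger screen bins unit spikes and SPA events at 10 ms and compares a
restricted autoregression of the SPA series on its own past against one
that adds the unit's past, with an F-test on the unit-lag block. The model
order (≤ 10) is chosen by BIC of the unrestricted fit. BIC rather than AIC
is a deliberate numerical choice: with AIC the post-selection F-test
rejected ~8% of independent pairs at a nominal 5%, while BIC selection
keeps the null rejection at ~5% without losing power on planted
lagged dependence (both properties are asserted in the tests). The pass
level is α = 0.05, uncorrected, exposed as an argument.

## Connectivity

Crosscorrelograms count target-minus-reference lags over ±40 ms in 1-ms
bins. Positive lag means the target fires after the reference; both
orderings of every simultaneously recorded pair are scanned, so the
presynaptic candidate is always the reference (published displays may put
the causal peak on either side of zero; this convention fixes it to the
positive side). The baseline is the flank bins with |lag| between 20 and
40 ms — far enough that mono- and short polysynaptic peaks cannot
contaminate it — and a connection requires the causal-side peak to exceed
baseline mean + 2 SD **and** hold ≥ 20 spike pairs. The zero-lag bin is
excluded as a common-input artifact. Peak lag 1–3 ms → monosynaptic,
beyond 3 ms → polysynaptic. On independent ~1–2 Hz Poisson pairs over
300 s the 20-count floor dominates and the measured false-positive rate is
below 10% (in practice near zero); planted connections at transmission
probability ≥ 0.2 and presynaptic rates ≥ 3 Hz are recovered with ≥ 90%
sensitivity. Pre- vs postsynaptic member contrasts (rate, burstiness) use
the Mann–Whitney test and report medians with quartiles.

## Cell counting

The counter reproduces an adaptive-thresholding pipeline on brightfield
micrographs of immunostained cell bodies: channel selection by maximal
intensity SD, optional resize (default 0.5), Gaussian denoise, local-mean
adaptive threshold of dark objects (box half-width 25 px, offset 0.15 —
the offset must exceed the background texture amplitude while staying well
below the stain contrast), Gaussian blur, morphological opening then
dilation (3×3), connected-component outlines, and a size filter keeping
objects within mean ± 2 SD of the per-image area distribution. Counts are
deterministic for a fixed configuration. Density is count / (net tissue
area × 60 µm section thickness), reported per 10⁶ µm³ by default; the
area is supplied in physical units, which makes density invariant to
resizing. Published densities in this literature appear in idiosyncratic
volume units, so the reporting volume is a parameter rather than a
reproduction target.

## Synapse morphometry statistics

One record is one measured active zone; a perforated synapse (one terminal,
one postsynaptic element, active zone split in two) contributes two records
sharing a synapse id. This granularity lets both "synapses examined" and
"active zones measured" denominators be derived from one table, and the
perforated *ratio* is computed over active zones — the arithmetic that
reproduces printed ratios such as 49/240 → 20.4% and 81/281 → 28.8%, which
a per-synapse denominator does not. Group summaries report mean ± SEM and
median [Q1–Q3] with linear-interpolation quantiles. Contingency tables use
Pearson chi-square without continuity correction by default (this is the
variant that reproduces the published worked examples), with Yates and
Fisher variants on request. Group comparisons are routed by the
D'Agostino–Pearson gate to ANOVA/t or Kruskal–Wallis/Mann–Whitney, with
Dunn's rank-based follow-up (no further adjustment unless requested).
D'Agostino–Pearson and Dunn's test are implemented in-package and verified
against an independent reference implementation (frozen values) and the
Mann–Whitney normal z (2-group equivalence), respectively. The age
control is an OLS regression of per-patient perforated fraction on age and
epilepsy status.

## The synthetic generator

`simConfig()` fixes the study conditions; every generator is a pure
function of (config, seed). Defaults: 300-s epochs for the four bath
conditions; 60 units (12 per class); base rates per class bracket the
published per-condition means (RS-PC 1.5–4 Hz, IB-PC 1–3 Hz, UF-PC
0.1–0.4 Hz, IN 2–6 Hz, UC 0.5–2 Hz — the low UF band encodes "no sustained
firing", which is what makes a PC-width unit unclear); waveform halfmax
widths are margin-separated (PC 0.5–0.7 ms, IN 0.12–0.17 ms, UC
0.25–0.35 ms) so true classes are unambiguous; IB-PC trains expand 60% of
events into bursts of 3–5 spikes at 4.2–5.8 ms intra-burst ISIs, placing
the ACG peak inside 3–10 ms by construction. Regular-spiking cells draw
ISIs from a Gamma with shape 3 — a relative refractoriness that thins
short-lag ACG mass the way regular firing does, where a pure Poisson model
would occasionally fake a 3–10 ms peak. SPA events follow a Gamma-renewal
process (shape 2) at 1 Hz, so recurrence estimators are exercised under
non-Poisson regularity; LFPg transients default to 22 µV and MUA bumps to
1.2 µV over a 0.3 µV rectified floor, matching the published amplitude
scales. Peri-event modulation multiplies unit rates inside ±50 ms of each
event (thinning below 1, added Poisson excess above 1). Synthetic
micrographs place dark ellipses (radius 8 ± 1.2 px at a 5×-objective-like
scale, minimum separation 26 px) on a bright textured background. The EM
table draws perforation per synapse at the published group ratios (0.204 /
0.288), targets at the published group distributions, log-normal active
zone lengths (medians ~0.23 µm non-perforated, ~0.165 µm perforated) and
group ages of 60 ± 12 vs 35 ± 12 years.

What the generator does **not** emulate: overlapping-spike sorting errors,
electrode drift, non-stationary rates within an epoch, inhibitory CCG
troughs, realistic tissue texture, or patient-level clustering of synapse
measurements. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not robustness to every
artifact of real recordings.

## Numerical conventions and degenerate inputs

* Half-open windows `[a, b)` throughout; time zero belongs to the
  peri-event window; a spike exactly at a 20-ms burst-window edge is
  inside.
* Spike times closer than 2 µs are collapsed on generation so text
  round-trips at 1-µs precision preserve strict ordering.
* Fewer than 3 spikes → ISI CV missing; fewer than 10 usable events →
  modulation "unchanged" with an insufficiency flag; fewer than 3 pairs →
  contrasts report "insufficient"; single-group regressions are rejected.
* The D'Agostino–Pearson test is undefined below n = 8 and returns NA;
  gated comparisons then take their parametric default, which matches how
  small-n paired contrasts are handled in this literature.
* Chi-square expected cells below 1 trigger a warning suggesting Fisher.

## Problem sizes

The test suite and the acceptance script run synthetic problems sized to
the study regime: 60-unit populations over four 300-s epochs, 300-s SPA
series at ~1 Hz, 600-s planted-connection recordings, 512×512 micrographs
with 10–150 cells, and EM tables of ~450 synapses. Calibration properties
use 200–1,000 replicates. These sizes were chosen so the whole suite
exercises every property at meaningful statistical resolution while
remaining quick to run on one CPU.

## Known limitations

* The greedy burst scan is one of two defensible readings of the burst
  definition; the alternative chain reading gives different bursts on
  pathological trains. Both implementations ship.
* Monotonicity of burstiness under spike insertion holds for insertions
  into isolated bursts but not universally under greedy semantics (an
  inserted spike can re-anchor the scan); the tests assert the former.
* CCG significance uses the simple baseline mean + 2 SD rule, not
  jitter-corrected or convolution baselines; inhibitory troughs are not
  detected.
* The Granger screen is linear and unidirectional (unit → SPA), a
  screening statistic rather than a causal claim.
* Cell counting has no stereological correction and assumes dark-on-bright
  staining.
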