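---
title: "Band-wise EEG connectivity for detecting the First Night Effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-wise EEG connectivity for detecting the First Night Effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiconn)
```

## The problem

Sleep quality degrades in unfamiliar surroundings — the *First Night
Effect*. In horses, which are moved between stables for competition,
breeding or veterinary care, the behavioural signature of disturbed sleep is
weak (flight animals conceal discomfort), so the effect is sought in the
EEG instead. `equiconn` implements the full analysis chain for an
eight-electrode full-band DC montage (frontal, temporal, parietal and
occipital positions on each hemisphere, sampled at 1000/s): band
decomposition, three complementary connectivity statistics, spatial
grouping of electrode pairs, and the nonparametric contrasts between a
familiar ("home box") and a novel ("guest box") night, recorded in a
habituated sport-horse population and a non-sport population.

Because the original recordings are not publicly deposited, the package
ships a synthetic cohort generator that emulates the coupling structure the
analysis is meant to detect. Every pipeline stage is therefore testable
against known ground truth.

## Montage, pairs and groups

The eight channels are numbered down the right hemisphere (frontal 1 to
occipital 4) and back up the left (occipital 5 to frontal 8). All
C(8,2) = 28 unordered pairs are enumerated lexicographically; pair 19 is the
interhemispheric occipital pair (channels 4, 5) and pair 9 the right-sided
occipitotemporal pair (channels 2, 4). Pairs crossing the midline form the
horizontal groups H1–H4 and within-hemisphere pairs the vertical groups
V1–V3, the digit growing with the anterior–posterior distance ("diagonal
grade") between the two regions. Directly opposite pairs are H1; the only
grade-3 combinations (frontal to contralateral occipital) are H4, which
completes the partition: sizes 4, 6, 4, 2 (H) and 6, 4, 2 (V), summing
to 28.

```{r groups}
table(group_scheme()$group)
```

## Band decomposition

Bands are delta 0–4, theta 4–8, alpha 8–13, beta 13–30 and gamma
30–120 Hz. Each is isolated with a third-order Butterworth filter
(normalised cutoffs `Wn = f / (fs/2)`; delta is a pure lowpass so the DC
level of the full-band acquisition survives) applied forward and backward,
so the net phase shift is zero and the magnitude response is
`|H(f)|^2` — half-power at the cutoff for any Butterworth order. Edge
transients are handled with the conventional contract: odd-reflection
padding of `3 * (order + 1)` samples plus steady-state initial conditions,
which matches the behaviour of the standard scientific tools to within
coefficient rounding. No line-noise notch is applied by default; stretches
with extended line noise are excluded as artifacts instead (a notch is
available as `notch_filter()`). Artifact exclusion itself is a transparent
amplitude rule (`select_clean_segments()`, default 200 µV after per-channel
median removal, minimum 10 s) standing in for the expert visual selection
used on real data; expert-chosen segments can be supplied instead through
the `segments` arguments.

## The three connectivity statistics

**Rank-biserial maps.** For each band and pair the two-sample rank-biserial
statistic `r = 2U/(n_x n_y) − 1` is computed between the two filtered
channel series (ties count one half in U), with an optional percentile
bootstrap over time indices (default configuration: 3000 resamples,
interval 2.5–97.5%; resampling the two channels independently, with paired
and moving-block variants available). Per-cohort maps are the element-wise
median over subjects, and conditions are compared as home − guest.

One property of this statistic deserves emphasis, because it explains a
design choice in the synthetic generator. `r` depends only on the two
*marginal* distributions: it measures stochastic dominance, is 0 for
identical marginals (`rank_biserial(x, x)` is exactly 0) and ±1 under
complete separation. It is therefore blind to zero-mean coupling between
two channels — no amount of shared band-limited signal moves it. What it
*does* respond to, in a full-band DC recording whose delta lowpass keeps
DC, is a standing-potential difference between electrodes relative to the
in-band fluctuation. The generator consequently models the guest-box
occipital effect with two mechanisms: a shared zero-mean delta source
(detected by the zero-lag correlation and by coherence) *and* a DC
standing-potential asymmetry between the two occipital electrodes (detected
by the rank-biserial map). The DC mechanism also reproduces, rather than
assumes, the empirical finding that only the delta band shows
suprathreshold rank-biserial values: every other band is effectively
AC-coupled by its bandpass and removes the offset. A related caveat: a DC
shift on one channel raises the statistic for *every* pair containing that
channel, so the map is read through its maximum and through thresholding,
not as a pair-exclusive detector.

**Welch coherence.** Magnitude-squared coherence
`|S_xy|² / (S_xx S_yy)` is estimated with Hann windows of 2000 samples,
100 samples of overlap and a 1000-point transform at fs = 1000, giving a
1 Hz frequency grid. Since the window exceeds the transform length, each
tapered segment is wrapped modulo nfft and summed before the FFT — the
documented behaviour of the reference estimator under these parameters,
reproduced literally (a conventional `window = nfft` mode is available via
`welch_config(wrap = FALSE)`). Per-segment means are removed before
tapering. The cross-frequency variant compares the delta-filtered series of
one electrode with the raw series of the other; both orientations are
computed, and the spectrum below 4 Hz doubles as the within-delta
coherence, because coherence is invariant to deterministic linear filtering
of one input where the filter has gain. Cohort results are stacked into a
frequency × pair × subject cube, medianed over subjects, and masked at
*strictly greater than* 0.8. With K averaged windows the estimator has the
usual small-sample bias: independent inputs give mean coherence ≈ 1/K, so a
single window (coherence ≡ 1) is refused as degenerate rather than
returned.

**Grouped zero-lag correlation.** The normalized cross-correlation at zero
delay (mean-removed inner product over the product of norms — the lag at
which these recordings peak) is computed per band and pair, thresholded at
*greater than or equal to* 0.8, and summarised per spatial group as the
fraction of member pairs above threshold (so V3 with both pairs
suprathreshold scores 1). Note the deliberate asymmetry against the
coherence rule: the two thresholds are honoured exactly as stated for each
statistic (>= for correlation counts, > for coherence). Negative
correlations never count. Delta is excluded from the grouped analysis
because broadly shared slow activity saturates every group — a property the
test suite demonstrates on a synthetic whole-montage slow source.

Per-subject home − guest differences of the group counts are then compared
between populations, and raw counts between conditions within a population,
with a two-sided Wilcoxon rank-sum test: exact when both samples have at
most 10 observations without ties, otherwise the normal approximation with
tie and continuity corrections. One test per band × group cell (4 bands × 7
groups = 28 tests); no multiple-testing correction is applied by default,
mirroring the original analysis, with a Benjamini–Hochberg option
(`adjust = "BH"`) for stricter use.

## The synthetic cohort generator

`generate_recording()` builds each channel as independent 1/f background
(exponent 1, flattened below 0.1 Hz so a finite night is mean-ergodic,
default 2 µV RMS) plus a white floor (1 µV RMS) plus the configured
sources. A source injects `amplitude * (sqrt(c_i) * shared +
sqrt(1 − c_i) * private_i)` into each target channel, with shared and
private components unit-variance signals of the same kind — band-limited
noise (filtered with the *same* zero-phase filters the analysis uses, with
a discarded two-second warm-up so narrowband edge transients never enter
the data), sinusoids, or DC offsets. The coupling `c` is the
shared-variance fraction, so the expected band correlation of two target
channels is `sqrt(c_i c_j)`, diluted only by the small in-band background;
`ground_truth()` evaluates that dilution exactly on a dense frequency grid
from the component spectra and also provides the normal-approximation
expectation of the rank-biserial statistic from the DC-induced mean
separations. Per-recording coupling jitter (uniform ±0.05 by default)
supplies between-subject heterogeneity. All randomness derives
deterministically from the cohort seed, subject, population and condition,
so cohorts replay byte-identically.

`default_presets()` encodes the qualitative study pattern with 6 subjects
per population and 120 s recordings (about 60 Welch windows, a size chosen
for stable coherence medians at modest runtime; the amplitudes keep signals
in the 10–50 µV range of the acquisition system):

- *guest nights* (both populations): a shared delta source over channels
  2/4/5 with coupling 0.97 at the occipital pair and 0.9 at the temporal
  channel — pair 19 carries the strongest slow coupling and pair 9 shows
  suprathreshold coherence across the 1–3 Hz bins — plus a ±25 µV occipital
  standing-potential asymmetry driving the delta rank-biserial map;
- *non-sport contrast*: guest-only alpha sources on two H1 and the two H4
  pairs (coupling 0.9 vs 0.25 at home), giving clean alpha-band
  interhemispheric rejections, and near-threshold (coupling 0.8)
  theta/beta/gamma sources whose jitter produces realistic between-subject
  count variability;
- *sport habituation*: identical moderate (coupling 0.55) alpha-to-gamma
  sources in both conditions, so home − guest count differences concentrate
  at zero and their spread is smaller than in the non-sport cohort.

What the generator does *not* emulate: volume conduction and reference
effects, sleep microstructure (spindles, K-complexes, stage transitions),
nonstationary arousals, movement or line-noise artifacts, and any
behavioural covariates. Passing tests on this synthetic cohort therefore
demonstrate that the pipeline detects the modelled coupling structure at
the stated sizes and thresholds — not that real horse EEG behaves this way.

## Numerical choices and degenerate inputs

- Filters are designed by the standard bilinear-transform routine and
  checked for pole stability; band edges at or above Nyquist are design
  errors (the gamma band needs fs > 240).
- Zero-phase filtering needs more than `3 * (order + 1)` samples; shorter
  inputs are length errors.
- Coherence needs at least two windows; fewer is a degeneracy error. The
  estimator clips to [0, 1] only within floating-point tolerance and leaves
  zero-power bins as `NA`.
- Rank-biserial U uses midranks, making the O(n log n) rank-sum identity
  exact under ties; the test suite cross-checks it against an O(n²)
  counting oracle.
- Bootstrap intervals are order statistics `sorted[ceiling(n p)]`; the
  interval is reported even when it does not bracket the point estimate
  (percentile bootstrap makes no such promise).
- The rank-sum test switches from the exact to the approximate path at
  n > 10 or in the presence of ties; fully tied samples short-circuit to
  p = 1 (the approximation's variance is zero there).
- Zero-variance inputs to the zero-lag correlation are errors, not NA.
- Missing cohort entries propagate as absent (`NA` slices, dropped
  subjects with warnings), never as zeros.

## Known limitations

The rank-biserial map's marginal-dominance semantics (above) mean its
values are not "correlations" in the joint sense despite the conventional
name; the zero-lag correlation and coherence modules carry the
coupling-sensitive part of the analysis. EDF export quantises to 16 bits
over each channel's range and requires whole-second recordings. The
amplitude-threshold artifact rule is a deliberate simplification of expert
review. Statistical results on the synthetic presets say nothing about
p-values attainable on the real recordings, which would require the
original data.
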