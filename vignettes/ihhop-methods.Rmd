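---
title: "Recurrence-threshold screening of intermittent oximetry patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-threshold screening of intermittent oximetry patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous pulse-oximetry (SaO2) recordings from patients at risk of
sleep-disordered breathing — here, hemodialysis patients monitored during
treatment — intermittently show *intermittent high-frequency
high-amplitude oximetry patterns* (IHHOP): trains of sawtooth-shaped
desaturation–resaturation cycles with periods of tens of seconds and
depths of a few percentage points. These trains track sleep-related
breathing events, but the conventional detection route (counting
baseline-referenced desaturation events) is fragile: it needs a reliable
baseline, which patients with chronically low or drifting saturation do
not offer, and its event definition breaks down at low sampling rates.

`ihhop` implements a recurrence-based alternative: a per-segment scalar
biomarker that needs no baseline, plus the conventional metrics as the
reference, plus the classification harness that turns the biomarker into
a screening score.

## The biomarker

For a signal segment $x_1, \dots, x_N$, two samples are *recurrent* at
threshold $\varepsilon$ when $|x_i - x_j| \le \varepsilon$; the binary
matrix $R_{ij}$ of recurrent pairs is the recurrence plot. The samples
are compared directly (no phase-space embedding): similarity of raw
saturation values is the relevant notion here. *Determinism* is the
fraction of recurrent points that sit on diagonal runs of at least
$\ell_{\min}$ consecutive recurrent pairs,

$$\mathrm{DET}(\varepsilon;\ell_{\min}) =
  \frac{\sum_{\ell \ge \ell_{\min}} \ell\, P(\ell,\varepsilon)}
       {\sum_{\ell \ge 1} \ell\, P(\ell,\varepsilon)},$$

where $P(\ell,\varepsilon)$ counts maximal diagonal lines of length
$\ell$ (the line of identity is excluded by a Theiler window of 1).
$\mathrm{DET}(\varepsilon)$ rises from 0 to 1 as $\varepsilon$ grows; the
biomarker is the threshold at which it rises fastest,

$$\varepsilon_{\mathrm{opt}} = \arg\max_\varepsilon
  \frac{d\,\mathrm{DET}(\varepsilon;\ell_{\min})}{d\varepsilon}.$$

Ordered, quasi-constant saturation produces long diagonals already at
thresholds comparable to the measurement noise, so
$\varepsilon_{\mathrm{opt}}$ is small; large irregular excursion trains
delay the DET rise to thresholds comparable to the excursion amplitude.
Tracked in rolling windows, $\varepsilon_{\mathrm{opt}}$ becomes a
real-time intermittency biomarker.

### Parameters that matter

- `l_min` — minimal counted diagonal length, in samples. It should span
  roughly 10 s of signal: 10 samples at 1 Hz, 2 at 0.1 Hz
  (`l_min_for_fs()`). Shorter values let chance alignments of noise count
  as structure; much longer values discard the cycle-scale structure of
  interest.
- threshold grid — 100 uniform points from 0 to the segment's range, with
  a 0.01-percentage-point spacing guard for near-constant segments
  (`default_eps_grid()`). The guard keeps the grid meaningful when a
  window is flat.
- `smooth_w` — DET-curve smoothing window (grid points) used before
  differentiation. The empirical DET curve is stepwise constant (it can
  only change where a pairwise distance sits), so the raw adjacent-point
  derivative argmax degenerates to the location of the single largest
  distance atom, which sits at small thresholds regardless of episode
  amplitude; in simulation this made the biomarker independent of the
  injected dip depth. The biomarker-level functions therefore average the
  DET curve over 5 grid points (about 5% of the threshold span) before
  taking central differences — wide enough to pool the distance
  granularity, narrow compared to the curve's structure. The low-level
  `epsilon_opt()` keeps the raw curve (`smooth_w = 1`) as the definition.
- windows — 5-min windows with 1-min steps for distribution and
  classification work; 10-min windows when comparing against the
  desaturation density. The final window is anchored to the end of the
  record so the recording tail is always covered.
- degenerate windows (constant signal, or no off-identity recurrence at
  any grid threshold) are flagged and excluded from downstream
  distributions rather than silently scored 0.

## Preprocessing

Raw series pass through floor-clipping (samples below 75% SaO2, plus
dropouts encoded as zeros or missing values, are removed and linearly
interpolated; boundary runs are filled by nearest-valid constant
extension so no trend is invented), a zero-phase 4th-order Butterworth
low-pass at 0.25 Hz (forward-backward filtering with odd-reflection
padding, so event timing and DC level are preserved), and optional 10-s
block averaging down to 0.1 Hz (trailing partial blocks dropped for a
deterministic length). Filtering happens at the original rate, where it
doubles as an anti-alias stage before decimation.

## Reference metrics

The baseline is the mean of the first 3 min and is held fixed. A
desaturation is a maximal run strictly below baseline − N (N percentage
points, N = 3 by default) lasting 10–60 s, timestamped at its first
sample; runs outside the duration bounds are discarded. ODI is events per
hour of the reference period (sleep intervals when annotated); ODD at
time $t$ counts events in the half-open trailing window $(t-600, t]$ s.
At 0.1 Hz the 10-s minimum duration equals one sample — the known
fragility of duration-based rules at low rates, and part of the
motivation for the recurrence biomarker.

## Classing and screening

Per-segment biomarker values are split into "no / maybe / with IHHOP" by
exact 1-D natural-breaks classing (`jenks_breaks()`, dynamic programming
over all contiguous partitions; interior breaks reported as midpoints
between adjacent class-edge values). The shipped defaults 0.33/0.73
apply to 5-min, 1 Hz, $\ell_{\min}=10$ analysis and should be re-derived
for other settings, since the biomarker scale depends on segment length,
rate and $\ell_{\min}$.

For screening, each 5-min segment gets a severity label from its
desaturation count (count × 6 → events/h, then the ASDS cut-offs 5/15/30,
boundaries to the higher class), binarized under one of three schemes
(">Mild", ">Moderate", ">Severe"; positive sets are nested). The harness
z-scores features on the training split only, uses a 70/30 stratified
split, fits discrete AdaBoost over decision stumps, LDA and a random
forest, and reports test ROC/AUC plus sensitivity, specificity, PPV and
NPV at the ROC point farthest from (FPR = 1, TPR = 0). Segments are
treated as independent, so two segments of one recording may land in
different splits. All stochastic steps flow from one explicit seed.

## The synthetic generator

No public oximetry corpus accompanies the method, so the package ships a
generator (`generate_record()`, `generate_corpus()`) that emulates the
study's recordings: baseline level 94.3% with a between-record SD of
2.1%, slow sinusoidal drift (0.5% amplitude, 30-min period), white
measurement noise (SD 0.3%), and scheduled episodes of either sawtooth
desaturation trains (per-cycle period uniform in 30–90 s, depth uniform
in 3–10 percentage points, slow desaturation over 80% of the cycle and
fast resaturation over 20%) or single rectangular desaturations. The
amplitude/period ranges are modelling choices — the clinical source
reports no quantitative IHHOP statistics — chosen to match the described
phenomenology. Depth and baseline are independent, so trains above and
below the conventional 90% hypoxemia line are both generatable. Noise is
white and pre-filter; the preprocessing chain is expected to run on
generator output just as on real data.

What the generator does *not* model: device quantization, motion and
perfusion artifacts, graded within-episode severity drift, sleep staging,
and any coupling between baseline level and episode intensity. Passing
tests on this generator show that the pipeline recovers planted structure
under realistic noise; they do not certify clinical performance.

## Reproduction study sizes and observed behavior

The packaged reproduction (`scripts/acceptance.R`, mirrored in the test
suite) uses 1200 five-minute 1-Hz segments (half with episode trains) for
the screening benchmark and 10 three-hour sessions with 3–5 episodes each
for the biomarker-vs-density comparison — sizes chosen to give stable
statistics at desk scale. On this corpus the best classifier reaches AUC
≈ 0.98 with sensitivity and specificity ≈ 0.9–0.95, comfortably inside
the clinically reported regime (AUC > 0.90, both rates > 0.8).

For the density comparison, the analysis period per session is the
*sleep-block analog*: one window length before the first annotated
episode onset to one window length after the last episode end. This
mirrors the clinical computation, which restricts the correlation to
reported sleep — a block containing event clusters, the quiet sleep
between them, and both metrics' onset rise and offset decay. The mean
per-session Pearson r on the default corpus is about 0.5 (0.50–0.55
across seeds), positive and substantial but below the ≈0.7 reported
clinically. The shortfall is
structural and worth knowing: with independently drawn per-cycle depths
and periods, episode intensity is internally unstructured, so within an
episode both metrics saturate and decorrelate (their within-episode
correlation is ≈0), leaving the quiet↔active transitions to carry all
covariation; clinical recordings add graded severity variation across the
night that the generator deliberately does not invent. The whole-session
correlation of the same two series is ≈0.69.

## Numerical choices and degenerate inputs

- Zero distance counts as recurrent (right-continuous step), so the
  recurrence matrix has a unit diagonal even at $\varepsilon = 0$.
- Derivative estimation: central differences in the grid interior,
  one-sided at the ends; ties break toward the smallest threshold (a
  single unit DET step between grid points reports the lower point).
- A segment whose DET curve is flat (constant window; or an empty
  diagonal histogram at every threshold, DET sentinel 0) returns the
  smallest grid value flagged `degenerate`.
- Desaturation comparisons are strict (`< baseline − N`); samples exactly
  at the threshold end a run. Durations live on the sample grid.
- The exact natural-breaks program is $O(k n^2)$ and refuses $n > 10^4$;
  subsample larger corpora.
- Block averaging requires the block to be an integer multiple of the
  sampling interval; the trailing partial block is dropped.

## Known limitations

The biomarker scale is in raw SaO2 percentage points and does not
transfer across rescaled inputs; the shipped class thresholds are
setting-specific. The screening harness uses the classifiers' library
defaults (stump AdaBoost 50 rounds, 500-tree forest, LDA) with no
hyperparameter tuning. Patient-level aggregation, alternative ODI
variants, other recurrence quantifiers and proprietary device formats
are out of scope.
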