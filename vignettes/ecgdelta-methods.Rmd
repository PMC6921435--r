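---
title: "Methods: paired ECG segment analysis of the glucose response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired ECG segment analysis of the glucose response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgdelta)
```

## The design and its statistics

The package analyses a paired-session design: each participant contributes a
glucose (G) session, with 75 g of glucose ingested 30 minutes in, and a
control (NG) session recorded under identical conditions. Nine per-beat
series are derived from the single-channel ECG of each session — RR-I (the
HRV series), HR, R-H, P-H, QRS, PRQ, QT, QTC and ST — and the question asked
of each is directional: did its distribution shift between NG and G, and how
consistently across the cohort?

The statistical layer deliberately avoids hypothesis tests. Per session the
distribution of a series is reduced to six boxplot statistics (mode, mean,
median, Q1, Q3, interquartile range); minima and maxima are excluded as
noise-sensitive. The G-minus-NG delta of each statistic is classified as
Increase/Decrease/Equality, the cohort share of each direction is banded
into statuses (h ≥ 80 %, 60 % ≤ m < 80 %, else l), and a segment is called
affected when at least four of its six parameter statuses are moderate or
strong. The spectral layer asks the same directional question of the Welch
periodogram peak of each series, with a single ≥ 60 % occurrence rule.
Sensitivities are the shares of each status label.

## Numerical conventions

Several quantities are only pinned down once a convention is chosen; the
package fixes these explicitly:

* **Quartiles** interpolate linearly between order statistics (Q1 at rank
  1 + (n−1)/4), the common analytic default, so tests can assert exact
  values.
* **Mode on continuous data** is computed after quantising each series to
  its measurement resolution — 1 ms for interval series, 1 bpm for HR,
  0.01 mV for wave heights — taking the most frequent quantised value and
  breaking ties towards the smallest. An unquantised mode of a continuous
  series is degenerate.
* **Direction equality band.** A paired delta is classed Equality when its
  magnitude is below the same measurement resolution. This matters: with
  roughly 7&nbsp;000 beats per session, the sampling noise of a session
  median is of order 0.1–1 ms, so under a true null the sign of a raw delta
  is a fair coin. With 16 participants a fair coin reaches the 60 % status
  band in about 45 % of cohorts per parameter — the scoring layer would
  call unaffected segments "affected" almost half the time. Requiring a
  delta to exceed the resolution of the underlying measurement before it
  counts as a direction restores a meaningful null (sub-resolution shifts
  are not observable changes) while leaving real effects, which move these
  statistics by tens of units, untouched. The band is a per-call argument
  (`equal_tol`); setting it to `1e-9` recovers strict sign classification.
* **Equality-dominated parameters** contribute nothing to the occurrence
  score: "change" counts directional (I/D) patterns only.
* **Status banding** uses the exact percentage; rounding (half-up, so
  13/16 prints as 81 %) is applied only for display.
* **Welch estimator**: rectangular window, frame length M = 256, overlap
  10, step R = M − overlap, K = floor((N − M)/R) + 1 full frames (trailing
  samples discarded), per-frame periodogram |DFT|²/M, one-sided grid
  ω_k = k·fs/M with fs = 0.8 nominal. The series mean is subtracted first
  and the zero-frequency bin is excluded from the peak: interval series
  have large constant offsets (RR ≈ 900 ms) whose DC leakage would dominate
  every peak, and the mean level is already compared by the boxplot layer,
  so the peak is made to reflect oscillatory content. Both choices are
  config switches (`demean`, `include_dc`) because the convention used in
  the original analysis is not recorded; the nominal 0.8 only scales the
  frequency axis and cannot change which of two peaks is larger.
* **QTC** uses the Bazett correction QT/√(RR in s), the default clinical
  choice where the source analysis says only "corrected QT".
* **PRQ** is measured from P onset (not P peak) to the R peak; **ST** from
  the S wave to T onset. **Heights** are raw signal values at the peak
  sample, without baseline subtraction.
* **Fiducial indices** are 1-based sample positions (the natural R
  convention); all intervals are converted to milliseconds at extraction,
  so nothing downstream depends on the index base.

## The synthetic generator

No recordings are deposited with the original study, so the package ships a
generator whose defaults emulate the study conditions: paired 7200 s
sessions at 500 Hz, baseline 66 bpm (≈ 7 900 cycles per session, the same
order as the reported ≈ 13 000 cycles per participant over both sessions),
beat-to-beat RR jitter of 40 ms, respiratory sinus arrhythmia of 25 ms at
0.25 Hz, white measurement noise of 0.02 mV, and a glucose effect ramped in
linearly from 1800 s over 300 s and then sustained. Blood glucose in fact
peaks and declines, but the scoring layer reads only the *direction* of
change over the session, so a sustained effect is sufficient and simpler.

Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with
participant-specific amplitudes, widths and offsets; wave onsets and ends
are defined where a bump falls to 5 % of its peak (centre ± k·width,
k = √(2 ln 20)), which is also the delineator's baseline-return rule, so
generator ground truth and a correct delineation agree by construction.
Per-beat physiological variation is injected as interval jitter (QT 4,
ST 3, PRQ 3, QRS 2 ms), multiplicative amplitude jitter (3 %) and a 4 %
respiratory modulation of wave heights; the T wave's centre and width are
solved per beat from the target QT and ST spans. Effect multipliers apply
to the corresponding generator parameter; `hr_gain` and `rr_gain` both act
on the RR series (multiplier `rr_gain/hr_gain`), since HR ≡ 60000/RR has no
independent parameter. R times are snapped to the sample grid so the R
sample carries the full configured height. Beat times are placed
sequentially (each RR depends on its own onset time), everything else is
vectorised, and all randomness derives from
`(participant_seed, random_seed)`.

What the generator does *not* emulate: real QRS morphology (notches,
biphasic T waves), baseline wander and electrode artifacts, arrhythmia,
QT–RR hysteresis, or the actual blood-glucose trajectory. Passing tests on
this synthetic cohort therefore demonstrate that the pipeline's stages are
correct and that the scoring layer recovers directional effects of the
injected kind — not that real recordings would be delineated with the same
accuracy.

## Delineation

R peaks come from a Pan-Tompkins chain (zero-phase 5–15 Hz Butterworth
band-pass, derivative, squaring, 150 ms integration, adaptive signal/noise
threshold with a 200 ms refractory period, refinement to the raw-signal
maximum). Q and S are the nearest local minima within 80 ms of R; the P
peak is the maximum in (R − 250, R − 80) ms and the T peak in (R + 120,
R + min(450, 0.7·RR)) ms; onsets and ends are found searching outward from
each peak for the first sample back within 5 % of the local baseline
(median of the quiet pre-P span). All window constants are configuration in
spirit — they are named constants in one function — because the original
analysis delegated delineation to acquisition software whose settings are
unrecorded. A landmark whose search fails (e.g. an absent P wave) is NA, so
the beat is lost only by the series that need it; the first and last beats
are always dropped. Cleaning removes impossible values (HR outside
(20, 250) bpm, non-positive intervals) and beats beyond 5 MADs from the
per-series median, skipping the MAD rule for zero-spread series, and warns
when a series loses more than 20 % of its beats.

## Problem sizes used by the tests

The delineation-recovery check runs one clean 600 s session at 500 Hz
(≈ 670 beats), on which every fiducial must fall within 5 ms of ground
truth for ≥ 99 % of beats and every extracted series within 2 sample
periods of its true value (QTC, which compounds the QT and RR measurement
errors, is allowed 3 sample periods; heights 0.01 mV). The end-to-end
Monte-Carlo runs 20 replicates of a 16-participant cohort with 3600 s
sessions — long enough that session statistics are estimated to well under
the equality band, and the strong injected gains (HR ×1.1, RR ×0.9,
QT/ST/PRQ ×0.95) dominate at either session length — requiring the five
affected segments to be recovered and the gain-free ones rejected in
≥ 90 % of replicates, and a null cohort to yield "No" for at least 8 of 9
segments equally often. QTC is asserted in neither direction there: with
RR shortened ≈ 18 % and QT ≈ 5 %, Bazett coupling raises QTC ≈ 5 %, so it
is genuinely affected under these conditions despite having no gain of its
own.

## Known limitations

* The scoring layer inherits the original design's lack of inferential
  control: with 16 participants the 60 %/80 % occurrence bands are coarse,
  and the spectral single-parameter rule in particular has an irreducible
  false-positive rate under a strict-sign null (a periodogram peak
  comparison is never exactly tied), which is why the equality band applies
  to the statistical layer where measurement resolution gives it a natural
  scale.
* Beat-indexed series are treated as evenly sampled in the spectral layer,
  as in the original analysis; no Lomb-Scargle or resampling correction is
  applied.
* The Welch peak of a white-noise-like series falls as the number of
  averaged frames grows, so comparing sessions of different lengths biases
  the spectral direction of unaffected segments; paired sessions of equal
  duration largely cancel this, but an elevated G-session heart rate still
  yields more beats and hence slightly more frames.
* Single-lead, sinus-rhythm ECG only; no arrhythmia handling, U waves
  ignored.
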