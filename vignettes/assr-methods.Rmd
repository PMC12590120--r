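---
title: "Methods: mobile-EEG ASSR analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobile-EEG ASSR analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`ambulassr`: what each stage computes, which parameters matter and why their
defaults were chosen, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The measurement model

Dichotic frequency tagging assigns each ear its own amplitude-modulation
rate: a 1000 Hz carrier modulated at 39 Hz in the left ear and 41 Hz in the
right ear (100% depth). Auditory cortex entrains at the modulation rate, so
scalp power at 39 and 41 Hz indexes the cortical gain of the left- and
right-ear input respectively. Three derived quantities drive all analyses:

* **Parameterized power** — oscillatory power over and above the aperiodic
  (1/f) background, obtained by spectral parameterization (below); used for
  state comparisons (stand / step / walk) of ASSR and occipital alpha power.
* **Lateralization index** — `(P39 − P41)/(P39 + P41)` on time-resolved
  band powers; bounded in [−1, 1], positive when the left-ear input is
  preferred, invariant to common gain, antisymmetric under swapping the
  ears. Samples with zero power sum are flagged `NA`, never silently zeroed.
* **Perturbation response** — after a 100 ms noise-burst interruption of one
  (or both) tones, the trial-averaged time-resolved ASSR power is
  log-baselined against the `[−400, 0]` ms prestimulus window and averaged
  over `[0, 700]` ms, in dB. Trials are averaged *before* baseline
  correction; the log-ratio form makes the measure invariant to global
  power scaling.

## Preprocessing

EEG is rereferenced to the average of the two earlobe electrodes, then
filtered zero-phase (forward–backward Butterworth): 1 Hz high-pass (order 2
per pass), 100 Hz low-pass (order 4), 49.5–50.5 Hz band-stop (order 2)
against line noise. Zero-phase filtering was chosen so ERP latencies are not
shifted; orders are configurable in `filter_spec()`. The passband is flat to
within 1 dB over 2–45 Hz and 50 Hz is attenuated by far more than 20 dB
after the two passes.

Dimensionality is reduced to 16 principal components (18 scalp EEG channels
in the supported montage) and decomposed with extended Infomax ICA
(`ica::icaimax`, tanh nonlinearity with kurtosis-based sign switching — the
ASSR sources are sub-Gaussian sinusoids, which plain Infomax cannot
separate). The seed, iteration cap and tolerance are recorded in the
decomposition object; a FastICA backend is available behind the same
contract. EOG channels are excluded from the decomposition. Welch spectra
(Hamming window, 1 s segments, 50% overlap, one-sided density) are computed
per component on the resulting 1 Hz grid.

**Component selection.** ASSR components must show a parameterized-spectrum
peak centered within ±0.5 Hz of 39 or 41 Hz with over-aperiodic height
above 0.10 log10 units *and* fitted width at most 4 Hz FWHM. The width cap
is this package's addition: a steady-state response is a spectral line, and
without the cap broad spectral wiggles over the aperiodic fit occasionally
matched the target frequency on signal-free data. Alpha components must
satisfy four criteria: a local spectral peak between 6 and 14 Hz; peak width
(distance between the adjacent local minima, plateaus tie-broken toward the
lower frequency, spectrum edges counting as minima) of at least 4 Hz, taking
the widest in-band peak when several exist; peak power at least three times
the mean power between 20 and 50 Hz; and maximum absolute topography weight
over O1/O2/POz exceeding the maximum over all other sensors. All accepted
components are back-projected jointly — multiplicity is expected and allowed.

## Spectral parameterization

Power spectra on 1–48 Hz are decomposed into an aperiodic component
(`log10 P = offset − exponent · log10 f`; no knee term, appropriate for a
fit range ending at 48 Hz) plus Gaussian peaks in log-power. The algorithm
is guess-and-refine: a robust aperiodic fit (ordinary least squares, refit
on the half of the points least above the first fit, since peaks only push
residuals upward); then repeatedly take the largest point of the flattened
spectrum as a peak guess (center at the argmax bin, width from the
half-height span) and re-fit **all** current Gaussians jointly by bounded
Levenberg–Marquardt, with each center confined near its guess. Extraction
stops when the next candidate falls below max(0.05 log10 units, 2 SD of the
current flattened spectrum) or at 6 peaks; widths are bounded to 1–12 Hz
FWHM. The joint refit with bounded centers is essential for this design:
the 39 and 41 Hz lines sit 2 Hz apart on a 1 Hz grid, and unconstrained
per-peak fits merge them into one broad Gaussian near 40 Hz.

`parameterized_power()` returns the height (log10 units over the aperiodic
fit) of the peak closest to the target within 1 Hz, 0 when none; for alpha
it sums the heights of all peaks with centers in 8–14 Hz. The unit
convention (heights in log10-over-aperiodic units) is recorded in the
object; multiplying an input spectrum by k shifts only the offset by
log10 k.

## Walking-path extraction

Turns are read from the waist gyroscope's vertical-axis angular velocity
(yaw). The trace is low-pass filtered at 0.3 Hz (zero-phase spectral filter;
the turn fundamental on a ~12 s lap is ~1/12 Hz, the gait ripple ~2 Hz, so
the cutoff sits comfortably between them and is configurable). Positive
local maxima are left-turn apices and negative minima right-turn apices
(right-hand rule about the vertical axis; the convention is flippable and
must match the generator's). Apices closer than 3 s merge to the larger
magnitude; turn duration is the span where |yaw| exceeds half the apex
magnitude. The detection threshold defaults to half the median absolute
extremum magnitude of a calibration pass but never falls below 10 deg/s —
the absolute floor is this package's choice so that a standing recording
(noise-only yaw) yields zero turns rather than adapting its threshold down
to the noise.

Trials are cut at apex ± 2 s (2001 samples at 500 Hz, t = 0 at the lock
sample); motion-clock (120 Hz) event times are mapped to the nearest EEG
sample, a round-trip error below one EEG sample. Events whose window crosses
a recording edge are dropped and counted.

## Time-resolved power and the turn-locked contrast

Band power is the squared magnitude of the analytic signal of the
band-passed trace (center ± 0.5 Hz). Both the band-pass and the analytic
signal are built in a single zero-phase spectral pass (cosine-tapered
transition of 0.5 Hz, mirror padding against wrap-around); for a ±0.5 Hz
band this is cleaner at the edges than a very long FIR. Power is computed on
the continuous block *before* epoching; the first and last 0.5 s are flagged
as edge-contaminated, and turn trials touching them are dropped.

The turn-locked contrast epochs the lateralization index by apex per
direction and feeds a paired cluster-based permutation test: pointwise
paired t statistics, clusters formed by contiguous |t| above the two-sided
p < 0.05 threshold, cluster mass = sum of t, and a max-|mass| null built
from 1000 per-pair sign flips (Monte-Carlo p with the plus-one correction;
a one-sided variant is available). Pairing is by trial index — on the
8-shaped path directions alternate strictly, so counts match; a study with
several participants would pair at the participant level instead. The same
machinery applied at 37 and 44 Hz is the specificity control: those bands
carry no tagged input, so any systematic contrast there would indicate a
broadband (e.g. movement-related) confound.

## Statistics

* `rm_anova()` implements the textbook sums-of-squares decomposition for
  balanced fully-within designs (Möbius inversion over cell means; the
  error stratum of each effect is its interaction with subjects).
  Greenhouse–Geisser epsilon is computed per effect from the covariance of
  the within-subject cell scores in orthonormal-contrast form, clipped to
  [1/df, 1], and applied to effects with more than one numerator df
  (`p_gg`). The implementation is cross-checked against `aov()` error
  strata in the test suite.
* `fdr_adjust()` is Benjamini–Hochberg step-up adjustment.
* `robust_spearman()` flags bivariate outliers by three methods — boxplot
  rule (1.5 IQR), median-absolute-deviation rule (cutoff 2.24) and an
  S-outlier rule on the Rousseeuw–Croux Sn robust scale (cutoff 2.24; a
  point is flagged by a method if either coordinate is) — and removes only
  points flagged by *all three*. Spearman's rho uses average ranks for
  ties; p is one-sided in the declared direction where the hypothesis is
  directional.

## The synthetic-session generator

`simulate_eeg()` builds `topographies × sources + noise` at 500 Hz on an
18-channel scalp montage (plus two earlobe references and six noise-only
EOG channels):

* **ASSR sources**: sinusoids at 39 and 41 Hz with slightly lateralized
  frontocentral Gaussian topographies (left-ear source weighted toward the
  contralateral hemisphere). Amplitudes per movement state default to
  0.35 / 0.55 / 0.80 µV (stand / step / walk) — inside the published range
  for 40 Hz ASSRs and ordered as walking > stepping > standing.
* **Alpha source**: an 8–14 Hz narrowband carrier multiplied by a slow
  positive envelope (waxing/waning bursts; this yields the super-Gaussian
  amplitude statistics of real alpha that ICA needs to separate it), with
  occipital topography and state amplitudes 4 / 3 / 2 µV
  (standing > stepping > walking).
* **Background**: ten spatially smooth 1/f sources (offset 0, exponent 1.2,
  flat below 0.5 Hz) mixed to the scalp, plus 0.5 µV white sensor noise per
  channel. Real EEG background is spatially correlated and low-dimensional;
  independent per-channel noise would make blind source separation
  ill-posed by construction.
* **Burst effects**: each burst multiplies the affected ASSR source
  (left ear → 39 Hz, right → 41 Hz, central → both) by a 50% amplitude dip
  held for 300 ms with 150 ms exponential recovery, and adds P1/P2 ERP
  templates (Gaussians at 165 ± 15 ms, 2.5 µV and 325 ± 25 ms, 4 µV at the
  topography peak).
* **Turn-phase modulation**: within apex ± half a turn duration the
  turn-side frequency is scaled by gain g (default 1.5 in pipeline runs)
  and the other by 1/g, with the assignment flipping at the apex — the
  ground-truth version of the turn-locked lateralization pattern.
* **Gyroscope**: walking yaw is a sinusoid with the lap period (~12 s, so
  apices alternate every 6 s and the half-magnitude turn duration is 4 s),
  plus a 2 Hz gait ripple and white noise; standing is noise only. Burst
  schedules draw inter-burst intervals uniformly from 3–7 s per kind
  (8 per kind standing, 32 walking in pipeline defaults).

Everything is deterministic given the seed; ground truth (apex times and
directions, source waveforms, topographies, amplitudes) rides along as an
attribute for recovery tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genuine head-model mixing (topographies are
Gaussian profiles, not leadfields), eye movements and muscle artifacts
(EOG channels carry plain noise), movement artifacts coupled to gait, the
auditory pathway between the stimulus and the cortical source (sources are
modeled directly at the modulation frequencies), non-stationarity of the
background, and between-participant variability. Sessions stand in for
participants in group-level checks.

## Numerical conventions and problem sizes

Epoch windows are ±2 s; the printed analysis windows ([−400, 0], [0, 700],
[−700, 0], [140, 190], [300, 350] ms) are honored inclusively as printed.
The P1 window follows the 140–190 ms convention; the 150–200 ms variant
that also appears in the literature is available as a preset. Sample
indices are 0-based in event tables; epoch time axes are in seconds with
t = 0 at the lock sample. Tie-breaks: spectral plateaus resolve toward the
lower frequency; a burst exactly at an apex belongs to the post-apex
(opposite-preference) half.

The test and acceptance suites run on desk-scale problem sizes chosen to
keep full runs in minutes: 20–240 s sessions, 10–30 laps, 500 null/150
power datasets for permutation-test calibration at a 201-point time
resolution (the envelope bandwidth is ~1 Hz, so 50–100 Hz resolution loses
nothing), 10–20 seeded sessions for group-level recovery checks. Group-level
quantities (zero-dip perturbation bias, ERP template recovery) are asserted
on means over seeded sessions, mirroring averaging over participants.

## Known limitations

* The ICA stage concentrates most but not all ASSR line power in a few
  components; small leakage peaks above the 0.10 log10 selection threshold
  occur in other components, so multiple accepted ASSR components per
  session are normal (as they are in practice).
* `rm_anova()` requires complete balanced designs; there is no missing-cell
  handling.
* The cluster permutation test assumes exchangeable paired differences
  (symmetric null); it pairs trials by index within a session.
* Narrowband envelope estimates carry ~1 Hz-bandwidth noise; single-session
  perturbation responses have ~0.4 dB standard error at 25 trials, which is
  why group-level means are the reported quantity.
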