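---
title: "Models and methods behind arcpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arcpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcpulse)
```

## The signal and the analysis problem

Arcuate kisspeptin (KNDy) neurons discharge in near-simultaneous
population bursts — synchronous episodes, SEs — that drive GnRH/LH
pulses. Recorded by fiber photometry with a calcium indicator, one SE is a
sharp fluorescence transient: a fast rise over tens of seconds and a slower
exponential-like decay. `arcpulse` quantifies these transients across the
estrous cycle and across reproductive aging: how often they occur in 6 h
light and dark sessions, how tall they are, and how their waveform is
shaped, then aggregates those measurements into cohort-level comparisons.

Because chronic multi-month recordings cannot be regenerated at desk scale,
the package ships a synthetic-data generator with known ground truth. Every
downstream stage is exercised against that generator, so the test suite
measures the pipeline's recovery of known quantities rather than merely its
ability to run.

## Normalization: two baselines, one formula

The fluorescence trace `F_t` is normalized as `dF/F = (F_t - F_0) / F_0`
twice, with different baselines:

* **Session-wide**: `F_0` is the mean over the whole 6 h session
  (`global_dff()`). This removes the animal- and session-specific optical
  gain and centers the trace at zero.
* **Peri-event**: for each pulse, the raw trace on −240..+120 s around the
  peak (peak at 0 s) is re-normalized against the mean of the −240..−120 s
  pre-peak segment (`peri_event_window()`). This local baseline removes
  slow drift before heights and widths are measured.

The local re-baseline is computed algebraically from the global dF/F trace
as `(1 + v) / (1 + v_baseline) − 1`, which is identical to recomputing from
raw fluorescence. Whether the local baseline should be formed on raw
fluorescence or on the already-normalized trace is ambiguous in principle;
the two are algebraically interchangeable under this formula, and the
raw-fluorescence reading is adopted. Events whose window would cross a
session boundary are excluded from waveform and height statistics but still
counted in frequency statistics, so counting never depends on window
geometry. Averaged waveforms are block-mean downsampled to 10 Hz
(`downsample_window()`).

## Calibrated pulse detection

Absolute dF/F heights vary several-fold between animals (virus expression,
fiber placement), so detection is calibrated per animal:

1. **Stereotyped height** (`calibrate_height()`): candidate local maxima
   above half the smoothed session maximum are ranked by topographic
   prominence; those whose full width at half maximum exceeds 10 s qualify,
   and the mean re-baselined height of the top 5 is the stereotyped height
   `H`. The prominence ranking is the package's deterministic proxy for the
   manual practice of picking "obvious" stereotyped peaks; the 10 s FWHM
   gate excludes noise spikes and movement artifacts.
2. **Detection** (`detect_pulses()`): local maxima with re-baselined height
   ≥ 0.4 × `H` are events, subject to a 60 s minimum separation.

Two numerical guards make the threshold rule operational on noisy traces,
and both are exposed as parameters:

* **Pre-detection smoothing** (`smooth_sec`, default 5 s): white sensor
  noise splits every summit into many micro-maxima. A moving average far
  below the pulse time scale (the kernel FWHM is ≈ 90 s) removes them while
  biasing pulse heights by well under 0.1%.
* **Prominence gate** (`prominence_frac`, default 0.5 × the height
  threshold): the decay tail of a large pulse can stay above the absolute
  threshold beyond the 60 s separation window, so a residual noise uptick
  there would register as a second event. Requiring topographic prominence
  comparable to the threshold rejects these; a genuine pulse rising from
  baseline has prominence close to its full height. The per-sample odds of
  such a tail uptick are independent of sampling rate (the noise gain and
  the slope both scale with the rate), so a separation rule alone cannot
  suppress them.

With both guards at their defaults, detection on default-noise synthetic
recordings recovers ground truth exactly (sensitivity 1, FDR 0 across
hundreds of events); the oracle tests pin this. Detection is monotone in
the threshold by construction: both gates tighten as the threshold rises,
and the time-ordered greedy separation pass realizes the maximum separated
subset of the accepted candidates. On noiseless fixtures the tests disable
smoothing (`smooth_sec = 0`) when they assert sample-exact peak
localization and 1e-6-level waveform recovery, since the moving average
shifts the asymmetric kernel's argmax by ≈ 0.07 s — the smoothing is a
noise guard, not part of the waveform model.

## Waveform metrics

`quarter_max_widths()` measures, on the re-baselined window, the time from
the first quarter-maximum crossing left of the peak to the peak (LWQM),
peak to first crossing on the right (RWQM), and their sum (FWQM).
Crossings are linearly interpolated between samples and the scan moves
outward from the peak, taking the first crossing on each side (robust to
secondary bumps). Widths are amplitude-invariant and satisfy
`fwqm = lwqm + rwqm` exactly. `pointwise_compare()` applies an
uncorrected Welch t-test at every grid point at α = 0.05, matching the
point-wise treatment of averaged waveforms; grid points where both groups
have zero variance return p = 1 when the means are equal and p = 0
otherwise, so degenerate fixtures behave deterministically.

## Estrous staging, cycles, and alignment

`stage_smear()` renders the classical cytology prose as a deterministic
rule table over four features (leukocytes, cornified and nucleated
epithelial cells, smear amount); combinations outside the table return
`unknown` rather than failing. A cycle (`count_cycles()`) runs from one
proestrus to the next, lasts ≥ 4 days, and contains ≥ 1 estrus day and
≥ 1 metestrus-or-diestrus day; consecutive proestrus days collapse to one
proestrus event, unknown days break cycles (conservative counting), and
25-day windows are consecutive non-overlapping blocks. `classify_phase()`
is a step function: ≥ 3 cycles/25 d regular, 1–2 irregular, 0 acyclic.

Recordings from different animals are aligned on physiology rather than
calendar: the dark/light count ratio collapses below 0.5 at the proestrus
that follows diestrus (progesterone suppression), and
`align_to_proestrus()` sets that day to Day 0 (earliest qualifying day on
ties). Animals without a qualifying day — the typical outcome in aging
animals, where the suppression disappears — raise an alignment failure and
are excluded from aligned analyses while remaining in frequency analyses.

## Cohort statistics

Heights are normalized per animal to the proestrus-light group mean
(`normalized_heights()`; anchor mean exactly 1 by construction), aging
intensity is summarized as per-animal phase means over the regular-cyclic
mean (`aging_fold_change()`), dispersion as sd/mean (`height_cv()`), and
interval distributions are compared with the two-sample Kolmogorov–Smirnov
test on empirical CDFs (`interval_cdf_compare()`). `test_battery()`
dispatches each figure-style design to the standard routine (one-way and
repeated-measures ANOVA with Tukey contrasts, Kruskal–Wallis with
Mann–Whitney post hoc, two-way interaction ANOVA, paired and unpaired t,
KS), executed through `stats`, `nlme` and `multcomp`; the package's own
contribution there is the dispatch, the uniform report, and the
compact-letter display, which is assigned by maximal cliques of the
pairwise non-significance graph in group order.

## qPCR quantification

`relative_expression()` implements 2^−ΔΔCt with the two-reference chain
used for arcuate tissue: target Ct minus `Gapdh` Ct on the cycle scale,
division by the `Npy`-vs-`Gapdh` expression on the expression scale (the
regional-marker normalization; the expression-scale reading is the one
under which the 2^−ΔΔCt arithmetic stays coherent), then division by the
reference-phase mean, which is therefore exactly 1. Replicate wells are
averaged on the Ct scale first. The chain is invariant to per-sample plate
offsets, and a +1 cycle on the target exactly halves its output.

## The synthetic generator

`simulate_session()` draws SE peak times from a gamma renewal process
(CV 0.3) whose mean interval depends on (stage, period); each event adds a
difference-of-exponentials kernel (rise 20 s, decay 60 s, unit peak,
FWHM ≈ 90 s) scaled by the stage/period amplitude multiplier and the aging
intensity multiplier, on a baseline with a 2%-amplitude slow sinusoidal
drift and 1% white noise. Defaults (see `generator_config()`):

* mean inter-pulse intervals (min), light/dark: proestrus 60/360, estrus
  90/60, metestrus 60/40, diestrus 60/40 — proestrus-dark is the rarest
  cell and metestrus/diestrus-dark the most frequent, and the proestrus
  dark/light count ratio falls well below 0.5;
* amplitude multipliers: proestrus 1.0 (anchor), estrus 1.2, metestrus
  1.5 light / 1.4 dark, diestrus 1.2 — the light period two days after
  proestrus carries the ≈ 1.5-fold maximum;
* aging intensity: reproductive and regular-cyclic 1.0, irregular 0.8,
  acyclic 0.5, with pulse rates unchanged across phases (intensity
  declines, frequency does not).

None of these absolute rates or amplitudes is printed anywhere as a
number; they are the package's one-time choice of realistic values
constrained by the published qualitative orderings and the two printed
ratios (the 0.5 suppression bound and the 1.5-fold amplitude maximum).
Events are kept one kernel span (≈ 330 s; implemented as peak time + five
decay constants) away from session edges, which also guarantees each
generated event a full peri-event window. Ground-truth peak times and
amplitudes ride along with every session, so detection can be scored
exactly.

`simulate_timeline()` emits daily true stages plus cytology features drawn
consistently with the staging table: regular phases cycle P→E→M→D in 4–5
days, irregular phases extend the diestrus run to 5–9 days (1–2 complete
cycles per 25 days), acyclic phases never reach proestrus. A 2% per-day
feature-corruption rate (`misread_prob`) emulates smear-reading error;
staging then recovers the true stage on ≈ 98% of days, and occasionally —
as with real smears — a corrupted pre-proestrus day costs a recording its
alignment anchor. `simulate_ct_table()` produces Ct tables with per-sample
plate offsets and known fold changes for the qPCR round trip.

What the generator does **not** model: photobleaching, movement artifacts,
isosbestic correction, any biophysical synchronization mechanism, or
LH secretion. Passing tests therefore demonstrate that the analysis
recovers the statistical structure it assumes — renewal-timed stereotyped
transients on a drifting noisy baseline — not that it is robust to every
pathology of real photometry.

## Problem sizes and numerical choices

The simulation studies in the tests and the acceptance script use the
study's native geometry — 6 h sessions at 120 Hz, 7-day recordings, 20
seeded replicates for the regular-cycle study and 10 paired replicates for
the aging study — which keeps each study within a few minutes on one CPU.
Unit tests exercise the same code paths at 10–20 Hz, where behaviour is
rate-independent. All randomness flows through explicit integer seeds
(child seeds are derived arithmetically and stay below 2^31), simulation
functions restore the caller's RNG state, and identical seeds give
bit-identical outputs. Tie-breaks are deterministic throughout: plateau
maxima report their earliest sample, equal-height candidates in
non-maximum suppression keep the earliest, and alignment picks the
earliest qualifying proestrus day.

## Known limitations

* The staging table resolves only the feature combinations the cytology
  prose describes; rarer intermediate smears return `unknown`.
* Overlapping pulses closer than the 60 s separation are counted once; no
  deconvolution is attempted.
* The dark/light ratio is undefined for a zero light count; such days
  cannot anchor alignment.
* `test_battery()` implements the designs used in this analysis, not a
  general modelling interface.
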