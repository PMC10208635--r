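# arcpulse

Analysis of pulsatile synchronous calcium episodes (SEs) of arcuate
kisspeptin neurons recorded by fiber photometry, across the estrous cycle
and reproductive aging — for neuroendocrinologists quantifying GnRH
pulse-generator activity from chronic 6 h light/dark recordings.

Arcuate KNDy neurons fire in population-wide bursts whose photometric
signature is a stereotyped ΔF/F transient. `arcpulse` implements the full
quantification chain around that signal:

* **ΔF/F normalization** — `(F_t − F_0)/F_0` with a session-wide `F_0`
  (6 h mean) and, per event, a local `F_0` over −240..−120 s before the
  peak on a fixed −240..+120 s window (`global_dff()`,
  `peri_event_window()`, 10 Hz `downsample_window()`).
* **Calibrated detection** — a per-animal stereotyped height `H` from the
  most prominent peaks with full width at half maximum > 10 s; events are
  local maxima with re-baselined height ≥ 0.4 `H` and ≥ 60 s separation
  (`calibrate_height()`, `detect_pulses()`).
* **Waveform metrics** — left/right/full widths at quarter maximum with
  linear interpolation, averaged waveforms, and uncorrected point-wise
  t-test comparisons (`quarter_max_widths()`, `averaged_waveform()`,
  `pointwise_compare()`).
* **Estrous staging and alignment** — cytology-rule staging, cycle
  counting (≥ 4 days, P→…→P with ≥ 1 E and ≥ 1 M/D day), phase
  classification (≥ 3 cycles/25 d regular, 1–2 irregular, 0 acyclic), and
  alignment of recordings at the post-diestrus proestrus whose dark/light
  SE-count ratio drops below 0.5 (`stage_smear()`, `count_cycles()`,
  `classify_phase()`, `darklight_ratio()`, `align_to_proestrus()`).
* **Cohort statistics** — per-animal height normalization to the
  proestrus-light anchor, interval CDFs with Kolmogorov–Smirnov
  comparison, height CV, aging fold changes, and a dispatcher for the
  standard test battery (`normalized_heights()`, `interval_cdf_compare()`,
  `height_cv()`, `aging_fold_change()`, `test_battery()`).
* **qPCR** — 2^−ΔΔCt with sequential Gapdh→Npy normalization and a
  reference-phase mean of exactly 1 (`relative_expression()`).
* **Synthetic data** — a generator with ground truth that emulates the
  recordings' statistical structure: gamma-renewal pulse trains,
  stage/period-dependent rates and amplitudes, aging intensity scaling,
  drift and sensor noise, cytology day-sequences, and Ct tables
  (`generator_config()`, `simulate_session()`, `simulate_timeline()`,
  `simulate_ct_table()`).

## Worked example

Simulate a 7-day regular-cycling recording (one light and one dark 6 h
session per day), run the whole analysis, and read off the two headline
quantities — the proestrus dark/light suppression and the amplitude
modulation across the cycle:

```r
library(arcpulse)

cfg <- generator_config(sampling_rate = 20)   # reduced rate for the example
rec <- simulate_recording(cfg, phase = "reproductive", n_days = 7, seed = 11)
an  <- analyze_recording(rec)

an$calibration
#> <calibration_result> animal A1: stereotyped height 1.48 dF/F from 5 peaks (FWHM > 10 s)

print(an$daily, digits = 2)
#>   day     stage light_count dark_count ratio
#> 1   1 proestrus           4          1  0.25
#> 2   2    estrus           4          6  1.50
#> 3   3 metestrus           6          8  1.33
#> 4   4  diestrus           6          7  1.17
#> 5   5 proestrus           6          1  0.17
#> 6   6 metestrus           4          6  1.50
#> 7   7 metestrus           6          8  1.33

an$alignment$day0      # post-diestrus proestrus with ratio < 0.5 -> Day 0
#> [1] 5

ev <- an$events
nh <- normalized_heights(ev, ev$day_offset == 0 & ev$period == "light",
                         group_cols = c("day_offset", "period"))
print(subset(nh$group_means, period == "light"), digits = 3)
#>    day_offset period mean_norm_height n_animals
#> 2          -1  light            1.198         1
#> 4          -2  light            1.495         1
#> 6          -3  light            1.199         1
#> 8          -4  light            0.995         1
#> 10          0  light            1.000         1
#> 12          1  light            1.204         1
#> 14          2  light            1.499         1
```

Reading the output: SE counts collapse in the dark period of both
proestrus days (ratios 0.25 and 0.17, below the 0.5 suppression bound that
marks the pre-ovulatory progesterone surge), the recording aligns at day 5,
and the normalized peak height peaks at ≈ 1.5 in the light period two days
after proestrus (the metestrus amplitude maximum), with the proestrus-light
anchor pinned at exactly 1. `run_pipeline()` wraps the same chain for a
cohort and writes `events.csv`, `daily_counts.csv` and a provenance record.

The methods vignette (`vignettes/arcpulse-methods.Rmd`) documents the
models, parameter choices, and the generator's scope.

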