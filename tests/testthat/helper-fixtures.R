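# Fixture builders shared across the suite. All fixtures are generated in
# code; unit tests run at reduced sampling rates (10-20 Hz) to stay fast,
# which does not change any algorithmic behaviour.

test_config <- function(...) {
  generator_config(sampling_rate = 20, ...)
}

# A photometry session whose raw trace is baseline * (1 + sum of pulses).
# `shape` selects the canonical difference-of-exponentials kernel or a
# triangle of given FWHM; `times` are pulse PEAK times in seconds.
make_session <- function(times, heights, rate = 10, duration = NULL,
                         baseline = 100, shape = "kernel", fwhm = 20,
                         stage = "proestrus", period = "light") {
  if (is.null(duration)) duration <- max(times) + 400
  n <- as.integer(round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  rel <- rep(1, n)
  for (i in seq_along(times)) {
    rel <- rel + heights[i] * pulse_shape(t, times[i], shape, fwhm)
  }
  structure(list(
    samples = baseline * rel, sampling_rate = rate,
    animal_id = "fix", day_index = 1L, period = period, stage = stage,
    phase = "reproductive", seed = 0L,
    truth = list(times = times, amplitudes = heights)
  ), class = "photometry_session")
}

pulse_shape <- function(t, centre, shape, fwhm) {
  if (shape == "kernel") {
    tp <- se_kernel_peak_time(20, 60)
    se_kernel(t - (centre - tp), 20, 60)
  } else {
    # triangle with apex at `centre`; half max at fwhm/2 each side
    pmax(0, 1 - abs(t - centre) / fwhm)
  }
}

# A bare dff_trace with baseline exactly 0 (no global-mean shift), for
# closed-form detection fixtures.
make_dff <- function(values, rate = 10, animal_id = "fix") {
  structure(list(values = values, sampling_rate = rate,
                 baseline_value = 1, animal_id = animal_id,
                 day_index = 1L, period = "light", stage = "proestrus",
                 phase = "reproductive", truth = NULL),
            class = "dff_trace")
}

# A peri_event_window on the standard -240..+120 s grid.
make_window <- function(values, rate = 10) {
  n <- length(values)
  structure(list(time = seq(-240, by = 1 / rate, length.out = n),
                 values = values, sampling_rate = rate,
                 local_baseline = 0, peak_time = NA_real_,
                 downsampled = FALSE),
            class = "peri_event_window")
}

# Windows of pure Gaussian noise for null-calibration studies.
noise_windows <- function(n_windows, n_points, rate = 10, sd = 1) {
  lapply(seq_len(n_windows), function(i) {
    make_window(stats::rnorm(n_points, 0, sd), rate = rate)
  })
}
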