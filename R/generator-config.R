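#' Configuration of the synthetic photometry generator
#'
#' Bundles every generative parameter of the synthetic recordings: stage- and
#' period-resolved pulse rates and amplitudes, the pulse kernel shape, the
#' renewal-process jitter, baseline/drift/noise levels, the aging intensity
#' scaling, and the session geometry. The defaults encode the qualitative
#' structure of regular-cycling recordings: synchronous episodes (SEs) are
#' rarest in the proestrus dark period, most frequent in the metestrus and
#' diestrus dark periods, and their amplitude peaks in the light period two
#' days after proestrus at roughly 1.5 times the proestrus-light amplitude,
#' which serves as the normalization anchor (multiplier exactly 1).
#'
#' @param stage_rate_table numeric matrix of mean inter-pulse intervals in
#'   minutes, rows = estrus stages (`proestrus`, `estrus`, `metestrus`,
#'   `diestrus`), columns = `light`, `dark`.
#' @param stage_amplitude_table numeric matrix of pulse-amplitude multipliers
#'   on the same layout; the `proestrus`/`light` cell must equal 1 (anchor).
#' @param pulse_height peak delta-F/F of a unit-multiplier pulse.
#' @param kernel_rise_tau,kernel_decay_tau rise and decay time constants of
#'   the difference-of-exponentials pulse kernel, seconds; rise must be
#'   shorter than decay.
#' @param interval_jitter_cv coefficient of variation of the gamma-distributed
#'   inter-pulse intervals (dimensionless).
#' @param baseline_level baseline fluorescence, arbitrary units.
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift,
#'   as a fraction of `baseline_level`.
#' @param noise_sd standard deviation of the additive white sensor noise,
#'   as a fraction of `baseline_level`.
#' @param aging_intensity_scale named numeric vector of amplitude multipliers
#'   per reproductive phase (`reproductive`, `regular`, `irregular`,
#'   `acyclic`); pulse rates are not scaled by phase.
#' @param session_duration session length in seconds (default 6 h).
#' @param sampling_rate sampling rate in Hz (default 120, the disk rate after
#'   decimation from the acquisition rate).
#' @param seed default integer seed recorded in the configuration.
#'
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config()
#' cfg$stage_rate_table["proestrus", "dark"]   # rarest cell, 360 min
#' @export
generator_config <- function(stage_rate_table = default_rate_table(),
                             stage_amplitude_table = default_amplitude_table(),
                             pulse_height = 1.0,
                             kernel_rise_tau = 20,
                             kernel_decay_tau = 60,
                             interval_jitter_cv = 0.3,
                             baseline_level = 100,
                             drift_amplitude = 0.02,
                             noise_sd = 0.01,
                             aging_intensity_scale = c(reproductive = 1.0,
                                                       regular = 1.0,
                                                       irregular = 0.8,
                                                       acyclic = 0.5),
                             session_duration = 21600,
                             sampling_rate = 120,
                             seed = 1L) {
  cfg <- list(
    stage_rate_table = as.matrix(stage_rate_table),
    stage_amplitude_table = as.matrix(stage_amplitude_table),
    pulse_height = pulse_height,
    kernel_rise_tau = kernel_rise_tau,
    kernel_decay_tau = kernel_decay_tau,
    interval_jitter_cv = interval_jitter_cv,
    baseline_level = baseline_level,
    drift_amplitude = drift_amplitude,
    noise_sd = noise_sd,
    aging_intensity_scale = aging_intensity_scale,
    session_duration = session_duration,
    sampling_rate = sampling_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @export
default_rate_table <- function() {
  m <- matrix(c(60, 360,
                90,  60,
                60,  40,
                60,  40),
              nrow = 4, byrow = TRUE,
              dimnames = list(ESTRUS_STAGES, c("light", "dark")))
  m
}

#' @rdname generator_config
#' @export
default_amplitude_table <- function() {
  m <- matrix(c(1.0, 1.0,
                1.2, 1.2,
                1.5, 1.4,
                1.2, 1.2),
              nrow = 4, byrow = TRUE,
              dimnames = list(ESTRUS_STAGES, c("light", "dark")))
  m
}

validate_generator_config <- function(cfg) {
  pos <- c("pulse_height", "kernel_rise_tau", "kernel_decay_tau",
           "interval_jitter_cv", "baseline_level", "session_duration",
           "sampling_rate")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop_arcpulse(sprintf("generator config field '%s' must be a positive scalar", f),
                    "arcpulse_config_error")
    }
  }
  for (f in c("drift_amplitude", "noise_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      stop_arcpulse(sprintf("generator config field '%s' must be non-negative", f),
                    "arcpulse_config_error")
    }
  }
  for (tab in c("stage_rate_table", "stage_amplitude_table")) {
    m <- cfg[[tab]]
    if (!all(ESTRUS_STAGES %in% rownames(m)) ||
        !all(c("light", "dark") %in% colnames(m))) {
      stop_arcpulse(sprintf("%s must have rows %s and columns light/dark",
                            tab, paste(ESTRUS_STAGES, collapse = ", ")),
                    "arcpulse_config_error")
    }
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop_arcpulse(sprintf("%s entries must be finite and strictly positive", tab),
                    "arcpulse_config_error")
    }
  }
  if (abs(cfg$stage_amplitude_table["proestrus", "light"] - 1) > 1e-12) {
    stop_arcpulse("stage_amplitude_table proestrus/light must equal 1 (normalization anchor)",
                  "arcpulse_config_error")
  }
  if (cfg$kernel_rise_tau >= cfg$kernel_decay_tau) {
    stop_arcpulse("kernel_rise_tau must be smaller than kernel_decay_tau",
                  "arcpulse_config_error")
  }
  if (!all(AGING_PHASES %in% names(cfg$aging_intensity_scale)) ||
      any(cfg$aging_intensity_scale <= 0)) {
    stop_arcpulse("aging_intensity_scale must name all phases with positive multipliers",
                  "arcpulse_config_error")
  }
  n <- cfg$session_duration * cfg$sampling_rate
  if (abs(n - round(n)) > 1e-9) {
    stop_arcpulse("session_duration x sampling_rate must be an integer sample count",
                  "arcpulse_config_error")
  }
  invisible(cfg)
}
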