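#' Difference-of-exponentials pulse kernel
#'
#' Canonical shape of one synchronous episode: a fast-rise, slow-decay
#' transient `exp(-t/decay) - exp(-t/rise)` for `t >= 0`, scaled so its peak
#' value is exactly 1. The analytic peak time is
#' `rise * decay / (decay - rise) * log(decay / rise)` seconds after onset.
#'
#' @param t time in seconds since kernel onset (vectorized); values < 0 give 0.
#' @param rise_tau,decay_tau time constants in seconds, `rise_tau < decay_tau`.
#' @return kernel values, unit peak.
#' @export
se_kernel <- function(t, rise_tau = 20, decay_tau = 60) {
  if (rise_tau >= decay_tau) {
    stop_arcpulse("rise_tau must be smaller than decay_tau", "arcpulse_config_error")
  }
  v <- ifelse(t >= 0, exp(-t / decay_tau) - exp(-t / rise_tau), 0)
  v / se_kernel_peak_value(rise_tau, decay_tau)
}

#' @rdname se_kernel
#' @export
se_kernel_peak_time <- function(rise_tau = 20, decay_tau = 60) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

se_kernel_peak_value <- function(rise_tau, decay_tau) {
  tp <- se_kernel_peak_time(rise_tau, decay_tau)
  exp(-tp / decay_tau) - exp(-tp / rise_tau)
}

# Time after which the kernel is negligible; also the exclusion margin that
# keeps generated events clear of the session edges.
kernel_span <- function(rise_tau, decay_tau) {
  se_kernel_peak_time(rise_tau, decay_tau) + 5 * decay_tau
}

#' Simulate one 6-hour photometry session
#'
#' Draws synchronous-episode times from a gamma renewal process whose mean
#' interval comes from the stage/period cell of `stage_rate_table`, places an
#' asymmetric pulse kernel at each event with amplitude
#' `pulse_height x stage_amplitude_table[stage, period] x
#' aging_intensity_scale[phase]`, and adds a slow sinusoidal baseline drift
#' plus white sensor noise. Event times are expressed as kernel PEAK times and
#' are kept at least one kernel span away from the session edges. Ground
#' truth (event peak times and amplitudes) is returned with the trace.
#'
#' @param config a [generator_config()].
#' @param stage estrus stage, one of `proestrus`, `estrus`, `metestrus`,
#'   `diestrus`.
#' @param period `light` or `dark`.
#' @param phase aging phase, one of `reproductive`, `regular`, `irregular`,
#'   `acyclic`.
#' @param seed integer seed; identical (config, arguments, seed) give
#'   bit-identical sessions.
#' @param animal_id,day_index metadata carried on the session.
#' @param event_times optional numeric vector of forced event peak times in
#'   seconds (bypasses the renewal draw; used for controlled fixtures).
#' @param event_amplitudes optional amplitudes (delta-F/F) matching
#'   `event_times`; defaults to the configured stage amplitude.
#'
#' @return A `photometry_session`: list with `samples` (raw fluorescence),
#'   `sampling_rate`, metadata fields, and `truth` (`times`, `amplitudes`).
#' @export
simulate_session <- function(config, stage, period, phase = "reproductive",
                             seed = config$seed, animal_id = "sim",
                             day_index = 1L,
                             event_times = NULL, event_amplitudes = NULL) {
  validate_generator_config(config)
  stage  <- match.arg(stage, ESTRUS_STAGES)
  period <- match.arg(period, c("light", "dark"))
  phase  <- match.arg(phase, AGING_PHASES)

  dur  <- config$session_duration
  rate <- config$sampling_rate
  span <- kernel_span(config$kernel_rise_tau, config$kernel_decay_tau)
  if (dur < span) {
    stop_arcpulse("session_duration too short to hold one pulse kernel",
                  "arcpulse_config_error")
  }
  n <- as.integer(round(dur * rate))
  amp0 <- config$pulse_height *
    config$stage_amplitude_table[stage, period] *
    config$aging_intensity_scale[[phase]]

  local_seed(seed, {
    if (is.null(event_times)) {
      times <- draw_renewal_times(
        mean_interval = config$stage_rate_table[stage, period] * 60,
        cv = config$interval_jitter_cv,
        duration = dur, margin = min(span, dur / 2)
      )
      amps <- rep(amp0, length(times))
    } else {
      times <- as.numeric(event_times)
      amps <- if (is.null(event_amplitudes)) rep(amp0, length(times)) else
        as.numeric(event_amplitudes)
      if (length(amps) != length(times)) {
        stop_arcpulse("event_amplitudes must match event_times in length",
                      "arcpulse_config_error")
      }
    }

    t_grid <- seq_len(n) / rate - 1 / rate
    rel <- rep(1, n)
    tp <- se_kernel_peak_time(config$kernel_rise_tau, config$kernel_decay_tau)
    for (i in seq_along(times)) {
      onset <- times[i] - tp
      i0 <- max(0L, floor(onset * rate)) + 1L
      i1 <- min(n, ceiling((onset + span) * rate) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      rel[idx] <- rel[idx] +
        amps[i] * se_kernel(t_grid[idx] - onset,
                            config$kernel_rise_tau, config$kernel_decay_tau)
    }

    drift <- if (config$drift_amplitude > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      config$drift_amplitude * sin(2 * pi * t_grid / dur + phi)
    } else 0
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(n, 0, config$noise_sd * config$baseline_level)
    } else 0
    samples <- config$baseline_level * (rel + drift) + noise

    structure(list(
      samples = samples,
      sampling_rate = rate,
      animal_id = animal_id,
      day_index = as.integer(day_index),
      period = period,
      stage = stage,
      phase = phase,
      seed = as.integer(seed),
      truth = list(times = times, amplitudes = amps)
    ), class = "photometry_session")
  })
}

# Gamma renewal event times on (margin, duration - margin).
draw_renewal_times <- function(mean_interval, cv, duration, margin) {
  shape <- 1 / cv^2
  scale <- mean_interval * cv^2
  n_draw <- max(10L, ceiling(duration / mean_interval * 3) + 10L)
  times <- cumsum(stats::rgamma(n_draw, shape = shape, scale = scale))
  while (length(times) && times[length(times)] < duration) {
    times <- c(times, times[length(times)] +
                 cumsum(stats::rgamma(n_draw, shape = shape, scale = scale)))
  }
  times[times >= margin & times <= duration - margin]
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %s day %d %s/%s (%s), %d samples @ %g Hz, %d true events\n",
              x$animal_id, x$day_index, x$stage, x$period, x$phase,
              length(x$samples), x$sampling_rate, length(x$truth$times)))
  invisible(x)
}
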