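#' Session-wide delta-F/F normalization
#'
#' Computes `(F_t - F_0) / F_0` where `F_0` is the mean fluorescence over the
#' whole session. The output has mean zero by construction; the raw trace is
#' recoverable as `(values + 1) * baseline_value`, which the peri-event
#' re-baselining exploits.
#'
#' @param session a `photometry_session`.
#' @return a `dff_trace`: list with `values`, `sampling_rate`,
#'   `baseline_value` (the global F_0) and the session metadata.
#' @export
global_dff <- function(session) {
  x <- session$samples
  if (!length(x)) stop_arcpulse("session has no samples", "arcpulse_format_error")
  f0 <- mean(x)
  if (!is.finite(f0) || f0 <= 0) {
    stop_arcpulse("degenerate baseline: mean fluorescence must be positive",
                  "arcpulse_baseline_error")
  }
  structure(list(
    values = (x - f0) / f0,
    sampling_rate = session$sampling_rate,
    baseline_value = f0,
    animal_id = session$animal_id,
    day_index = session$day_index,
    period = session$period,
    stage = session$stage,
    phase = session$phase,
    truth = session$truth
  ), class = "dff_trace")
}

# Window geometry shared by the peri-event operations (seconds).
PERI_PRE  <- 240
PERI_BASE <- 120   # local baseline ends this many seconds before the peak
PERI_POST <- 120

#' Extract a re-baselined peri-event window around one pulse
#'
#' Cuts the raw trace from -240 to +120 s around the peak (peak at 0 s) and
#' recomputes delta-F/F against a local F_0: the mean raw fluorescence over
#' -240..-120 s. The re-baselining is performed on the raw fluorescence
#' implied by the global delta-F/F trace (algebraically
#' `(1 + v) / (1 + v_baseline) - 1`), so no raw copy is needed.
#'
#' @param dff a `dff_trace` from [global_dff()].
#' @param peak_time peak time in seconds from session start.
#' @return a `peri_event_window` (list with `time` on -240..+120 s, `values`,
#'   `sampling_rate`, `local_baseline` as a fraction of global F_0,
#'   `peak_time`, `downsampled`), or `NULL` when the window would cross the
#'   session boundary (the event is then excluded from waveform statistics
#'   but still counted in frequency statistics).
#' @export
peri_event_window <- function(dff, peak_time) {
  r <- dff$sampling_rate
  n <- length(dff$values)
  ipk <- as.integer(round(peak_time * r)) + 1L
  lo <- ipk - as.integer(round(PERI_PRE * r))
  hi <- ipk + as.integer(round(PERI_POST * r))
  if (lo < 1L || hi > n) return(NULL)
  b0 <- lo
  b1 <- ipk - as.integer(round(PERI_BASE * r))
  vbar <- mean(dff$values[b0:b1])
  vals <- (1 + dff$values[lo:hi]) / (1 + vbar) - 1
  structure(list(
    time = (lo:hi - ipk) / r,
    values = vals,
    sampling_rate = r,
    local_baseline = vbar,
    peak_time = peak_time,
    downsampled = FALSE
  ), class = "peri_event_window")
}

# Re-baselined peak height with the baseline window clipped to the available
# trace, so boundary events still get a height for counting/thresholding.
# Falls back to the global delta-F/F value when no pre-peak baseline exists.
local_peak_height <- function(dff, ipk, values = dff$values) {
  r <- dff$sampling_rate
  b0 <- max(1L, ipk - as.integer(round(PERI_PRE * r)))
  b1 <- ipk - as.integer(round(PERI_BASE * r))
  if (b1 < b0) return(values[ipk])
  vbar <- mean(values[b0:b1])
  (1 + values[ipk]) / (1 + vbar) - 1
}

#' Downsample a peri-event window by block averaging
#'
#' Applies [decimate()] to the window values and time grid (each decimated
#' time is the mean time of its block). Used to downsize recalculated
#' delta-F/F windows to 10 Hz before averaging waveforms.
#'
#' @param window a `peri_event_window`.
#' @param out_rate target rate in Hz (default 10).
#' @return a `peri_event_window` at `out_rate` with `downsampled = TRUE`.
#' @export
downsample_window <- function(window, out_rate = 10) {
  structure(list(
    time = decimate(window$time, window$sampling_rate, out_rate),
    values = decimate(window$values, window$sampling_rate, out_rate),
    sampling_rate = out_rate,
    local_baseline = window$local_baseline,
    peak_time = window$peak_time,
    downsampled = TRUE
  ), class = "peri_event_window")
}
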