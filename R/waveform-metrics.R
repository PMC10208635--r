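#' Quarter-maximum widths of one pulse waveform
#'
#' Measures the left width at quarter maximum (LWQM: first crossing of
#' peak/4 left of the peak, to the peak), the right width (RWQM: peak to the
#' first crossing right of the peak), and their sum (FWQM) on a re-baselined
#' peri-event window. The scan moves outward from the peak and takes the
#' FIRST crossing on each side, with linear interpolation between samples;
#' widths are therefore invariant to amplitude scaling and satisfy
#' `fwqm = lwqm + rwqm` exactly.
#'
#' @param window a `peri_event_window` (any sampling rate). The peak is taken
#'   as the maximum of the window values.
#' @return list with `lwqm`, `rwqm`, `fwqm` in seconds (NA for a side with no
#'   crossing inside the window, in which case `fwqm` is also NA and the
#'   event should be excluded from width statistics), plus `peak_value`.
#' @export
quarter_max_widths <- function(window) {
  w <- window$values
  p <- which.max(w)
  pk <- w[p]
  if (!is.finite(pk) || pk <= 0) {
    stop_arcpulse("window peak value must be positive", "arcpulse_waveform_error")
  }
  q <- pk / 4
  dt <- 1 / window$sampling_rate
  left <- crossing_before(w, p, q)
  right <- crossing_after(w, p, q)
  lwqm <- if (is.na(left)) NA_real_ else (p - left) * dt
  rwqm <- if (is.na(right)) NA_real_ else (right - p) * dt
  list(lwqm = lwqm, rwqm = rwqm, fwqm = lwqm + rwqm, peak_value = pk)
}

#' Average peri-event waveforms on a common grid
#'
#' Point-wise mean and standard error across windows; all windows must share
#' the same time grid (same length and sampling rate).
#'
#' @param windows list of `peri_event_window` objects.
#' @return data.frame with `time`, `mean`, `sem` (sem is 0 for n = 1).
#' @export
averaged_waveform <- function(windows) {
  if (!length(windows)) {
    stop_arcpulse("at least one window is required", "arcpulse_grid_error")
  }
  lens <- vapply(windows, function(w) length(w$values), integer(1))
  rates <- vapply(windows, function(w) w$sampling_rate, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
    stop_arcpulse("windows are not on a common grid", "arcpulse_grid_error")
  }
  m <- do.call(rbind, lapply(windows, function(w) w$values))
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1L) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  data.frame(time = windows[[1]]$time, mean = mu, sem = sem)
}

#' Point-wise comparison of two groups of waveforms
#'
#' Welch two-sample t-test at every grid point, with no multiplicity
#' correction; the significance mask marks p < `alpha`. Grid points where
#' both groups have zero variance get p = 1 when the group means are equal
#' and p = 0 otherwise (deterministic handling of degenerate fixtures).
#'
#' @param group_a,group_b lists of `peri_event_window` objects (>= 2 each) on
#'   a common grid.
#' @param alpha significance level for the mask (default 0.05).
#' @return data.frame with `time`, `p`, `significant`.
#' @export
pointwise_compare <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_arcpulse("both groups need at least two windows", "arcpulse_grid_error")
  }
  all_w <- c(group_a, group_b)
  lens <- vapply(all_w, function(w) length(w$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_arcpulse("windows are not on a common grid", "arcpulse_grid_error")
  }
  ma <- do.call(rbind, lapply(group_a, function(w) w$values))
  mb <- do.call(rbind, lapply(group_b, function(w) w$values))
  p <- welch_columns(ma, mb)
  data.frame(time = group_a[[1]]$time, p = p, significant = p < alpha)
}

# Vectorized Welch t-test down the columns of two matrices (rows = subjects).
welch_columns <- function(ma, mb) {
  na <- nrow(ma); nb <- nrow(mb)
  mua <- colMeans(ma); mub <- colMeans(mb)
  va <- colSums(sweep(ma, 2, mua)^2) / (na - 1)
  vb <- colSums(sweep(mb, 2, mub)^2) / (nb - 1)
  sa <- va / na; sb <- vb / nb
  se2 <- sa + sb
  tstat <- (mua - mub) / sqrt(se2)
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(mua[degen] == mub[degen], 1, 0)
  p
}
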