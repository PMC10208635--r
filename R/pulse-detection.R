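# Local maxima of a trace, plateau-aware: a run of equal values that is
# strictly above both neighbouring runs is one maximum, reported at the
# EARLIEST sample of the plateau (deterministic tie-break). Endpoints are
# never maxima.
find_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  d <- diff(v)
  if (!anyNA(d) && !any(d == 0)) {      # fast path: no plateaus
    return(which(d[-(n - 1L)] > 0 & d[-1L] < 0) + 1L)
  }
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  mid <- 2:(k - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_peak]
}

# Centered moving average with shrinking windows at the edges; used to
# suppress sensor-noise-split maxima before peak finding. The pulse
# bandwidth (tens of seconds) is far below the analysis rate, so a few
# seconds of averaging leave pulse heights essentially untouched.
moving_average <- function(v, rate, smooth_sec) {
  half <- as.integer(floor(smooth_sec * rate / 2))
  if (half < 1L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  if (n <= 2L * half + 1L) {
    i <- seq_len(n)
    lo <- pmax(1L, i - half)
    hi <- pmin(n, i + half)
    return((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  }
  out <- numeric(n)
  mid <- (half + 1L):(n - half)
  out[mid] <- (cs[mid + half + 1L] - cs[mid - half]) / (2L * half + 1L)
  for (i in seq_len(half)) {
    out[i] <- cs[i + half + 1L] / (i + half)
    out[n - i + 1L] <- (cs[n + 1L] - cs[n - i - half + 1L]) / (i + half)
  }
  out
}

# Non-maximum suppression: among maxima closer than `win` samples, keep the
# highest (earliest on ties). O(m) after the sort.
thin_maxima <- function(idx, v, win) {
  m <- length(idx)
  if (m < 2L || win < 1L) return(idx)
  ord <- order(v[idx], -idx, decreasing = TRUE)
  state <- integer(m)              # 0 undecided, 1 kept, -1 suppressed
  for (j in ord) {
    if (state[j] != 0L) next
    state[j] <- 1L
    k <- j - 1L
    while (k >= 1L && idx[j] - idx[k] < win) {
      if (state[k] == 0L) state[k] <- -1L
      k <- k - 1L
    }
    k <- j + 1L
    while (k <= m && idx[k] - idx[j] < win) {
      if (state[k] == 0L) state[k] <- -1L
      k <- k + 1L
    }
  }
  idx[state == 1L]
}

# Topographic prominence of candidate maxima: drop from the peak to the
# deeper of the two key saddles, each found by walking towards the nearest
# strictly higher candidate (or the trace end). Removing candidates lower
# than a peak never changes that peak's prominence, so prominences are
# stable under the candidate pre-filters below.
candidate_prominence <- function(v, idx) {
  m <- length(idx)
  if (!m) return(numeric(0))
  h <- v[idx]
  bounds <- c(1L, idx, length(v))
  segs <- vapply(seq_len(m + 1L), function(j) min(v[bounds[j]:bounds[j + 1L]]),
                 numeric(1))
  vapply(seq_len(m), function(j) {
    lmin <- segs[j]; k <- j - 1L
    while (k >= 1L && h[k] <= h[j]) { lmin <- min(lmin, segs[k]); k <- k - 1L }
    rmin <- segs[j + 1L]; k <- j + 1L
    while (k <= m && h[k] <= h[j]) { rmin <- min(rmin, segs[k + 1L]); k <- k + 1L }
    h[j] - max(lmin, rmin)
  }, numeric(1))
}

# Full width at half maximum of a pulse, measured on the re-baselined
# peri-event values around the peak, with linear interpolation at the two
# half-maximum crossings. Returns NA when a side never crosses.
measure_fwhm <- function(dff, ipk, values = dff$values) {
  r <- dff$sampling_rate
  n <- length(values)
  lo <- max(1L, ipk - as.integer(round(PERI_PRE * r)))
  hi <- min(n, ipk + as.integer(round(PERI_POST * r)))
  b1 <- ipk - as.integer(round(PERI_BASE * r))
  vbar <- if (b1 >= lo) mean(values[lo:b1]) else 0
  w <- (1 + values[lo:hi]) / (1 + vbar) - 1
  p <- ipk - lo + 1L
  half <- w[p] / 2
  left <- crossing_before(w, p, half)
  right <- crossing_after(w, p, half)
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / r
}

# First downward crossing of `level` scanning left from index p (fractional
# index, linear interpolation); NA if none.
crossing_before <- function(w, p, level) {
  below <- which(w[seq_len(p)] < level)
  if (!length(below)) return(NA_real_)
  j <- max(below)               # w[j] < level <= w[j+1]
  j + (level - w[j]) / (w[j + 1L] - w[j])
}

# First downward crossing of `level` scanning right from index p.
crossing_after <- function(w, p, level) {
  tail_idx <- which(w[p:length(w)] < level)
  if (!length(tail_idx)) return(NA_real_)
  j <- p + min(tail_idx) - 1L   # w[j] < level <= w[j-1]
  (j - 1L) + (level - w[j - 1L]) / (w[j] - w[j - 1L])
}

#' Extract pulse candidates from one session
#'
#' Shared first stage of calibration and detection: smooths the global
#' delta-F/F trace with a `smooth_sec` moving average, finds its local
#' maxima, keeps those above `floor_frac` of the smoothed session maximum
#' (at most `max_candidates`, highest first), and annotates each candidate
#' with its re-baselined height and topographic prominence. The FWHM is
#' measured only for the calibration-relevant subset (the `4 * calib_k` most
#' prominent candidates above `calib_prefilter` of the session maximum);
#' other rows carry NA. The smoothed trace is discarded afterwards, which
#' keeps multi-session memory use flat.
#'
#' @param dff a `dff_trace`.
#' @param smooth_sec pre-detection moving-average width, seconds.
#' @param floor_frac candidate floor as a fraction of the smoothed session
#'   maximum; far below any meaningful detection threshold.
#' @param max_candidates cap on retained candidates per session.
#' @param calib_k,calib_prefilter calibration parameters determining the
#'   FWHM-annotated subset (see [calibrate_height()]).
#' @return data.frame with `idx`, `peak_time`, `smoothed_value`, `height`,
#'   `prominence`, `fwhm`, sorted by time; attribute `max_v` holds the
#'   smoothed session maximum.
#' @export
session_candidates <- function(dff, smooth_sec = 5, floor_frac = 0.25,
                               max_candidates = 500L, calib_k = 5L,
                               calib_prefilter = 0.5) {
  v <- moving_average(dff$values, dff$sampling_rate, smooth_sec)
  idx <- find_local_maxima(v)
  max_v <- if (length(v)) max(v) else -Inf
  empty <- data.frame(idx = integer(0), peak_time = numeric(0),
                      smoothed_value = numeric(0), height = numeric(0),
                      prominence = numeric(0), fwhm = numeric(0))
  if (!length(idx)) return(structure(empty, max_v = max_v))
  idx <- idx[v[idx] >= floor_frac * max_v]
  if (!length(idx)) return(structure(empty, max_v = max_v))
  # non-maximum suppression at a 2 s radius: a summit keeps one maximum,
  # its noise-split siblings (always lower) are discarded before the more
  # expensive prominence computation
  idx <- thin_maxima(idx, v, win = as.integer(round(2 * dff$sampling_rate)))
  # rank by prominence before capping: a summit carries one high-prominence
  # maximum, residual tail bumps carry almost none
  prom <- candidate_prominence(v, idx)
  if (length(idx) > max_candidates) {
    keep <- order(prom, decreasing = TRUE)[seq_len(max_candidates)]
    keep <- sort(keep)
    idx <- idx[keep]; prom <- prom[keep]
  }
  h <- vapply(idx, function(i) local_peak_height(dff, i, values = v), numeric(1))
  fwhm <- rep(NA_real_, length(idx))
  cal_set <- which(v[idx] >= calib_prefilter * max_v)
  if (length(cal_set)) {
    cal_set <- cal_set[order(prom[cal_set], decreasing = TRUE)]
    cal_set <- cal_set[seq_len(min(length(cal_set), 4L * calib_k))]
    fwhm[cal_set] <- vapply(idx[cal_set], function(i) {
      measure_fwhm(dff, i, values = v)
    }, numeric(1))
  }
  structure(data.frame(idx = idx,
                       peak_time = (idx - 1L) / dff$sampling_rate,
                       smoothed_value = v[idx],
                       height = h,
                       prominence = prom,
                       fwhm = fwhm),
            max_v = max_v)
}

#' Calibrate the stereotyped pulse height of one animal
#'
#' Because absolute signal intensity varies with surgery and expression, the
#' per-animal reference height is estimated from the most prominent peaks of
#' that animal's sessions: candidate local maxima above `prefilter_frac` of
#' the smoothed session maximum (a deterministic proxy for "visually
#' obvious" peaks) are ranked by topographic prominence, gated by a
#' full-width-at-half-maximum requirement (`fwhm_min`, default 10 s,
#' measured on re-baselined delta-F/F with linear interpolation), and the
#' mean re-baselined height of the top `k` qualifying peaks (default 5,
#' pooled across sessions) is the stereotyped height.
#'
#' @param dffs a `dff_trace` or list of `dff_trace` objects from one animal.
#' @param k number of calibration peaks (all qualifying peaks if fewer).
#' @param fwhm_min minimum full width at half maximum in seconds.
#' @param prefilter_frac candidate gate as a fraction of the smoothed
#'   session maximum.
#' @param smooth_sec pre-detection moving-average width in seconds
#'   (default 5; 0 disables).
#' @param candidates_list optional list of precomputed [session_candidates()]
#'   tables (one per session, same parameters), to share work with
#'   [detect_pulses()].
#' @return a `calibration_result`: list with `animal_id`,
#'   `stereotyped_height`, `peaks` (data.frame of contributing peaks),
#'   `n_contributing`.
#' @export
calibrate_height <- function(dffs, k = 5L, fwhm_min = 10, prefilter_frac = 0.5,
                             smooth_sec = 5, candidates_list = NULL) {
  if (inherits(dffs, "dff_trace")) dffs <- list(dffs)
  if (!length(dffs)) {
    stop_arcpulse("no sessions supplied for calibration", "arcpulse_calibration_error")
  }
  rows <- list()
  for (s in seq_along(dffs)) {
    cand <- candidates_list[[s]] %||%
      session_candidates(dffs[[s]], smooth_sec = smooth_sec,
                         calib_k = k, calib_prefilter = prefilter_frac)
    if (!nrow(cand)) next
    cand <- cand[cand$smoothed_value >= prefilter_frac * attr(cand, "max_v"), ,
                 drop = FALSE]
    if (!nrow(cand)) next
    cand$session <- s
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) {
    stop_arcpulse("calibration failure: no candidate peaks found",
                  "arcpulse_calibration_error")
  }
  cand <- do.call(rbind, rows)
  ok <- cand[!is.na(cand$fwhm) & cand$fwhm > fwhm_min & cand$height > 0, ]
  if (!nrow(ok)) {
    stop_arcpulse(sprintf(
      "calibration failure: no peak passes the FWHM > %g s gate", fwhm_min),
      "arcpulse_calibration_error")
  }
  ok <- ok[order(ok$prominence, decreasing = TRUE), ]
  use <- ok[seq_len(min(k, nrow(ok))), ]
  structure(list(
    animal_id = dffs[[1]]$animal_id,
    stereotyped_height = mean(use$height),
    peaks = use[, c("session", "peak_time", "height", "prominence", "fwhm")],
    n_contributing = nrow(use),
    k = k,
    fwhm_min = fwhm_min
  ), class = "calibration_result")
}

#' Detect synchronous episodes in a delta-F/F trace
#'
#' Keeps candidate local maxima whose re-baselined peak height is at least
#' `threshold_frac` (default 0.4) of the animal's calibrated stereotyped
#' height and whose topographic prominence is at least `prominence_frac` of
#' that threshold (rejecting residual noise upticks riding on the decay tail
#' of a real pulse, whose absolute height can clear the threshold while
#' their prominence is minuscule), then enforces a minimum peak separation
#' with a time-ordered greedy pass. Both gates tighten as the threshold
#' rises and the greedy pass realizes the maximum separated subset, so the
#' detected count is monotone non-increasing in the threshold.
#'
#' @param dff a `dff_trace`.
#' @param calibration a `calibration_result` for the animal.
#' @param threshold_frac detection threshold as a fraction of the
#'   stereotyped height.
#' @param min_separation minimum time between detected peaks, seconds.
#' @param smooth_sec pre-detection moving-average width in seconds (default
#'   5, as in [calibrate_height()]).
#' @param prominence_frac minimum prominence as a fraction of the height
#'   threshold (default 0.5).
#' @param candidates optional precomputed [session_candidates()] table for
#'   this session.
#' @return data.frame of events: `peak_time` (s), `height` (re-baselined
#'   delta-F/F), plus session metadata columns (`animal_id`, `day_index`,
#'   `period`, `stage`, `phase`); zero rows when nothing crosses threshold.
#' @export
detect_pulses <- function(dff, calibration, threshold_frac = 0.4,
                          min_separation = 60, smooth_sec = 5,
                          prominence_frac = 0.5, candidates = NULL) {
  thr <- threshold_frac * calibration$stereotyped_height
  cand <- candidates %||% session_candidates(dff, smooth_sec = smooth_sec)
  keep <- cand$height >= thr & cand$prominence >= prominence_frac * thr
  idx <- cand$idx[keep]
  h <- cand$height[keep]
  if (length(idx) > 1L) {
    sep <- min_separation * dff$sampling_rate
    acc <- logical(length(idx))
    last <- -Inf
    for (j in seq_along(idx)) {
      if (idx[j] - last >= sep) { acc[j] <- TRUE; last <- idx[j] }
    }
    idx <- idx[acc]; h <- h[acc]
  }
  data.frame(
    peak_time = (idx - 1L) / dff$sampling_rate,
    height = h,
    animal_id = rep(dff$animal_id %||% NA_character_, length(idx)),
    day_index = rep(dff$day_index %||% NA_integer_, length(idx)),
    period = rep(dff$period %||% NA_character_, length(idx)),
    stage = rep(dff$stage %||% NA_character_, length(idx)),
    phase = rep(dff$phase %||% NA_character_, length(idx)),
    stringsAsFactors = FALSE
  )
}

#' Within-session inter-peak intervals
#'
#' Successive peak-time differences in minutes, never formed across session
#' boundaries.
#'
#' @param events event data.frame(s) as returned by [detect_pulses()]; pass a
#'   list for multiple sessions, or a single data.frame with a `session`
#'   column (otherwise `animal_id` + `day_index` + `period` delimit
#'   sessions).
#' @return numeric vector of intervals in minutes (empty when every session
#'   has fewer than two events).
#' @export
interpeak_intervals <- function(events) {
  if (is.data.frame(events)) {
    key <- if ("session" %in% names(events)) {
      events$session
    } else {
      paste(events$animal_id, events$day_index, events$period)
    }
    events <- split(events, key)
  }
  out <- unlist(lapply(events, function(e) {
    if (nrow(e) < 2L) return(numeric(0))
    diff(sort(e$peak_time)) / 60
  }), use.names = FALSE)
  if (is.null(out)) numeric(0) else out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> animal %s: stereotyped height %.4g dF/F from %d peaks (FWHM > %g s)\n",
              x$animal_id, x$stereotyped_height, x$n_contributing, x$fwhm_min))
  invisible(x)
}
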