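#' Stage a vaginal smear from its cytology features
#'
#' Deterministic rendering of the classical smear-reading rules: proestrus is
#' dominated by nucleated epithelial cells (a few leukocytes are tolerated in
#' early proestrus); estrus by cornified epithelial cells without leukocytes
#' in a large smear; metestrus shows either cornified cells in abundant
#' leukocytes (early) or some nucleated cells in abundant leukocytes (late);
#' diestrus is the smallest smear, dominated by leukocytes with few
#' epithelial cells. Combinations outside the table return `"unknown"`,
#' never an error.
#'
#' @param leukocytes,cornified,nucleated abundance levels: `none`, `low`, or
#'   `high`.
#' @param smear smear amount: `small`, `medium`, or `large`.
#' @return stage label: `proestrus`, `estrus`, `metestrus`, `diestrus`, or
#'   `unknown`. Vectorized over rows when vectors are supplied.
#' @export
stage_smear <- function(leukocytes, cornified, nucleated, smear) {
  n <- length(leukocytes)
  out <- character(n)
  for (i in seq_len(n)) {
    lk <- leukocytes[i]; co <- cornified[i]; nu <- nucleated[i]; sm <- smear[i]
    out[i] <-
      if (nu == "high" && lk %in% c("none", "low")) "proestrus"
      else if (co == "high" && lk == "none") "estrus"
      else if (co == "high" && lk == "high") "metestrus"          # early M
      else if (nu == "low" && lk == "high" && sm == "large") "metestrus" # late M
      else if (lk == "high" && sm == "small" &&
               co %in% c("none", "low") && nu %in% c("none", "low")) "diestrus"
      else "unknown"
  }
  out
}

#' @rdname stage_smear
#' @param features data.frame with columns `leukocytes`, `cornified`,
#'   `nucleated`, `smear` (e.g. from [simulate_timeline()]).
#' @export
stage_smears <- function(features) {
  stage_smear(features$leukocytes, features$cornified,
              features$nucleated, features$smear)
}

# Cycle spans under the definition: a cycle runs from one proestrus to the
# next (consecutive proestrus days collapse to one proestrus event at the
# run start), lasts at least `min_days` days, contains at least one estrus
# day and at least one metestrus-or-diestrus day, and no unknown day.
cycle_spans <- function(stages, min_days = 4L) {
  p_days <- which(stages == "proestrus")
  if (length(p_days) < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- p_days[c(TRUE, diff(p_days) > 1L)]   # collapse proestrus runs
  out <- list()
  for (j in seq_len(length(starts) - 1L)) {
    a <- starts[j]; b <- starts[j + 1L]
    inner <- stages[a:b]
    if ((b - a) >= min_days &&
        any(inner == "estrus") &&
        any(inner %in% c("metestrus", "diestrus")) &&
        !any(inner == "unknown")) {
      out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Count estrus cycles in 25-day windows
#'
#' A cycle is the span between subsequent proestrus stages, lasting at least
#' four days and containing at least one estrus day and one metestrus-or-
#' diestrus day; unknown days break cycles. Cycles are counted when fully
#' contained in a window; windows are consecutive non-overlapping blocks of
#' `window` days, and partial cycles at block edges are not counted.
#'
#' @param stages character vector of daily stage labels.
#' @param window window length in days (default 25).
#' @param min_days minimum cycle duration in days (default 4).
#' @return list with `spans` (data.frame of start/end proestrus days over the
#'   whole sequence), `block_counts` (cycles fully inside each block), and
#'   `cycles_per_25_days` (the first block's count).
#' @export
count_cycles <- function(stages, window = 25L, min_days = 4L) {
  if (length(stages) < window) {
    stop_arcpulse(sprintf("need at least %d days of staging, got %d",
                          window, length(stages)), "arcpulse_data_error")
  }
  spans <- cycle_spans(stages, min_days = min_days)
  n_blocks <- length(stages) %/% window
  block_counts <- vapply(seq_len(n_blocks), function(b) {
    lo <- (b - 1L) * window + 1L
    hi <- b * window
    sum(spans$start >= lo & spans$end <= hi)
  }, integer(1))
  list(spans = spans, block_counts = block_counts,
       cycles_per_25_days = block_counts[[1]])
}

#' Classify the reproductive phase from the cycle count
#'
#' Step function with breakpoints at 1 and 3 cycles per 25 days: three or
#' more cycles is `regular`, one or two is `irregular`, zero is `acyclic`.
#'
#' @param cycles_per_25_days non-negative cycle count.
#' @return `"regular"`, `"irregular"`, or `"acyclic"` (vectorized).
#' @export
classify_phase <- function(cycles_per_25_days) {
  if (any(cycles_per_25_days < 0)) {
    stop_arcpulse("cycle count must be non-negative", "arcpulse_data_error")
  }
  ifelse(cycles_per_25_days >= 3, "regular",
         ifelse(cycles_per_25_days >= 1, "irregular", "acyclic"))
}

#' Dark/light pulse-count ratio
#'
#' Count of synchronous episodes in a 6 h dark period divided by the count in
#' the preceding 6 h light period. A zero light count makes the ratio
#' undefined (NA), and such days are excluded from proestrus alignment.
#'
#' @param dark_count,light_count non-negative event counts (vectorized).
#' @return numeric ratio(s), NA where the light count is zero.
#' @export
darklight_ratio <- function(dark_count, light_count) {
  if (any(dark_count < 0) || any(light_count < 0)) {
    stop_arcpulse("counts must be non-negative", "arcpulse_data_error")
  }
  ifelse(light_count == 0, NA_real_, dark_count / light_count)
}

#' Align a recording to proestrus via the dark/light suppression ratio
#'
#' Day 0 is the earliest cytology-proestrus day that immediately follows a
#' diestrus day and whose dark/light ratio is below `ratio_cut` (default
#' 0.5), the stereotyped progesterone-driven suppression. When several days
#' qualify the earliest is taken; when none qualifies an alignment-failure
#' error is raised (as happens in aging animals, where the suppression
#' disappears and those animals are excluded from aligned analyses).
#'
#' @param stages daily stage labels.
#' @param ratios daily dark/light ratios from [darklight_ratio()] (NA =
#'   undefined).
#' @param ratio_cut suppression threshold (default 0.5).
#' @return list with `day0` (the aligned proestrus day) and `offsets`
#'   (day numbering with proestrus = 0).
#' @export
align_to_proestrus <- function(stages, ratios, ratio_cut = 0.5) {
  if (length(stages) != length(ratios)) {
    stop_arcpulse("stages and ratios must have the same length", "arcpulse_data_error")
  }
  n <- length(stages)
  ok <- which(seq_len(n) > 1L &
              stages == "proestrus" &
              c("", stages[-n]) == "diestrus" &
              !is.na(ratios) & ratios < ratio_cut)
  if (!length(ok)) {
    stop_arcpulse("alignment failure: no post-diestrus proestrus day with suppressed dark/light ratio",
                  "arcpulse_alignment_error")
  }
  day0 <- ok[1]
  list(day0 = day0, offsets = seq_len(n) - day0)
}
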