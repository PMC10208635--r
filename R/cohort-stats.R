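#' Normalize pulse heights to an anchor group, per animal
#'
#' Every event height is divided by its animal's mean height in the anchor
#' group (classically the proestrus light period), so the anchor-group mean
#' is 1 by construction for each animal. Animals without anchor events are
#' excluded with a warning.
#'
#' @param events event data.frame with at least `animal_id` and `height`.
#' @param anchor_mask logical vector (one per event) marking the anchor
#'   group, e.g. `events$stage == "proestrus" & events$period == "light"`.
#' @param group_cols character vector of column names defining the reporting
#'   groups (e.g. `c("stage", "period")` or `c("day_offset", "period")`).
#' @return list with `events` (input rows of retained animals plus a
#'   `norm_height` column) and `group_means` (data.frame of per-group mean
#'   normalized height, averaged across per-animal means, with `n_animals`).
#' @export
normalized_heights <- function(events, anchor_mask, group_cols = c("stage", "period")) {
  stopifnot(length(anchor_mask) == nrow(events))
  anchors <- tapply(events$height[anchor_mask], events$animal_id[anchor_mask], mean)
  keep <- events$animal_id %in% names(anchors)
  dropped <- setdiff(unique(events$animal_id), names(anchors))
  if (length(dropped)) {
    warning(sprintf("animal(s) without anchor-group events excluded: %s",
                    paste(dropped, collapse = ", ")))
  }
  ev <- events[keep, , drop = FALSE]
  ev$norm_height <- ev$height / as.numeric(anchors[ev$animal_id])
  key <- interaction(ev[group_cols], drop = TRUE, sep = "|")
  akey <- interaction(ev$animal_id, key, drop = TRUE, sep = "||")
  per_animal <- tapply(ev$norm_height, akey, mean)
  parts <- do.call(rbind, strsplit(names(per_animal), "||", fixed = TRUE))
  gm <- tapply(as.numeric(per_animal), parts[, 2], mean)
  gn <- tapply(as.numeric(per_animal), parts[, 2], length)
  cols <- do.call(rbind, strsplit(names(gm), "|", fixed = TRUE))
  group_means <- data.frame(cols, mean_norm_height = as.numeric(gm),
                            n_animals = as.integer(gn),
                            stringsAsFactors = FALSE)
  names(group_means)[seq_along(group_cols)] <- group_cols
  rownames(group_means) <- NULL
  list(events = ev, group_means = group_means)
}

#' Compare two inter-pulse interval distributions
#'
#' Empirical CDFs plus the two-sample Kolmogorov-Smirnov test. With fewer
#' than two intervals in either group the comparison is marked not
#' computable.
#'
#' @param intervals_a,intervals_b numeric interval vectors (minutes).
#' @return list with `computable`, `statistic`, `p_value`, `ecdf_a`, `ecdf_b`.
#' @export
interval_cdf_compare <- function(intervals_a, intervals_b) {
  if (length(intervals_a) < 2L || length(intervals_b) < 2L) {
    return(list(computable = FALSE, statistic = NA_real_, p_value = NA_real_,
                ecdf_a = NULL, ecdf_b = NULL))
  }
  ks <- suppressWarnings(stats::ks.test(intervals_a, intervals_b))
  list(computable = TRUE,
       statistic = unname(ks$statistic),
       p_value = ks$p.value,
       ecdf_a = stats::ecdf(intervals_a),
       ecdf_b = stats::ecdf(intervals_b))
}

#' Coefficient of variation of pulse heights
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' scale-invariant by construction. Undefined (NA) for zero mean.
#'
#' @param heights numeric vector, length >= 2.
#' @return CV, dimensionless.
#' @export
height_cv <- function(heights) {
  if (length(heights) < 2L) {
    stop_arcpulse("need at least two heights for a CV", "arcpulse_data_error")
  }
  m <- mean(heights)
  if (m == 0) return(NA_real_)
  stats::sd(heights) / m
}

#' Per-animal fold change of pulse heights across aging phases
#'
#' Mean height in each phase divided by the same animal's mean height in the
#' reference phase (regular cyclic by convention). Animals without
#' reference-phase events are excluded with a warning.
#'
#' @param events event data.frame with `animal_id`, `phase`, `height`.
#' @param reference_phase the denominator phase (default `"regular"`).
#' @return data.frame with `animal_id`, `phase`, `fold_change`.
#' @export
aging_fold_change <- function(events, reference_phase = "regular") {
  ref <- events[events$phase == reference_phase, , drop = FALSE]
  ref_means <- tapply(ref$height, ref$animal_id, mean)
  keep <- events$animal_id %in% names(ref_means)
  dropped <- setdiff(unique(events$animal_id), names(ref_means))
  if (length(dropped)) {
    warning(sprintf("animal(s) without reference-phase events excluded: %s",
                    paste(dropped, collapse = ", ")))
  }
  ev <- events[keep, , drop = FALSE]
  key <- interaction(ev$animal_id, ev$phase, drop = TRUE, sep = "||")
  m <- tapply(ev$height, key, mean)
  parts <- do.call(rbind, strsplit(names(m), "||", fixed = TRUE))
  data.frame(animal_id = parts[, 1], phase = parts[, 2],
             fold_change = as.numeric(m) /
               as.numeric(ref_means[parts[, 1]]),
             stringsAsFactors = FALSE)
}
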