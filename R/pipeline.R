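#' Simulate a multi-day chronic recording of one animal
#'
#' Draws a daily estrus-stage timeline for the requested aging phase, then
#' simulates one light and one dark 6 h photometry session per day with the
#' stage- and phase-appropriate pulse statistics. Per-session seeds are
#' derived deterministically from `seed`.
#'
#' @param config a [generator_config()].
#' @param phase aging phase label.
#' @param n_days number of recording days (default 7, the chronic-imaging
#'   protocol).
#' @param seed integer seed for the whole recording.
#' @param animal_id identifier stamped on every session.
#' @return a `recording`: list with `timeline` (from [simulate_timeline()])
#'   and `sessions` (list of `photometry_session`, 2 per day, light first).
#' @export
simulate_recording <- function(config = generator_config(), phase = "reproductive",
                               n_days = 7L, seed = config$seed,
                               animal_id = "A1") {
  phase <- match.arg(phase, AGING_PHASES)
  timeline <- simulate_timeline(config, phase, n_days, seed = derive_seed(seed, 0L))
  sessions <- list()
  for (d in seq_len(n_days)) {
    for (p in c("light", "dark")) {
      i <- 2L * (d - 1L) + (p == "dark") + 1L
      sessions[[i]] <- simulate_session(
        config, stage = timeline$true_stage[d], period = p, phase = phase,
        seed = derive_seed(seed, i), animal_id = animal_id, day_index = d
      )
    }
  }
  structure(list(timeline = timeline, sessions = sessions,
                 phase = phase, animal_id = animal_id, seed = seed,
                 config = config),
            class = "recording")
}

#' Analyze one chronic recording end to end
#'
#' Runs the full analysis chain on a recording: cytology staging of every
#' day, global delta-F/F per session, per-animal height calibration pooled
#' over the recording's sessions, pulse detection at the 40 percent
#' threshold, per-day light/dark counts and the dark/light suppression
#' ratio, proestrus alignment, peri-event windows and quarter-maximum
#' widths, and inter-peak intervals.
#'
#' @param recording a `recording` from [simulate_recording()] (or any list
#'   with `timeline` and `sessions` of the same shape).
#' @param threshold_frac detection threshold fraction (default 0.4).
#' @param fwhm_min calibration FWHM gate in seconds (default 10).
#' @param min_separation minimum peak separation in seconds (default 60).
#' @param ratio_cut dark/light suppression threshold for alignment
#'   (default 0.5).
#' @param calibration_k number of calibration peaks (default 5).
#' @return an `analysis`: list with `staged` (timeline plus recovered
#'   `stage`), `calibration`, `events` (with re-baselined heights,
#'   quarter-max width columns, recovered stage and, when alignment
#'   succeeds, `day_offset`), `daily` (per-day counts and ratio),
#'   `alignment` (list or NULL on failure, with the failure reason in
#'   `alignment_error`), `intervals` (minutes).
#' @export
analyze_recording <- function(recording, threshold_frac = 0.4, fwhm_min = 10,
                              min_separation = 60, ratio_cut = 0.5,
                              calibration_k = 5L) {
  tl <- recording$timeline
  staged <- tl
  staged$stage <- stage_smears(tl)

  dffs <- lapply(recording$sessions, global_dff)
  cands <- lapply(dffs, session_candidates, calib_k = calibration_k)
  calibration <- calibrate_height(dffs, k = calibration_k, fwhm_min = fwhm_min,
                                  candidates_list = cands)

  ev_list <- lapply(seq_along(dffs), function(i) {
    detect_pulses(dffs[[i]], calibration, threshold_frac = threshold_frac,
                  min_separation = min_separation, candidates = cands[[i]])
  })
  events <- do.call(rbind, ev_list)
  # analysis uses the cytology-recovered stage, as the bench pipeline would
  events$stage <- staged$stage[events$day_index]

  days <- seq_len(nrow(tl))
  light_counts <- vapply(days, function(d) {
    sum(events$day_index == d & events$period == "light")
  }, integer(1))
  dark_counts <- vapply(days, function(d) {
    sum(events$day_index == d & events$period == "dark")
  }, integer(1))
  ratios <- darklight_ratio(dark_counts, light_counts)
  daily <- data.frame(day = days, stage = staged$stage,
                      light_count = light_counts, dark_count = dark_counts,
                      ratio = ratios)

  alignment <- NULL
  alignment_error <- NULL
  al <- tryCatch(align_to_proestrus(staged$stage, ratios, ratio_cut = ratio_cut),
                 arcpulse_alignment_error = function(e) e)
  if (inherits(al, "condition")) alignment_error <- conditionMessage(al)
  else alignment <- al
  if (!is.null(alignment)) {
    events$day_offset <- alignment$offsets[events$day_index]
  }

  events <- event_widths(dffs, events)
  intervals <- interpeak_intervals(events)

  structure(list(
    animal_id = recording$animal_id, phase = recording$phase,
    staged = staged, calibration = calibration, events = events,
    daily = daily, alignment = alignment, alignment_error = alignment_error,
    intervals = intervals
  ), class = "analysis")
}

# Quarter-max widths for every event whose peri-event window fits inside the
# session; boundary events get NA widths but stay in the event table.
event_widths <- function(dffs, events) {
  if (!nrow(events)) {
    return(cbind(events, lwqm = numeric(0), rwqm = numeric(0), fwqm = numeric(0)))
  }
  session_of <- paste(vapply(dffs, function(d) d$day_index, integer(1)),
                      vapply(dffs, function(d) d$period, character(1)))
  key <- paste(events$day_index, events$period)
  w <- t(vapply(seq_len(nrow(events)), function(i) {
    dff <- dffs[[match(key[i], session_of)]]
    win <- peri_event_window(dff, events$peak_time[i])
    if (is.null(win)) return(c(NA_real_, NA_real_, NA_real_))
    qm <- quarter_max_widths(win)
    c(qm$lwqm, qm$rwqm, qm$fwqm)
  }, numeric(3)))
  events$lwqm <- w[, 1]; events$rwqm <- w[, 2]; events$fwqm <- w[, 3]
  events
}

#' Run a whole simulated study and write its tables
#'
#' Orchestrates simulate - stage - calibrate - detect - align - summarize
#' for a cohort and writes delimited-text tables plus a provenance record to
#' `out_dir`. Scenarios: `"reproductive"` (n regular-cycling animals, 7-day
#' recordings, Fig-1-style outputs), `"aging-longitudinal"` (each animal
#' recorded once per aging phase, fold-change outputs).
#'
#' @param scenario `"reproductive"` or `"aging-longitudinal"`.
#' @param config a [generator_config()].
#' @param n_animals number of simulated animals.
#' @param n_days days per recording (default 7).
#' @param seed master seed; all per-animal seeds derive from it.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param ... thresholds forwarded to [analyze_recording()].
#' @return invisible list with `analyses` (per animal/phase), `events`
#'   (pooled table), `daily` (pooled per-day table), and for the aging
#'   scenario `fold_changes`.
#' @export
run_pipeline <- function(scenario = c("reproductive", "aging-longitudinal"),
                         config = generator_config(), n_animals = 4L,
                         n_days = 7L, seed = config$seed, out_dir = NULL, ...) {
  scenario <- match.arg(scenario)
  phases <- if (scenario == "reproductive") "reproductive" else
    c("regular", "irregular", "acyclic")
  analyses <- list()
  skip_log <- character(0)
  for (a in seq_len(n_animals)) {
    aid <- sprintf("A%02d", a)
    for (ph in phases) {
      rec_seed <- derive_seed(seed, a * 100L + match(ph, AGING_PHASES))
      rec <- simulate_recording(config, phase = ph, n_days = n_days,
                                seed = rec_seed, animal_id = aid)
      an <- tryCatch(analyze_recording(rec, ...),
                     arcpulse_calibration_error = function(e) e)
      if (inherits(an, "condition")) {
        skip_log <- c(skip_log, sprintf("%s/%s: %s", aid, ph, conditionMessage(an)))
        next
      }
      if (!is.null(an$alignment_error)) {
        skip_log <- c(skip_log,
                      sprintf("%s/%s: %s (kept for frequency analyses)",
                              aid, ph, an$alignment_error))
      }
      analyses[[paste(aid, ph, sep = "/")]] <- an
    }
  }
  if (!length(analyses)) {
    stop_arcpulse("every animal failed calibration", "arcpulse_pipeline_error")
  }
  events <- do.call(rbind, lapply(analyses, function(an) {
    ev <- an$events
    if (!"day_offset" %in% names(ev)) ev$day_offset <- NA_integer_
    ev
  }))
  rownames(events) <- NULL
  daily <- do.call(rbind, lapply(names(analyses), function(k) {
    cbind(id = k, analyses[[k]]$daily, stringsAsFactors = FALSE)
  }))
  out <- list(scenario = scenario, analyses = analyses, events = events,
              daily = daily, skip_log = skip_log, seed = seed)
  if (scenario == "aging-longitudinal") {
    out$fold_changes <- aging_fold_change(events, reference_phase = "regular")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(daily, file.path(out_dir, "daily_counts.csv"), row.names = FALSE)
    if (!is.null(out$fold_changes)) {
      utils::write.csv(out$fold_changes, file.path(out_dir, "fold_changes.csv"),
                       row.names = FALSE)
    }
    writeLines(c(
      sprintf("scenario: %s", scenario),
      sprintf("seed: %d", seed),
      sprintf("n_animals: %d", n_animals),
      sprintf("n_days: %d", n_days),
      sprintf("package_version: %s", as.character(utils::packageVersion("arcpulse"))),
      if (length(skip_log)) paste("skip:", skip_log) else "skip: none"
    ), file.path(out_dir, "provenance.txt"))
  }
  invisible(out)
}

#' Summary statistics of the regular-cycle study used for acceptance checks
#'
#' For each of `n_seeds` simulated 7-day regular-cycling recordings, runs the
#' full pipeline and extracts (a) the dark/light ratio at the first
#' cytology-proestrus day that follows a diestrus day, and (b) the mean
#' normalized pulse height (proestrus-light anchor) of the light period two
#' days after the aligned proestrus.
#'
#' @param config a [generator_config()].
#' @param n_seeds number of independent recordings.
#' @param base_seed master seed.
#' @param n_days days per recording (default 7).
#' @return data.frame with one row per seed: `seed`, `post_diestrus_ratio`,
#'   `day2_light_norm_height` (NA when the recording lacks the respective
#'   day).
#' @export
regular_cycle_study <- function(config = generator_config(), n_seeds = 20L,
                                base_seed = 1L, n_days = 7L) {
  out <- lapply(seq_len(n_seeds), function(s) {
    rec <- simulate_recording(config, phase = "reproductive", n_days = n_days,
                              seed = derive_seed(base_seed, s),
                              animal_id = sprintf("S%02d", s))
    an <- analyze_recording(rec)
    st <- an$daily$stage
    post_d <- which(seq_along(st) > 1L & st == "proestrus" &
                    c("", st[-length(st)]) == "diestrus")
    ratio <- if (length(post_d)) an$daily$ratio[post_d[1]] else NA_real_
    h2 <- NA_real_
    if (!is.null(an$alignment)) {
      ev <- an$events
      anchor <- ev$day_offset == 0L & ev$period == "light"
      target <- ev$day_offset == 2L & ev$period == "light"
      if (any(anchor) && any(target)) {
        nh <- normalized_heights(ev, anchor, group_cols = c("day_offset", "period"))
        gm <- nh$group_means
        h2 <- gm$mean_norm_height[gm$day_offset == "2" & gm$period == "light"]
        if (!length(h2)) h2 <- NA_real_
      }
    }
    data.frame(seed = s, post_diestrus_ratio = ratio,
               day2_light_norm_height = h2)
  })
  do.call(rbind, out)
}
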