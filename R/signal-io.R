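#' Decimate a trace by block averaging
#'
#' Reduces the sampling rate by an integer factor: each output sample is the
#' mean of its non-overlapping block of `in_rate / out_rate` input samples.
#' A trailing partial block is dropped. Block averaging is used (rather than
#' filter-and-subsample) because it is bit-reproducible and preserves the
#' trace mean exactly when the length divides evenly.
#'
#' @param trace numeric sample vector.
#' @param in_rate,out_rate input and output sampling rates in Hz;
#'   `in_rate` must be an integer multiple of `out_rate`.
#' @return decimated numeric vector of length `floor(length(trace) * out_rate / in_rate)`.
#' @export
decimate <- function(trace, in_rate, out_rate) {
  if (in_rate <= 0 || out_rate <= 0) {
    stop_arcpulse("rates must be positive", "arcpulse_rate_error")
  }
  f <- in_rate / out_rate
  if (abs(f - round(f)) > 1e-9) {
    stop_arcpulse(sprintf("in_rate (%g Hz) is not an integer multiple of out_rate (%g Hz)",
                          in_rate, out_rate), "arcpulse_rate_error")
  }
  f <- as.integer(round(f))
  if (f == 1L) return(trace)
  nb <- length(trace) %/% f
  if (nb == 0L) return(numeric(0))
  colMeans(matrix(trace[seq_len(nb * f)], nrow = f))
}

#' Read and write photometry sessions as delimited text
#'
#' Sessions are stored as plain text: `# key: value` header lines carrying
#' the metadata (sampling rate, animal, day, period, stage, phase, seed, and
#' ground-truth event times/amplitudes when present), followed by one sample
#' value per line. `read_session(write_session(s))` restores every field and
#' the samples to within text-serialization precision (15 significant
#' digits).
#'
#' @param session a `photometry_session`.
#' @param path file path.
#' @return `read_session` returns a `photometry_session`; `write_session`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  h <- c(
    sprintf("# sampling_rate: %.15g", session$sampling_rate),
    sprintf("# animal_id: %s", session$animal_id),
    sprintf("# day_index: %d", session$day_index),
    sprintf("# period: %s", session$period),
    sprintf("# stage: %s", session$stage),
    sprintf("# phase: %s", session$phase),
    sprintf("# seed: %d", session$seed %||% NA_integer_)
  )
  if (!is.null(session$truth) && length(session$truth$times)) {
    h <- c(h,
      sprintf("# truth_times: %s",
              paste(sprintf("%.15g", session$truth$times), collapse = ",")),
      sprintf("# truth_amplitudes: %s",
              paste(sprintf("%.15g", session$truth$amplitudes), collapse = ",")))
  }
  writeLines(c(h, sprintf("%.15g", session$samples)), path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    stop_arcpulse(sprintf("empty session file: %s", path), "arcpulse_format_error")
  }
  is_hdr <- startsWith(lines, "#")
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  if (n_hdr > 0 && any(!is_hdr[seq_len(n_hdr)])) {
    stop_arcpulse("header lines must precede all samples", "arcpulse_format_error")
  }
  meta <- list()
  for (i in seq_len(n_hdr)) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3) {
      stop_arcpulse(sprintf("malformed header at line %d: %s", i, lines[i]),
                    "arcpulse_format_error")
    }
    meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$sampling_rate)) {
    stop_arcpulse("missing required header 'sampling_rate'", "arcpulse_format_error")
  }
  body <- lines[-seq_len(n_hdr)]
  if (!length(body)) {
    stop_arcpulse("session file contains no samples", "arcpulse_format_error")
  }
  samples <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(samples))
  if (length(bad)) {
    stop_arcpulse(sprintf("non-finite or unparseable sample at line %d: '%s'",
                          n_hdr + bad[1], body[bad[1]]),
                  "arcpulse_format_error")
  }
  truth <- NULL
  if (!is.null(meta$truth_times)) {
    truth <- list(
      times = as.numeric(strsplit(meta$truth_times, ",")[[1]]),
      amplitudes = as.numeric(strsplit(meta$truth_amplitudes %||% "", ",")[[1]])
    )
  }
  structure(list(
    samples = samples,
    sampling_rate = as.numeric(meta$sampling_rate),
    animal_id = meta$animal_id %||% NA_character_,
    day_index = as.integer(meta$day_index %||% NA),
    period = meta$period %||% NA_character_,
    stage = meta$stage %||% NA_character_,
    phase = meta$phase %||% NA_character_,
    seed = as.integer(meta$seed %||% NA),
    truth = truth
  ), class = "photometry_session")
}
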