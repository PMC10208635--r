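#' Simulate a daily estrus-cycle timeline with vaginal-cytology features
#'
#' Emits one record per day: the true estrus stage plus the four cytology
#' features (leukocyte, cornified- and nucleated-epithelial abundance, smear
#' amount) drawn to be consistent with the staging rules of [stage_smear()],
#' so that the stage can be recovered from the features.
#'
#' Phase behaviour: `regular` (and `reproductive`) cycles through
#' P-E-M-D with 4-5 day cycles (a second diestrus day is inserted with
#' probability 0.3); `irregular` lengthens the diestrus run to 5-9 days so a
#' 25-day window holds only 1-2 complete cycles; `acyclic` emits persistent
#' diestrus-like smears and never reaches proestrus.
#'
#' @param config a [generator_config()] (only its seed is consulted when
#'   `seed` is missing).
#' @param phase aging phase label.
#' @param n_days number of days to emit (>= 1).
#' @param seed integer seed.
#' @param misread_prob per-day probability that one cytology feature is
#'   corrupted, emulating smear-reading error (default 0.02).
#'
#' @return data.frame with columns `day`, `true_stage`, `leukocytes`,
#'   `cornified`, `nucleated`, `smear`.
#' @export
simulate_timeline <- function(config = generator_config(), phase, n_days,
                              seed = config$seed, misread_prob = 0.02) {
  phase <- match.arg(phase, AGING_PHASES)
  if (!is.numeric(n_days) || n_days < 1) {
    stop_arcpulse("n_days must be >= 1", "arcpulse_config_error")
  }
  n_days <- as.integer(n_days)

  local_seed(seed, {
    stages <- character(0)
    if (phase %in% c("reproductive", "regular")) {
      while (length(stages) < n_days + 6L) {
        cyc <- c("proestrus", "estrus", "metestrus", "diestrus")
        if (stats::runif(1) < 0.3) cyc <- c(cyc, "diestrus")
        stages <- c(stages, cyc)
      }
      offset <- sample.int(5L, 1L) - 1L
      stages <- stages[(offset + 1):(offset + n_days)]
    } else if (phase == "irregular") {
      while (length(stages) < n_days + 12L) {
        n_d <- sample(5:9, 1L)
        stages <- c(stages, "proestrus", "estrus", "metestrus",
                    rep("diestrus", n_d))
      }
      offset <- sample.int(10L, 1L) - 1L
      stages <- stages[(offset + 1):(offset + n_days)]
    } else {
      # acyclic: persistent diestrus-like smears with occasional metestrus-like
      # days, never proestrus
      stages <- ifelse(stats::runif(n_days) < 0.1, "metestrus", "diestrus")
    }

    feats <- do.call(rbind, lapply(stages, emit_cytology))
    # smear-reading noise: corrupt one random feature on a few days
    bad <- which(stats::runif(n_days) < misread_prob)
    for (i in bad) {
      j <- sample.int(4L, 1L)
      lev <- if (j == 4L) c("small", "medium", "large") else c("none", "low", "high")
      feats[i, j] <- sample(setdiff(lev, feats[i, j]), 1L)
    }
    data.frame(day = seq_len(n_days), true_stage = stages, feats,
               stringsAsFactors = FALSE)
  })
}

# Draw cytology features for one true stage, consistent with the rule table
# in stage_smear().
emit_cytology <- function(stage) {
  f <- switch(stage,
    proestrus = list(
      leukocytes = sample(c("none", "low"), 1L, prob = c(0.8, 0.2)),
      cornified  = sample(c("none", "low"), 1L, prob = c(0.4, 0.6)),
      nucleated  = "high",
      smear      = "medium"
    ),
    estrus = list(
      leukocytes = "none",
      cornified  = "high",
      nucleated  = sample(c("none", "low"), 1L, prob = c(0.7, 0.3)),
      smear      = "large"
    ),
    metestrus = if (stats::runif(1) < 0.5) {
      # early metestrus: cornified cells in abundant leukocytes
      list(leukocytes = "high", cornified = "high", nucleated = "none",
           smear = sample(c("medium", "large"), 1L))
    } else {
      # late metestrus: some nucleated cells in abundant leukocytes
      list(leukocytes = "high", cornified = "none", nucleated = "low",
           smear = "large")
    },
    diestrus = list(
      leukocytes = "high",
      cornified  = sample(c("none", "low"), 1L, prob = c(0.7, 0.3)),
      nucleated  = "none",
      smear      = "small"
    )
  )
  data.frame(f, stringsAsFactors = FALSE)
}

#' Simulate a Ct table for qPCR round-trip testing
#'
#' Generates cycle-threshold values for the KNDy marker genes (`Kiss1`,
#' `Tac2`, `Pdyn`), the regional marker `Npy`, and the housekeeping gene
#' `Gapdh` over two phases (`reproductive` reference and `acyclic`), such
#' that the 2^-ddCt chain of [relative_expression()] recovers
#' `true_fold_changes` in expectation. Each sample carries a random plate
#' offset (a constant added to all its Ct values) which the ddCt arithmetic
#' must cancel.
#'
#' @param true_fold_changes named numeric vector of expression fold changes
#'   (acyclic relative to reproductive) for a subset of genes; unnamed genes
#'   default to 1. Must be strictly positive.
#' @param n_samples samples per phase.
#' @param ct_noise_sd per-well Ct noise standard deviation, cycles.
#' @param seed integer seed.
#'
#' @return data.frame with columns `sample_id`, `phase`, `gene`, `ct`.
#' @export
simulate_ct_table <- function(true_fold_changes = c(Kiss1 = 1),
                              n_samples = 6, ct_noise_sd = 0, seed = 1L) {
  genes <- c("Kiss1", "Tac2", "Pdyn", "Npy", "Gapdh")
  base_ct <- c(Kiss1 = 24, Tac2 = 26, Pdyn = 27, Npy = 22, Gapdh = 18)
  if (any(true_fold_changes <= 0)) {
    stop_arcpulse("fold changes must be strictly positive", "arcpulse_config_error")
  }
  unknown <- setdiff(names(true_fold_changes), genes)
  if (length(unknown)) {
    stop_arcpulse(paste("unknown gene(s):", paste(unknown, collapse = ", ")),
                  "arcpulse_config_error")
  }
  if (ct_noise_sd < 0) {
    stop_arcpulse("ct_noise_sd must be >= 0", "arcpulse_config_error")
  }
  folds <- stats::setNames(rep(1, length(genes)), genes)
  folds[names(true_fold_changes)] <- true_fold_changes

  local_seed(seed, {
    rows <- list()
    for (ph in c("reproductive", "acyclic")) {
      for (s in seq_len(n_samples)) {
        sid <- sprintf("%s_%02d", ph, s)
        offset <- stats::rnorm(1, 0, 0.5)   # plate/loading shift, cancels in ddCt
        ct <- base_ct + offset
        if (ph == "acyclic") ct <- ct - log2(folds)
        if (ct_noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, phase = ph, gene = genes, ct = unname(ct),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
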