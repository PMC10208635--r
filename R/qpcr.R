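#' Relative expression by the 2^-ddCt method with sequential normalization
#'
#' Implements the two-reference chain used for arcuate-tissue expression:
#' each sample's target Ct is first normalized to the housekeeping gene
#' (`Gapdh`, on the Ct scale: `dCt = Ct_target - Ct_Gapdh`), the resulting
#' expression `2^-dCt` is then divided by the same sample's `Npy`-vs-`Gapdh`
#' expression (the regional-marker normalization, applied on the expression
#' scale), and the result is finally divided by the mean of that quantity in
#' the reference phase, whose mean is therefore exactly 1. Replicate wells
#' (duplicated sample/gene rows) are averaged on the Ct scale first. The
#' whole chain is invariant to adding a constant to all Ct values of a
#' sample (plate offset).
#'
#' @param records long data.frame with columns `sample_id`, `phase`, `gene`,
#'   `ct` (e.g. from [simulate_ct_table()]).
#' @param target_gene gene to quantify, e.g. `"Kiss1"`.
#' @param reference_phase phase whose mean defines 1 (default
#'   `"reproductive"`).
#' @param reference_genes housekeeping and regional reference genes, in
#'   order of application.
#' @return data.frame with `sample_id`, `phase`, `relative_expression`.
#' @export
relative_expression <- function(records, target_gene,
                                reference_phase = "reproductive",
                                reference_genes = c("Gapdh", "Npy")) {
  needed <- c("sample_id", "phase", "gene", "ct")
  if (!all(needed %in% names(records))) {
    stop_arcpulse(paste("records must have columns:", paste(needed, collapse = ", ")),
                  "arcpulse_input_error")
  }
  if (any(!is.finite(records$ct))) {
    stop_arcpulse("Ct values must be finite", "arcpulse_input_error")
  }
  for (g in c(target_gene, reference_genes)) {
    if (!g %in% records$gene) {
      stop_arcpulse(sprintf("gene '%s' missing from the Ct table", g),
                    "arcpulse_input_error")
    }
  }
  if (!reference_phase %in% records$phase) {
    stop_arcpulse(sprintf("reference phase '%s' missing from the Ct table",
                          reference_phase), "arcpulse_input_error")
  }
  # average replicate wells on the Ct scale
  key <- interaction(records$sample_id, records$gene, drop = TRUE, sep = "\r")
  cts <- tapply(records$ct, key, mean)
  parts <- do.call(rbind, strsplit(names(cts), "\r", fixed = TRUE))
  wide <- data.frame(sample_id = parts[, 1], gene = parts[, 2],
                     ct = as.numeric(cts), stringsAsFactors = FALSE)
  samples <- unique(records[, c("sample_id", "phase")])
  get_ct <- function(sid, g) {
    v <- wide$ct[wide$sample_id == sid & wide$gene == g]
    if (!length(v)) NA_real_ else v
  }
  hk <- reference_genes[1]; regional <- reference_genes[2]
  expr <- vapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    ct_t <- get_ct(sid, target_gene)
    ct_h <- get_ct(sid, hk)
    ct_r <- get_ct(sid, regional)
    if (any(is.na(c(ct_t, ct_h, ct_r)))) {
      stop_arcpulse(sprintf("sample '%s' lacks a Ct for %s", sid,
                            paste(c(target_gene, hk, regional)[
                              is.na(c(ct_t, ct_h, ct_r))], collapse = ", ")),
                    "arcpulse_input_error")
    }
    2^-(ct_t - ct_h) / 2^-(ct_r - ct_h)
  }, numeric(1))
  ref_mean <- mean(expr[samples$phase == reference_phase])
  data.frame(sample_id = samples$sample_id, phase = samples$phase,
             relative_expression = expr / ref_mean,
             stringsAsFactors = FALSE)
}

#' Relative-expression table for several target genes
#'
#' Convenience wrapper running [relative_expression()] for each target and
#' binding the results.
#'
#' @inheritParams relative_expression
#' @param target_genes character vector of targets (default the KNDy
#'   markers `Kiss1`, `Tac2`, `Pdyn`).
#' @return long data.frame with `gene`, `sample_id`, `phase`,
#'   `relative_expression`.
#' @export
qpcr_table <- function(records, target_genes = c("Kiss1", "Tac2", "Pdyn"),
                       reference_phase = "reproductive",
                       reference_genes = c("Gapdh", "Npy")) {
  do.call(rbind, lapply(target_genes, function(g) {
    out <- relative_expression(records, g, reference_phase, reference_genes)
    cbind(gene = g, out, stringsAsFactors = FALSE)
  }))
}
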