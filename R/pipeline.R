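#' End-to-end two-group comparison
#'
#' Runs the standard analysis chain on an exposure series: slope fitting,
#' QC filtering, signal-matrix construction, within-chip log2 fold-changes
#' with replicate averaging, resampling kinase enrichment on the pooled
#' differential set (optionally direction-split), and — when a substrate map
#' is supplied — percentile normalization of the enrichment z scores.
#'
#' @param series an `exposure_series`
#' @param case,control group labels to compare
#' @param map optional `kinase_peptide_map`; without it the kinase stages are
#'   skipped
#' @param low_signal_threshold,linearity_threshold QC thresholds
#'   (see [apply_qc()])
#' @param cutoff log2FC classification cutoff
#' @param iterations,seed resampling parameters (see [krsa_score()])
#' @param direction `"both"` pools up and down peptides into one differential
#'   set; `"split"` scores each direction separately
#' @return list with `slopes`, `qc`, `matrix`, `log2fc`, `global`,
#'   `cv`, and (with a map) `krsa` plus `krsa_percentiles`
#' @export
#' @examples
#' cfg <- simulation_config(n_kinases = 10, seed = 11,
#'   active_kinases = list(synaptosomal = c(KIN_01 = 1.8)))
#' sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
#' res <- analyze_comparison(sim$series, "synaptosomal", "nuclear",
#'   map = generate_kinase_map(cfg), iterations = 200, seed = 5)
#' head(res$krsa)
analyze_comparison <- function(series, case, control, map = NULL,
                               low_signal_threshold = 2,
                               linearity_threshold = 0.9,
                               cutoff = 0.15, iterations = 2000, seed = 1L,
                               direction = c("both", "split")) {
  direction <- match.arg(direction)
  df <- as.data.frame(series)
  sub <- df[df$group %in% c(case, control), , drop = FALSE]
  abort_if(nrow(sub) == 0, "groups absent from series")
  slopes <- fit_slopes(as_exposure_series(sub))
  qc <- apply_qc(slopes, low_signal_threshold, linearity_threshold)
  mat <- build_signal_matrix(slopes, keep = qc$keep)
  fc <- log2fc(mat, case, control, cutoff = cutoff)
  glob <- global_test(mat, c(case, control), paired = TRUE)
  cv <- cv_report(slopes, keep = qc$keep)
  out <- list(slopes = slopes, qc = qc, matrix = mat, log2fc = fc,
              global = glob, cv = cv)
  if (!is.null(map)) {
    if (direction == "both") {
      peps <- differential_peptides(fc, "both")
      abort_if(length(peps) == 0, "no differential peptides at cutoff ",
               cutoff)
      out$krsa <- krsa_score(peps, qc$keep, map,
                             iterations = iterations, seed = seed)
      out$krsa_percentiles <- percentile_normalize(out$krsa)
    } else {
      out$krsa <- krsa_direction_split(fc, map, universe = qc$keep,
                                       iterations = iterations, seed = seed)
    }
  }
  out
}

#' Duplicate a percentile table as a stand-in extra tool
#'
#' Testing helper for the multi-tool selection rule when only one real tool
#' is available: relabels a percentile table under a new tool name so the
#' "reported by >= 2 tools" requirement can be exercised.
#'
#' @param tool_percentiles data.frame `kinase`, `tool`, `percentile`
#' @param as_tool new tool label
#' @return the relabeled data.frame
#' @export
duplicate_tool <- function(tool_percentiles, as_tool) {
  out <- as.data.frame(tool_percentiles)
  out$tool <- as_tool
  out
}
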