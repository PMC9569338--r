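#' Within-chip log2 fold-changes between two groups
#'
#' For every replicate chip carrying both groups, the per-peptide log2
#' fold-change is the difference of log2 slope signals between the case and
#' control wells of that chip; chips are technical replicates, so per-chip
#' values are averaged into `mean_log2fc`. Peptides are classified `up` /
#' `down` / `unchanged` by comparing `|mean_log2fc|` to `cutoff` (default
#' 0.15, the magnitude of phosphorylation change commonly taken as
#' biologically meaningful on these arrays).
#'
#' @param matrix a `signal_matrix` from [build_signal_matrix()]
#' @param case,control group labels to compare (case relative to control)
#' @param cutoff classification cutoff on `|mean_log2fc|` (inclusive)
#' @return a `log2fc_table` data.frame: `peptide_id`, one `lfc_<chip>` column
#'   per chip, `mean_log2fc`, `classification`; attribute `chips` lists the
#'   chips used
#' @export
#' @examples
#' cfg <- simulation_config(n_kinases = 5, noise_cv = 0, seed = 3,
#'   active_kinases = list(synaptosomal = c(KIN_01 = 2)))
#' sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
#' m <- build_signal_matrix(fit_slopes(sim$series))
#' fc <- log2fc(m, "synaptosomal", "nuclear")
#' table(fc$classification)
log2fc <- function(matrix, case, control, cutoff = 0.15) {
  stopifnot(inherits(matrix, "signal_matrix"))
  abort_if(cutoff < 0, "cutoff must be >= 0")
  design <- matrix$design
  abort_if(!case %in% design$group, "case group absent: ", case)
  abort_if(!control %in% design$group, "control group absent: ", control)
  chips <- sort(unique(design$chip))
  usable <- vapply(chips, function(c) {
    any(design$group == case & design$chip == c) &&
      any(design$group == control & design$chip == c)
  }, logical(1))
  if (any(!usable))
    warning("chip(s) lacking one of the groups omitted: ",
            paste(chips[!usable], collapse = ", "))
  chips <- chips[usable]
  abort_if(length(chips) == 0,
           "no chip carries both ", case, " and ", control)
  per_chip <- vapply(chips, function(c) {
    cs <- design$sample_id[design$group == case & design$chip == c]
    ct <- design$sample_id[design$group == control & design$chip == c]
    matrix$log2[, cs] - matrix$log2[, ct]
  }, numeric(nrow(matrix$log2)))
  colnames(per_chip) <- paste0("lfc_", chips)
  mean_fc <- rowMeans(per_chip)
  cls <- ifelse(mean_fc >= cutoff, "up",
                ifelse(mean_fc <= -cutoff, "down", "unchanged"))
  out <- data.frame(peptide_id = rownames(matrix$log2), per_chip,
                    mean_log2fc = mean_fc, classification = cls,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  structure(out, class = c("log2fc_table", "data.frame"),
            chips = chips, case = case, control = control, cutoff = cutoff)
}

#' Differential peptides of a log2fc table
#' @param fc a `log2fc_table`
#' @param direction `"both"`, `"up"` or `"down"`
#' @return character vector of peptide ids
#' @export
differential_peptides <- function(fc, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 both = fc$classification != "unchanged",
                 up = fc$classification == "up",
                 down = fc$classification == "down")
  fc$peptide_id[keep]
}

#' Global nonparametric comparison of two groups
#'
#' Compares per-peptide signals between two groups with a two-sided Wilcoxon
#' test: rank-sum for unpaired use, signed-rank (paired over peptides) when
#' both groups measure the same peptides. Observations are per-peptide mean
#' log2 signals across each group's samples. Exact p-values are used for
#' small samples without ties; zero paired differences are dropped (the
#' classical signed-rank rule), and if all differences are zero the test is
#' reported with p = 1.
#'
#' @param matrix a `signal_matrix`
#' @param groups length-2 character vector of group labels
#' @param paired use the signed-rank test (pairing by peptide)
#' @return a `global_comparison` list: `groups`, `test` (`rank_sum` or
#'   `signed_rank`), `statistic`, `p_value`, `group_means` (mean log2 signal
#'   per group)
#' @export
global_test <- function(matrix, groups, paired = TRUE) {
  stopifnot(inherits(matrix, "signal_matrix"), length(groups) == 2)
  design <- matrix$design
  miss <- setdiff(groups, design$group)
  abort_if(length(miss) > 0, "group(s) absent: ", paste(miss, collapse = ", "))
  vals <- lapply(groups, function(g) {
    cols <- design$sample_id[design$group == g]
    rowMeans(matrix$log2[, cols, drop = FALSE])
  })
  x <- vals[[1]]; y <- vals[[2]]
  test <- if (paired) "signed_rank" else "rank_sum"
  if (paired) {
    abort_if(length(x) < 3, "need >= 3 paired observations")
    d <- x - y
    if (all(d == 0)) {
      stat <- 0; p <- 1
    } else {
      ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                         alternative = "two.sided"))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(groups = groups, test = test, statistic = stat, p_value = p,
                 group_means = setNames(vapply(vals, mean, numeric(1)), groups)),
            class = "global_comparison")
}

#' @export
print.global_comparison <- function(x, ...) {
  cat(sprintf("%s test, %s vs %s: statistic = %g, p = %.4g\n",
              x$test, x$groups[1], x$groups[2], x$statistic, x$p_value))
  invisible(x)
}

#' Chip-to-chip coefficient of variation report
#'
#' Reproducibility metric across replicate chips: for each peptide and group,
#' CV% = 100 * sd/mean of the slope signal over chips (sample sd, n-1
#' denominator). The per-group summary is the median CV over the retained
#' peptides; array vendors typically call median CV below ~9% acceptable.
#'
#' @param signals a `slope_signal` from [fit_slopes()]
#' @param keep peptides to include (e.g. the QC keep-list); `NULL` keeps all
#' @return a `cv_report` list: `per_peptide` (peptide_id, group, cv_pct) and
#'   `group_medians` (group, median_cv_pct). Peptides with zero mean signal
#'   in a group have undefined CV and are excluded with a warning.
#' @export
cv_report <- function(signals, keep = NULL) {
  df <- as.data.frame(signals)
  if (!is.null(keep)) df <- df[df$peptide_id %in% keep, , drop = FALSE]
  dt <- data.table::as.data.table(df)
  n_chips <- dt[, .(n = data.table::uniqueN(chip)), by = group]
  abort_if(any(n_chips$n < 2), "CV needs >= 2 chips per group")
  cv <- dt[, .(mean_signal = mean(signal),
               cv_pct = 100 * sd(signal) / mean(signal)),
           by = .(peptide_id, group)]
  undef <- cv$mean_signal == 0
  if (any(undef)) {
    warning(sum(undef), " (peptide, group) cell(s) with zero mean signal ",
            "excluded from the CV report")
    cv <- cv[!undef]
  }
  med <- cv[, .(median_cv_pct = median(cv_pct)), by = group]
  structure(list(per_peptide = as.data.frame(cv[, .(peptide_id, group, cv_pct)]),
                 group_medians = as.data.frame(med)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("median CV% by group:\n")
  print(x$group_medians, row.names = FALSE)
  invisible(x)
}
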