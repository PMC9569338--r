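#' Fit per-peptide kinetic slopes
#'
#' The activity readout of a reporter peptide is the slope of fluorescence
#' intensity versus camera exposure time, fitted by ordinary least squares
#' with an intercept, separately for each (peptide, group, chip) well. The
#' slope is multiplied by `scale_factor` (chip-ecosystem convention, default
#' 100) to form the working signal; negative fitted slopes are truncated to
#' zero since a phosphorylation signal cannot be negative.
#'
#' A well with constant intensity has undefined R-squared; it is recorded as
#' 0 with reason `constant_signal` so it fails the linearity filter.
#'
#' @param series an `exposure_series`
#' @param scale_factor multiplier applied to the raw slope to form `signal`
#' @return a `slope_signal` data.frame with one row per (peptide, group,
#'   chip): `slope`, `intercept`, `r_squared`, `signal_at_max_exposure`
#'   (intensity at the longest exposure), `signal` (truncated, scaled slope),
#'   `fit_flag` (`ok` or `constant_signal`)
#' @export
#' @examples
#' cfg <- simulation_config(n_kinases = 3, noise_cv = 0, seed = 7)
#' sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
#' slopes <- fit_slopes(sim$series)
#' head(slopes)
fit_slopes <- function(series, scale_factor = 100) {
  df <- as.data.frame(series)
  need <- c("peptide_id", "group", "chip", "exposure_ms", "intensity")
  abort_if(!all(need %in% names(df)), "not an exposure series")
  dt <- data.table::as.data.table(df)
  res <- dt[, {
    abort_if(data.table::uniqueN(exposure_ms) < 2,
             "slope fitting needs >= 2 distinct exposures for peptide ",
             peptide_id[1], ", sample ", sample_id(group[1], chip[1]))
    t <- exposure_ms; y <- intensity
    tm <- mean(t); ym <- mean(y)
    sxx <- sum((t - tm)^2); sxy <- sum((t - tm) * (y - ym))
    syy <- sum((y - ym)^2)
    b <- sxy / sxx
    r2 <- if (syy <= 0) 0 else (sxy * sxy) / (sxx * syy)
    .(slope = b, intercept = ym - b * tm, r_squared = r2,
      signal_at_max_exposure = y[which.max(t)],
      fit_flag = if (syy <= 0) "constant_signal" else "ok")
  }, by = .(peptide_id, group, chip)]
  res[, signal := pmax(slope, 0) * scale_factor]
  out <- as.data.frame(res)
  structure(out, class = c("slope_signal", "data.frame"))
}

#' Apply the low-signal and linearity quality-control filters
#'
#' A well passes QC when its intensity at the longest exposure reaches
#' `low_signal_threshold` (very dim spots carry no usable kinetic signal) and
#' its intensity-versus-exposure fit is adequately linear
#' (R-squared >= `linearity_threshold`). A peptide is kept when it passes in
#' all samples (`scope = "all"`, the default) or in at least one
#' (`scope = "any"`).
#'
#' @param signals a `slope_signal` from [fit_slopes()]
#' @param low_signal_threshold minimum intensity at the longest exposure
#' @param linearity_threshold minimum R-squared of the kinetic fit
#' @param scope `"all"` or `"any"` — how well-level passes combine per peptide
#' @return a `qc_result` list: `per_sample` (well-level `qc_pass` and
#'   `reason` in \{`low_signal`, `nonlinear`, `low_signal;nonlinear`, `""`\}),
#'   `keep` (character vector of kept peptides), `drop_reasons` (named vector,
#'   first failing reason per dropped peptide), plus the thresholds used
#' @export
apply_qc <- function(signals, low_signal_threshold = 2,
                     linearity_threshold = 0.9,
                     scope = c("all", "any")) {
  scope <- match.arg(scope)
  abort_if(low_signal_threshold < 0 || linearity_threshold < 0,
           "thresholds must be >= 0")
  df <- as.data.frame(signals)
  low <- df$signal_at_max_exposure < low_signal_threshold
  nonlin <- df$r_squared < linearity_threshold
  df$qc_pass <- !(low | nonlin)
  df$reason <- ifelse(low & nonlin, "low_signal;nonlinear",
                      ifelse(low, "low_signal",
                             ifelse(nonlin, "nonlinear", "")))
  agg <- if (scope == "all") all else any
  by_pep <- split(df$qc_pass, df$peptide_id)
  kept <- vapply(by_pep, agg, logical(1))
  keep <- names(kept)[kept]
  dropped <- names(kept)[!kept]
  drop_reasons <- vapply(dropped, function(p) {
    r <- df$reason[df$peptide_id == p & df$reason != ""]
    if (length(r) == 0) "" else r[1]
  }, character(1))
  structure(list(per_sample = df, keep = keep, drop_reasons = drop_reasons,
                 low_signal_threshold = low_signal_threshold,
                 linearity_threshold = linearity_threshold, scope = scope),
            class = "qc_result")
}

#' Build log2 and per-peptide Z-scaled signal matrices
#'
#' Signals are floored at `floor` before log2 so zero-slope wells do not
#' produce infinities; the floored log2 matrix is then standardized per
#' peptide row (mean 0, sd 1) for clustering and heatmaps. Constant rows get
#' an all-zero standardized row.
#'
#' @param signals a `slope_signal` from [fit_slopes()]
#' @param keep peptides to retain (e.g. `apply_qc(...)$keep`); `NULL` keeps all
#' @param floor lower bound applied to `signal` before log2
#' @return a `signal_matrix` list: `log2` (peptides x samples matrix of
#'   log2 signals), `z` (row-standardized copy), `design` (sample_id, group,
#'   chip for the columns)
#' @export
build_signal_matrix <- function(signals, keep = NULL, floor = 1) {
  df <- as.data.frame(signals)
  if (!is.null(keep)) {
    abort_if(length(keep) == 0, "empty keep-list")
    df <- df[df$peptide_id %in% keep, , drop = FALSE]
    abort_if(nrow(df) == 0, "keep-list matches no peptides")
  }
  df$sample_id <- sample_id(df$group, df$chip)
  design <- unique(df[c("sample_id", "group", "chip")])
  design <- design[order(match(design$group, unique(df$group)), design$chip), ]
  peps <- unique(df$peptide_id)
  m <- matrix(NA_real_, length(peps), nrow(design),
              dimnames = list(peps, design$sample_id))
  m[cbind(match(df$peptide_id, peps), match(df$sample_id, design$sample_id))] <-
    log2(pmax(df$signal, floor))
  abort_if(anyNA(m), "signal table is not complete over peptides x samples")
  z <- t(apply(m, 1, function(r) {
    s <- sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(m)
  structure(list(log2 = m, z = z, design = as_design(design)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$log2), "peptides x", ncol(x$log2), "samples (",
      length(unique(x$design$group)), "groups,",
      length(unique(x$design$chip)), "chips )\n")
  invisible(x)
}
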