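#' Clustered heatmap of Z-scaled signals
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance by default) of the per-peptide standardized signal matrix, drawn
#' with row and column dendrograms. Clustering is deterministic for a fixed
#' input and invariant to input row order. A constant matrix cannot be
#' clustered; it is drawn without dendrograms, with a warning.
#'
#' @param matrix a `signal_matrix`, or a numeric matrix already standardized
#' @param peptides optional subset of row names to display
#' @param linkage agglomeration method passed to the clusterer
#' @param metric distance metric
#' @param filename optional output file (png/pdf); `NA` draws to the device
#' @param ... passed on to [pheatmap::pheatmap()]
#' @return the pheatmap object, invisibly
#' @export
plot_heatmap <- function(matrix, peptides = NULL, linkage = "complete",
                         metric = "euclidean", filename = NA, ...) {
  m <- if (inherits(matrix, "signal_matrix")) matrix$z else matrix
  if (!is.null(peptides)) {
    miss <- setdiff(peptides, rownames(m))
    abort_if(length(miss) > 0, "unknown peptide(s): ",
             paste(head(miss, 3), collapse = ", "))
    m <- m[peptides, , drop = FALSE]
  }
  abort_if(nrow(m) < 2 || ncol(m) < 2, "heatmap needs >= 2 rows and columns")
  m <- m[order(rownames(m)), , drop = FALSE]
  constant <- sd(as.vector(m)) == 0
  if (constant) warning("constant matrix; clustering skipped")
  extra <- list(...)
  if (constant && is.null(extra$breaks)) # degenerate color scale needs breaks
    extra$breaks <- seq(m[1] - 1, m[1] + 1, length.out = 101)
  p <- do.call(pheatmap::pheatmap, c(list(
    m, cluster_rows = !constant, cluster_cols = !constant,
    clustering_method = linkage,
    clustering_distance_rows = metric,
    clustering_distance_cols = metric,
    filename = filename, silent = TRUE), extra))
  invisible(p)
}

#' Waterfall plot data
#'
#' Long-format table behind the waterfall plot: peptides ordered by mean
#' log2 fold-change, with per-chip values and the replicate mean, colored by
#' whether `|mean|` exceeds the display cutoff.
#'
#' @param fc a `log2fc_table`
#' @param display_cutoff coloring cutoff on `|mean_log2fc|` (display only;
#'   independent of the classification cutoff)
#' @return data.frame `peptide_id` (factor ordered by mean), `chip`
#'   (`"mean"` for the replicate mean), `log2fc`, `is_mean`, `color_class`
#' @export
waterfall_data <- function(fc, display_cutoff = 0.2) {
  stopifnot(inherits(fc, "log2fc_table"))
  lfc_cols <- grep("^lfc_", names(fc), value = TRUE)
  ord <- order(fc$mean_log2fc)
  lev <- fc$peptide_id[ord]
  long <- do.call(rbind, lapply(lfc_cols, function(cl) {
    data.frame(peptide_id = fc$peptide_id, chip = sub("^lfc_", "", cl),
               log2fc = fc[[cl]], is_mean = FALSE, stringsAsFactors = FALSE)
  }))
  long <- rbind(long, data.frame(peptide_id = fc$peptide_id, chip = "mean",
                                 log2fc = fc$mean_log2fc, is_mean = TRUE,
                                 stringsAsFactors = FALSE))
  cls <- setNames(ifelse(fc$mean_log2fc > display_cutoff, "up",
                         ifelse(fc$mean_log2fc < -display_cutoff, "down",
                                "within")), fc$peptide_id)
  long$color_class <- unname(cls[long$peptide_id])
  long$peptide_id <- factor(long$peptide_id, levels = lev)
  long[order(long$peptide_id, long$is_mean, long$chip), , drop = FALSE]
}

#' Waterfall plot of per-peptide log2 fold-changes
#'
#' Peptides sorted by mean log2FC on the vertical axis; small points are the
#' per-chip values, the large point is the replicate mean, colored by whether
#' the mean exceeds `display_cutoff` in magnitude.
#'
#' @inheritParams waterfall_data
#' @param filename optional output file; written via [ggplot2::ggsave()]
#' @return the ggplot object, invisibly
#' @export
plot_waterfall <- function(fc, display_cutoff = 0.2, filename = NULL) {
  d <- waterfall_data(fc, display_cutoff)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log2fc, y = peptide_id,
                                       color = color_class)) +
    ggplot2::geom_point(data = d[!d$is_mean, ], size = 1, alpha = 0.6) +
    ggplot2::geom_point(data = d[d$is_mean, ], size = 3) +
    ggplot2::geom_vline(xintercept = c(-display_cutoff, display_cutoff),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(up = "#d73027", down = "#4575b4",
                                           within = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = NULL, color = NULL)
  if (!is.null(filename)) ggplot2::ggsave(filename, p, width = 6, height = 8)
  invisible(p)
}

#' Kinetic signal curves
#'
#' Intensity versus exposure time for selected peptides, one panel per
#' peptide, colored by group; replicate chips are drawn as separate lines.
#'
#' @param series an `exposure_series`
#' @param peptides peptides to plot (must exist in the series)
#' @param filename optional output file
#' @return the ggplot object, invisibly
#' @export
plot_kinetic_curves <- function(series, peptides, filename = NULL) {
  abort_if(length(peptides) == 0, "empty peptide selection")
  df <- as.data.frame(series)
  miss <- setdiff(peptides, unique(df$peptide_id))
  abort_if(length(miss) > 0, "unknown peptide(s): ",
           paste(head(miss, 3), collapse = ", "))
  df <- df[df$peptide_id %in% peptides, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = exposure_ms, y = intensity,
                                        color = group,
                                        group = interaction(group, chip))) +
    ggplot2::geom_line(alpha = 0.8) + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~peptide_id, scales = "free_y") +
    ggplot2::labs(x = "exposure time (ms)", y = "signal intensity")
  if (!is.null(filename)) ggplot2::ggsave(filename, p, width = 8, height = 6)
  invisible(p)
}

#' Violin/box plot of global signals per group
#'
#' Per-peptide mean log2 signal by group, as violins with an overlaid
#' boxplot.
#'
#' @param matrix a `signal_matrix`
#' @param style `"violin"` or `"box"`
#' @param filename optional output file
#' @return the ggplot object, invisibly
#' @export
plot_global_signals <- function(matrix, style = c("violin", "box"),
                                filename = NULL) {
  style <- match.arg(style)
  design <- matrix$design
  d <- do.call(rbind, lapply(unique(design$group), function(g) {
    cols <- design$sample_id[design$group == g]
    data.frame(group = g,
               signal = rowMeans(matrix$log2[, cols, drop = FALSE]))
  }))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = group, y = signal, fill = group)) +
    ggplot2::labs(x = NULL, y = "mean log2 signal") +
    ggplot2::theme(legend.position = "none")
  p <- if (style == "violin")
    p + ggplot2::geom_violin() +
      ggplot2::geom_boxplot(width = 0.15, fill = "white")
  else p + ggplot2::geom_boxplot()
  if (!is.null(filename)) ggplot2::ggsave(filename, p, width = 6, height = 4)
  invisible(p)
}

#' Write a run manifest
#'
#' Records what a pipeline run consisted of: the configuration snapshot,
#' seeds, md5 digests and row counts of every output table, and the package
#' version — enough to re-run and verify bit-identical outputs.
#'
#' @param out_dir directory whose tabular outputs are listed
#' @param config list of configuration values to snapshot
#' @param seeds named list/vector of seeds used
#' @param path output JSON path (default `<out_dir>/manifest.json`)
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(out_dir, config = list(), seeds = list(),
                           path = file.path(out_dir, "manifest.json")) {
  files <- sort(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE))
  tables <- lapply(files, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)),
         rows = length(readLines(f)) - 1L)
  })
  manifest <- list(
    package = "kinact",
    version = as.character(utils::packageVersion("kinact")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = seeds, tables = tables)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
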