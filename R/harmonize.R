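#' Percentile-rank normalization of per-tool kinase scores
#'
#' Converts each tool's kinase ranking to percentiles so heterogeneous score
#' scales become comparable: within a tool, percentile = rank / N with
#' average ranks for ties, oriented so the best-scoring kinase gets exactly
#' 1.0. Tools whose scores are best-first ranks (`lower_is_better`) are
#' inverted before ranking. Percentiles are invariant to any strictly
#' monotone transform of a tool's scores.
#'
#' @param scores a `tool_scores` data.frame (see [as_tool_scores()]) or a
#'   `krsa_result` (converted via [krsa_as_tool_scores()])
#' @return data.frame `kinase`, `tool`, `percentile` (in (0, 1])
#' @export
#' @examples
#' s <- as_tool_scores(data.frame(
#'   kinase = c("A", "B", "C"), tool = "UKA", score = c(3, 2, 1),
#'   score_direction = "higher_is_better"))
#' percentile_normalize(s)
percentile_normalize <- function(scores) {
  if (inherits(scores, "krsa_result")) scores <- krsa_as_tool_scores(scores)
  scores <- as_tool_scores(scores)
  parts <- split(scores, scores$tool)
  out <- do.call(rbind, lapply(parts, function(p) {
    dirs <- unique(p$score_direction)
    abort_if(length(dirs) > 1,
             "mixed score_direction within tool ", p$tool[1])
    s <- if (dirs == "lower_is_better") -p$score else p$score
    data.frame(kinase = p$kinase, tool = p$tool,
               percentile = rank(s, ties.method = "average") / length(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert a KRSA result to a tool-score table
#'
#' The resampling z score is the ranking metric (higher is better); kinases
#' with an undefined z (degenerate null) are omitted with a warning.
#'
#' @param res a `krsa_result`
#' @param tool tool label to assign
#' @return a `tool_scores` data.frame
#' @export
krsa_as_tool_scores <- function(res, tool = "KRSA") {
  stopifnot(inherits(res, "krsa_result"))
  drop <- is.na(res$z)
  if (any(drop))
    warning(sum(drop), " kinase(s) with undefined z omitted from tool scores: ",
            paste(head(res$kinase[drop], 5), collapse = ", "))
  as_tool_scores(data.frame(kinase = res$kinase[!drop], tool = tool,
                            score = res$z[!drop],
                            score_direction = "higher_is_better",
                            stringsAsFactors = FALSE))
}

#' Harmonize per-tool kinase percentiles into unified scores
#'
#' Joins the percentile tables of several tools on a common kinase namespace
#' (optionally mapping input symbols through an alias table, e.g. to HGNC
#' symbols), then computes per kinase the mean and median percentile over the
#' tools that report it. A kinase is `selected` when it is reported by at
#' least `min_tools` tools and its mean percentile is at least
#' `min_mean_percentile`. For display, mean percentiles are binned into
#' quartiles Q1 [0, 0.25), Q2 [0.25, 0.5), Q3 [0.5, 0.75), Q4 [0.75, 1].
#'
#' @param tool_percentiles data.frame `kinase`, `tool`, `percentile` —
#'   typically `rbind()` of [percentile_normalize()] outputs
#' @param alias_table optional data.frame `alias`, `symbol`; kinase names
#'   matching `alias` are replaced by `symbol` before joining. If two inputs
#'   collapse onto one symbol within a tool, the better percentile is kept
#'   and a message is emitted.
#' @param min_tools minimum number of reporting tools for selection
#' @param min_mean_percentile minimum mean percentile for selection
#' @return a `harmonized_kinase` data.frame: `kinase`, one `pct_<tool>`
#'   column per tool, `n_tools`, `mean_percentile`, `median_percentile`,
#'   `selected`, `quartile_bin`; sorted by decreasing mean percentile
#' @export
harmonize <- function(tool_percentiles, alias_table = NULL,
                      min_tools = 2, min_mean_percentile = 0.75) {
  df <- as.data.frame(tool_percentiles)
  need <- c("kinase", "tool", "percentile")
  abort_if(!all(need %in% names(df)), "tool_percentiles needs columns ",
           paste(need, collapse = ", "))
  abort_if(any(df$percentile <= 0 | df$percentile > 1),
           "percentiles must lie in (0, 1]")
  if (!is.null(alias_table)) {
    abort_if(!all(c("alias", "symbol") %in% names(alias_table)),
             "alias_table needs columns alias, symbol")
    hit <- match(df$kinase, alias_table$alias)
    df$kinase <- ifelse(is.na(hit), df$kinase, alias_table$symbol[hit])
  }
  key <- paste(df$kinase, df$tool)
  if (anyDuplicated(key)) {
    message("alias collision(s) within a tool; keeping the better percentile")
    df <- df[order(key, -df$percentile), ]
    df <- df[!duplicated(paste(df$kinase, df$tool)), ]
  }
  tools_seen <- unique(df$tool)
  kinases <- unique(df$kinase)
  pct <- matrix(NA_real_, length(kinases), length(tools_seen),
                dimnames = list(kinases, tools_seen))
  pct[cbind(match(df$kinase, kinases), match(df$tool, tools_seen))] <-
    df$percentile
  n_tools <- rowSums(!is.na(pct))
  mean_p <- rowMeans(pct, na.rm = TRUE)
  med_p <- apply(pct, 1, median, na.rm = TRUE)
  selected <- n_tools >= min_tools & mean_p >= min_mean_percentile
  qb <- cut(mean_p, breaks = c(0, 0.25, 0.5, 0.75, 1),
            labels = c("Q1", "Q2", "Q3", "Q4"),
            right = FALSE, include.lowest = TRUE)
  qb[mean_p == 1] <- "Q4"
  out <- data.frame(kinase = kinases, pct,
                    n_tools = n_tools, mean_percentile = mean_p,
                    median_percentile = med_p, selected = selected,
                    quartile_bin = as.character(qb),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  names(out)[1 + seq_along(tools_seen)] <- paste0("pct_", tools_seen)
  out <- out[order(-out$mean_percentile, out$kinase), ]
  rownames(out) <- NULL
  structure(out, class = c("harmonized_kinase", "data.frame"),
            min_tools = min_tools, min_mean_percentile = min_mean_percentile)
}

#' Selected kinases of a harmonized table
#' @param harmonized a `harmonized_kinase` data.frame
#' @return character vector
#' @export
selected_kinases <- function(harmonized) {
  harmonized$kinase[harmonized$selected]
}

#' Overlap of selected kinases between two comparisons
#'
#' Partitions the union of two selected-kinase sets into kinases selected in
#' both comparisons and kinases unique to each; the three sets are pairwise
#' disjoint and their union is all selected kinases.
#'
#' @param selected_a,selected_b character vectors (or `harmonized_kinase`
#'   tables, from which the selected set is taken)
#' @return an `overlap_sets` list: `common`, `only_a`, `only_b`
#' @export
overlap <- function(selected_a, selected_b) {
  if (inherits(selected_a, "harmonized_kinase"))
    selected_a <- selected_kinases(selected_a)
  if (inherits(selected_b, "harmonized_kinase"))
    selected_b <- selected_kinases(selected_b)
  a <- unique(as.character(selected_a))
  b <- unique(as.character(selected_b))
  structure(list(common = sort(intersect(a, b)),
                 only_a = sort(setdiff(a, b)),
                 only_b = sort(setdiff(b, a))),
            class = "overlap_sets")
}

#' @export
print.overlap_sets <- function(x, ...) {
  cat(sprintf("common: %d | only A: %d | only B: %d\n",
              length(x$common), length(x$only_a), length(x$only_b)))
  invisible(x)
}
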