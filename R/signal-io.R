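## Tabular IO with strict validation. Canonical dialect is TSV with a header
## row; comma-separated input is accepted via `sep = ","`. All validators
## reject malformed input (naming offending rows/keys) rather than coerce.

read_delim_strict <- function(path, required, sep = "\t") {
  abort_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL)
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0,
           basename(path), ": missing required column(s): ",
           paste(missing, collapse = ", "))
  df
}

check_numeric_column <- function(df, col, path, nonnegative = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val))
  abort_if(length(bad) > 0,
           basename(path), ": non-numeric ", col, " on data row(s) ",
           paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
  if (nonnegative) {
    neg <- which(val < 0)
    abort_if(length(neg) > 0,
             basename(path), ": negative ", col, " on data row(s) ",
             paste(head(neg, 5), collapse = ", "))
  }
  val
}

#' Validate/construct an exposure series
#'
#' An exposure series holds one raw fluorescence intensity per
#' (peptide, group, chip, exposure time); it is the pipeline's entry point.
#'
#' @param df data.frame with columns `peptide_id`, `group`, `chip`,
#'   `exposure_ms`, `intensity`
#' @return the validated data.frame, classed `exposure_series`
#' @export
as_exposure_series <- function(df) {
  need <- c("peptide_id", "group", "chip", "exposure_ms", "intensity")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           "exposure series lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  abort_if(!is.numeric(df$exposure_ms) || any(df$exposure_ms <= 0),
           "exposure_ms must be positive numbers")
  abort_if(!is.numeric(df$intensity) || any(is.na(df$intensity)),
           "intensity must be numeric and non-missing")
  key <- paste(df$peptide_id, df$group, df$chip, df$exposure_ms)
  dup <- which(duplicated(key))
  abort_if(length(dup) > 0,
           "duplicate (peptide, group, chip, exposure) key(s): ",
           paste(head(unique(key[dup]), 3), collapse = "; "))
  n_exp <- table(paste(df$peptide_id, df$group, df$chip))
  abort_if(any(n_exp < 2),
           "every (peptide, sample) needs >= 2 exposure times; offender(s): ",
           paste(head(names(n_exp)[n_exp < 2], 3), collapse = "; "))
  rownames(df) <- NULL
  structure(df, class = c("exposure_series", "data.frame"))
}

#' Read an exposure series table
#'
#' @param path delimited file with header columns `peptide_id`, `group`,
#'   `chip`, `exposure_ms`, `intensity`
#' @param sep field separator (tab by default)
#' @param rename optional named character vector mapping file column names to
#'   the canonical schema, e.g. `c(Peptide = "peptide_id")`
#' @return an `exposure_series`
#' @export
read_exposure_series <- function(path, sep = "\t", rename = NULL) {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL)
  if (!is.null(rename)) {
    hit <- names(df) %in% names(rename)
    names(df)[hit] <- rename[names(df)[hit]]
  }
  need <- c("peptide_id", "group", "chip", "exposure_ms", "intensity")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           basename(path), ": missing required column(s): ",
           paste(missing, collapse = ", "))
  df$exposure_ms <- check_numeric_column(df, "exposure_ms", path)
  df$intensity <- check_numeric_column(df, "intensity", path, nonnegative = TRUE)
  as_exposure_series(df)
}

#' Validate/construct a kinase-to-peptide map
#' @param df data.frame with columns `kinase`, `peptide_id`
#' @return classed `kinase_peptide_map` data.frame with unique pairs
#' @export
as_kinase_map <- function(df) {
  need <- c("kinase", "peptide_id")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           "kinase map lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  key <- paste(df$kinase, df$peptide_id)
  dup <- which(duplicated(key))
  abort_if(length(dup) > 0, "duplicate (kinase, peptide) pair(s): ",
           paste(head(unique(key[dup]), 3), collapse = "; "))
  rownames(df) <- NULL
  structure(df, class = c("kinase_peptide_map", "data.frame"))
}

#' Read a kinase-to-peptide map table
#' @inheritParams read_exposure_series
#' @return a `kinase_peptide_map`
#' @export
read_kinase_map <- function(path, sep = "\t") {
  as_kinase_map(read_delim_strict(path, c("kinase", "peptide_id"), sep))
}

#' Validate/construct external tool scores
#'
#' Kinase rankings produced outside this package (e.g. a vendor scoring
#' engine's final scores, or web-service enrichment ranks) enter the
#' harmonization step as score tables. `score_direction` is explicit because
#' some tools rank best-first (rank 1 = best, lower is better) while others
#' score best-highest.
#'
#' @param df data.frame with columns `kinase`, `tool`, `score`,
#'   `score_direction` (each `"higher_is_better"` or `"lower_is_better"`)
#' @return classed `tool_scores` data.frame
#' @export
as_tool_scores <- function(df) {
  need <- c("kinase", "tool", "score", "score_direction")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           "tool scores lack column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  abort_if(!is.numeric(df$score) || any(is.na(df$score)),
           "score must be numeric and non-missing")
  bad <- !df$score_direction %in% c("higher_is_better", "lower_is_better")
  abort_if(any(bad), "invalid score_direction value(s): ",
           paste(unique(df$score_direction[bad]), collapse = ", "))
  key <- paste(df$kinase, df$tool)
  dup <- which(duplicated(key))
  abort_if(length(dup) > 0, "duplicate (kinase, tool) pair(s): ",
           paste(head(unique(key[dup]), 3), collapse = "; "))
  rownames(df) <- NULL
  structure(df, class = c("tool_scores", "data.frame"))
}

#' Read an external tool score table
#' @inheritParams read_exposure_series
#' @return a `tool_scores` data.frame
#' @export
read_tool_scores <- function(path, sep = "\t") {
  df <- read_delim_strict(path, c("kinase", "tool", "score", "score_direction"),
                          sep)
  df$score <- check_numeric_column(df, "score", path)
  as_tool_scores(df)
}

#' Validate/construct a sample design table
#' @param df data.frame with columns `sample_id`, `group`, `chip`
#' @return classed `design` data.frame
#' @export
as_design <- function(df) {
  need <- c("sample_id", "group", "chip")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           "design lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  dup <- which(duplicated(df$sample_id))
  abort_if(length(dup) > 0, "duplicate sample_id(s): ",
           paste(unique(df$sample_id[dup]), collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("design", "data.frame"))
}

#' Read a design table
#' @inheritParams read_exposure_series
#' @return a `design` data.frame
#' @export
read_design <- function(path, sep = "\t") {
  as_design(read_delim_strict(path, c("sample_id", "group", "chip"), sep))
}

#' Derive the sample design implied by an exposure series
#'
#' One sample per (group, chip) well; `sample_id` is `group_chip`.
#'
#' @param series an `exposure_series`
#' @return a `design` data.frame
#' @export
design_from_series <- function(series) {
  u <- unique(as.data.frame(series)[c("group", "chip")])
  u <- u[order(match(u$group, unique(series$group)), u$chip), ]
  as_design(data.frame(sample_id = sample_id(u$group, u$chip),
                       group = u$group, chip = u$chip,
                       stringsAsFactors = FALSE))
}

#' Write any pipeline table as TSV
#'
#' Writers and readers are symmetric: writing an object and reading it back
#' with the matching reader reproduces it.
#'
#' @param obj data.frame (possibly classed)
#' @param path output file
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_table <- function(obj, path, sep = "\t") {
  utils::write.table(as.data.frame(obj), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
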