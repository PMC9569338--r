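`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Sample identifier for a (group, chip) well
#'
#' One sample is loaded per (group, chip) well, so the pair identifies a
#' sample uniquely; the label is used as the column name of signal matrices.
#'
#' @param group group label(s)
#' @param chip chip label(s)
#' @return character vector of sample ids
#' @export
sample_id <- function(group, chip) paste(group, chip, sep = "_")

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
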