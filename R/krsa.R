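#' Random-resampling upstream-kinase enrichment scores
#'
#' Scores each kinase (family) by how over-represented its mapped reporter
#' peptides are in a differential peptide set, relative to a resampling null:
#' for each of `iterations` draws, `|differential|` peptides are sampled
#' uniformly without replacement from the QC-passed universe and per-kinase
#' hit counts are recorded. The score is the standardized excess
#' `z = (observed - null_mean) / null_sd`.
#'
#' As `iterations` grows the null moments converge to those of the
#' hypergeometric distribution: mean `n*m/N` and sd
#' `sqrt(n * (m/N) * (1 - m/N) * (N - n) / (N - 1))`, where `N` is the
#' universe size, `m` the kinase's mapped peptides in the universe and `n`
#' the differential set size.
#'
#' Degenerate kinases (mapped to none or all of the universe) have a zero
#' null sd; their `z` is reported as `NA` with a `note`, never as infinity.
#'
#' @param differential_peptides character vector, subset of `universe`
#' @param universe character vector of QC-passed peptides the differential
#'   set was drawn from
#' @param map a `kinase_peptide_map`; peptides outside the universe are
#'   ignored (with a warning when a kinase has no in-universe peptide)
#' @param iterations number of resampling draws (>= 100)
#' @param seed integer RNG seed (resampling is deterministic given it)
#' @return a `krsa_result` data.frame sorted by decreasing `z`: `kinase`,
#'   `observed`, `mapped` (in-universe mapped peptides), `null_mean`,
#'   `null_sd`, `z`, `note`, `iterations`, `seed`
#' @export
#' @examples
#' map <- data.frame(kinase = rep(c("A", "B"), each = 3),
#'                   peptide_id = c("p1", "p2", "p3", "p4", "p5", "p6"))
#' krsa_score(c("p1", "p2"), paste0("p", 1:10), map, iterations = 500, seed = 1)
krsa_score <- function(differential_peptides, universe, map,
                       iterations = 2000, seed = 1L) {
  map <- as_kinase_map(map)
  # canonicalize the universe so results are invariant to input order
  universe <- sort(unique(as.character(universe)))
  differential_peptides <- unique(as.character(differential_peptides))
  abort_if(iterations < 100, "iterations must be >= 100")
  extra <- setdiff(differential_peptides, universe)
  abort_if(length(extra) > 0,
           "differential peptides outside the universe: ",
           paste(head(extra, 3), collapse = ", "))
  N <- length(universe)
  n <- length(differential_peptides)
  abort_if(n == 0, "empty differential set")
  kinases <- unique(map$kinase)
  in_univ <- map$peptide_id %in% universe
  pep_sets <- split(match(map$peptide_id[in_univ], universe),
                    factor(map$kinase[in_univ], levels = kinases))
  m <- lengths(pep_sets)
  if (any(m == 0))
    warning("kinase(s) with no mapped peptide in the universe: ",
            paste(head(kinases[m == 0], 5), collapse = ", "))
  membership <- lapply(pep_sets, function(idx) {
    v <- logical(N); v[idx] <- TRUE; v
  })
  diff_idx <- match(differential_peptides, universe)
  observed <- vapply(membership, function(v) sum(v[diff_idx]), integer(1))

  # resample in chunks: n x chunk index matrix, per-kinase column hit counts
  sums <- numeric(length(kinases))
  sumsq <- numeric(length(kinases))
  with_seed(seed, {
    left <- as.integer(iterations)
    while (left > 0) {
      chunk <- min(left, 10000L)
      idx <- vapply(seq_len(chunk), function(i) sample.int(N, n),
                    integer(n))
      dim(idx) <- c(n, chunk)
      for (k in seq_along(kinases)) {
        hits <- colSums(matrix(membership[[k]][idx], n, chunk))
        sums[k] <- sums[k] + sum(hits)
        sumsq[k] <- sumsq[k] + sum(hits * hits)
      }
      left <- left - chunk
    }
  })
  null_mean <- sums / iterations
  null_var <- pmax(0, sumsq / iterations - null_mean^2) *
    iterations / (iterations - 1)
  null_sd <- sqrt(null_var)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  note <- ifelse(m == 0, "no_mapped_peptides",
                 ifelse(null_sd == 0, "degenerate_null", ""))
  out <- data.frame(kinase = kinases, observed = observed, mapped = unname(m),
                    null_mean = null_mean, null_sd = null_sd, z = z,
                    note = note, iterations = as.integer(iterations),
                    seed = as.integer(seed),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-ifelse(is.na(out$z), -Inf, out$z), out$kinase), ]
  rownames(out) <- NULL
  structure(out, class = c("krsa_result", "data.frame"))
}

#' Direction-split kinase enrichment
#'
#' Runs [krsa_score()] separately on the up- and down-classified peptide sets
#' of a log2 fold-change table, so kinases driving increased and decreased
#' phosphorylation are scored against their own differential sets.
#'
#' @param fc a `log2fc_table` from [log2fc()]
#' @param universe QC-passed peptide universe (defaults to all peptides in
#'   `fc`, which are already QC-filtered in the standard pipeline)
#' @param map a `kinase_peptide_map`
#' @inheritParams krsa_score
#' @return named list with elements `up` and/or `down` (`krsa_result`);
#'   an empty direction is skipped with a warning
#' @export
krsa_direction_split <- function(fc, map, universe = fc$peptide_id,
                                 iterations = 2000, seed = 1L) {
  stopifnot(inherits(fc, "log2fc_table"))
  out <- list()
  for (dir in c("up", "down")) {
    peps <- differential_peptides(fc, dir)
    if (length(peps) == 0) {
      warning("no peptides classified ", dir, "; direction skipped")
      next
    }
    out[[dir]] <- krsa_score(peps, universe, map,
                             iterations = iterations, seed = seed)
  }
  out
}
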