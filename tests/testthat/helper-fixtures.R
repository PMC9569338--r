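# Small in-code fixtures shared across test files.

# compact two-group chip layout for fast tests
tiny_config <- function(...) {
  defaults <- list(n_peptides = 30, n_kinases = 4,
                   peptides_per_kinase = c(3, 6),
                   groups = c("case", "ctrl"), n_chips = 2,
                   n_low_signal = 0, seed = 1L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# slope-signal data.frame straight from per-sample signal values;
# `signals` is a named list sample_id -> numeric vector over peptides
make_slope_df <- function(signals, peptides = NULL, group_of, chip_of) {
  peptides <- peptides %||% paste0("p", seq_along(signals[[1]]))
  do.call(rbind, lapply(names(signals), function(s) {
    data.frame(peptide_id = peptides, group = group_of[[s]],
               chip = chip_of[[s]], slope = signals[[s]] / 100,
               intercept = 0, r_squared = 1,
               signal_at_max_exposure = signals[[s]],
               fit_flag = "ok", signal = signals[[s]],
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# two-group signal matrix built from per-chip case/control signal vectors
two_group_matrix <- function(case_by_chip, ctrl_by_chip, peptides = NULL) {
  chips <- seq_along(case_by_chip)
  sig <- c(setNames(case_by_chip, paste0("case_", chips)),
           setNames(ctrl_by_chip, paste0("ctrl_", chips)))
  group_of <- c(setNames(rep("case", length(chips)), paste0("case_", chips)),
                setNames(rep("ctrl", length(chips)), paste0("ctrl_", chips)))
  chip_of <- c(setNames(chips, paste0("case_", chips)),
               setNames(chips, paste0("ctrl_", chips)))
  build_signal_matrix(make_slope_df(sig, peptides, group_of, chip_of))
}

# exhaustive-enumeration oracle for the two-sided exact signed-rank p-value
# (independent of stats::wilcox.test); n <= 14, no tied |d|, zeros dropped
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w >= obs), mean(w <= obs)))
}

# hypergeometric null moments for drawing n of N with m marked
hyper_moments <- function(N, m, n) {
  mu <- n * m / N
  list(mean = mu,
       sd = sqrt(n * (m / N) * (1 - m / N) * (N - n) / (N - 1)))
}
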