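## Validation experiments: self-contained checks of the resampling engine and
## of end-to-end kinase recovery on the synthetic world. Used by the test
## suite and the acceptance report.

#' Compare resampling null moments with the hypergeometric closed form
#'
#' Drawing n peptides without replacement from a universe of N, with m mapped
#' to a kinase, the hit count is hypergeometric; the resampling null moments
#' must converge to its mean and sd. Returns both alongside their relative
#' errors.
#'
#' @param N universe size
#' @param m kinase's mapped peptides
#' @param n differential set size
#' @param iterations resampling iterations
#' @param seed RNG seed
#' @return list: `null_mean`, `null_sd`, `expected_mean`, `expected_sd`,
#'   `rel_err_mean`, `rel_err_sd`
#' @export
benchmark_krsa_oracle <- function(N = 100, m = 10, n = 20,
                                  iterations = 200000, seed = 1L) {
  universe <- sprintf("p%03d", seq_len(N))
  map <- data.frame(kinase = "K", peptide_id = universe[seq_len(m)])
  res <- krsa_score(universe[seq_len(n)], universe, map,
                    iterations = iterations, seed = seed)
  exp_mean <- n * m / N
  exp_sd <- sqrt(n * (m / N) * (1 - m / N) * (N - n) / (N - 1))
  list(null_mean = res$null_mean, null_sd = res$null_sd,
       expected_mean = exp_mean, expected_sd = exp_sd,
       rel_err_mean = abs(res$null_mean - exp_mean) / exp_mean,
       rel_err_sd = abs(res$null_sd - exp_sd) / exp_sd)
}

#' Calibration of kinase z scores under random differential sets
#'
#' Draws `n_nulls` random "differential" sets from a fixed peptide universe
#' and scores a fixed kinase map against each; under this null the pooled z
#' scores should have mean about 0 and sd about 1.
#'
#' @param n_nulls number of simulated null differential sets
#' @param n_peptides universe size
#' @param n_kinases kinases in the map
#' @param n_differential size of each random differential set
#' @param iterations resampling iterations per null
#' @param seed RNG seed
#' @return list: `z` (vector over nulls x kinases), `mean_z`, `sd_z`
#' @export
benchmark_null_calibration <- function(n_nulls = 200, n_peptides = 144,
                                       n_kinases = 20, n_differential = 48,
                                       iterations = 1000, seed = 1L) {
  cfg <- simulation_config(n_peptides = n_peptides, n_kinases = n_kinases,
                           n_low_signal = 0, seed = seed)
  map <- generate_kinase_map(cfg)
  universe <- peptide_ids(cfg)
  z <- unlist(lapply(seq_len(n_nulls), function(i) {
    diff <- with_seed(seed + 7919 * i,
                      sample(universe, n_differential))
    krsa_score(diff, universe, map, iterations = iterations,
               seed = seed + i)$z
  }))
  z <- z[!is.na(z)]
  list(z = z, mean_z = mean(z), sd_z = sd(z))
}

#' End-to-end recovery of injected kinases on synthetic chips
#'
#' For each seed, simulates a two-group chip experiment (144 peptides, 3
#' replicate chips, multiplicative noise) in which `n_injected` kinases are
#' elevated in the case group, runs the full pipeline (QC, within-chip log2
#' fold-changes at the 0.15 cutoff, resampling kinase enrichment,
#' percentile-rank harmonization with the KRSA percentiles duplicated as a
#' stand-in second tool and the >=2-tool / >=0.75-mean selection rule), and
#' records whether every injected kinase was selected and what fraction of
#' non-injected kinases were.
#'
#' @param n_seeds number of simulated experiments
#' @param multiplier activity multiplier of injected kinases
#' @param noise_cv generator noise level
#' @param n_kinases total kinases in the map
#' @param n_injected elevated kinases in the case group
#' @param n_peptides,n_chips chip geometry
#' @param iterations resampling iterations
#' @param base_seed seeds are `base_seed + 1:n_seeds`
#' @return list: `all_recovered` (logical per seed), `false_rate` (per seed),
#'   `recovery_rate`, `mean_false_rate`
#' @export
benchmark_recovery <- function(n_seeds = 50, multiplier = 1.5,
                               noise_cv = 0.05, n_kinases = 20,
                               n_injected = 5, n_peptides = 144, n_chips = 3,
                               iterations = 2000, base_seed = 0L) {
  injected <- sprintf("KIN_%02d", seq_len(n_injected))
  per_seed <- lapply(seq_len(n_seeds), function(i) {
    s <- base_seed + i
    cfg <- simulation_config(
      n_peptides = n_peptides, n_kinases = n_kinases,
      groups = c("case", "ctrl"), n_chips = n_chips, noise_cv = noise_cv,
      seed = s,
      active_kinases = list(case = setNames(rep(multiplier, n_injected),
                                            injected)))
    map <- generate_kinase_map(cfg)
    sim <- simulate_exposure_series(cfg, map)
    res <- analyze_comparison(sim$series, "case", "ctrl", map = map,
                              iterations = iterations, seed = s)
    pct <- res$krsa_percentiles
    harm <- harmonize(rbind(pct, duplicate_tool(pct, "STANDIN")))
    sel <- selected_kinases(harm)
    list(all = all(injected %in% sel),
         false_rate = length(setdiff(sel, injected)) /
           (n_kinases - n_injected))
  })
  all_recovered <- vapply(per_seed, `[[`, logical(1), "all")
  false_rate <- vapply(per_seed, `[[`, numeric(1), "false_rate")
  list(all_recovered = all_recovered, false_rate = false_rate,
       recovery_rate = mean(all_recovered),
       mean_false_rate = mean(false_rate))
}
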