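#' Simulation configuration for synthetic chip data
#'
#' Describes a synthetic serine/threonine peptide-array experiment: a grid of
#' reporter peptides read at several camera exposure times, with one sample
#' per (group, chip) well and group-specific upstream-kinase activity driving
#' the phosphorylation rate of mapped peptides.
#'
#' The default layout mirrors the standard STK chip design: 144 reporter
#' peptides, four sample groups (three subcellular fractions plus total
#' homogenate) run in triplicate on three chips, and five exposure times
#' (10, 20, 50, 100, 200 ms).
#'
#' @param n_peptides number of reporter peptides on the array
#' @param n_kinases number of upstream kinases in the substrate map
#' @param peptides_per_kinase length-2 integer range; each kinase is mapped to
#'   a peptide set whose size is drawn uniformly from this range
#' @param groups character vector of sample group labels
#' @param n_chips number of replicate chips (each group appears once per chip)
#' @param exposure_times camera exposure times in milliseconds, strictly
#'   increasing and positive
#' @param active_kinases named list: `group -> c(kinase = multiplier)`.
#'   A multiplier m scales the phosphorylation slope of the kinase's mapped
#'   peptides in that group; m = 1 is baseline, m >= 0.
#' @param baseline_slope phosphorylation rate (intensity per ms) of a peptide
#'   mapped to no active kinase
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   intensity noise (mean 1)
#' @param intercept intensity offset at zero exposure
#' @param n_low_signal number of peptides generated with a near-zero slope, to
#'   exercise the low-signal QC filter (the last `n_low_signal` peptide ids)
#' @param low_signal_slope the near-zero slope used for those peptides
#' @param seed integer RNG seed; all generator randomness derives from it
#' @return an object of class `simulation_config` (a validated list)
#' @export
#' @examples
#' cfg <- simulation_config(n_kinases = 10, seed = 1)
#' cfg$n_peptides
simulation_config <- function(n_peptides = 144,
                              n_kinases = 20,
                              peptides_per_kinase = c(5, 15),
                              groups = c("nuclear", "cytosolic",
                                         "synaptosomal", "total"),
                              n_chips = 3,
                              exposure_times = c(10, 20, 50, 100, 200),
                              active_kinases = list(),
                              baseline_slope = 0.5,
                              noise_cv = 0.05,
                              intercept = 0,
                              n_low_signal = 3,
                              low_signal_slope = 0.005,
                              seed = 1L) {
  abort_if(n_peptides < 1 || n_kinases < 1, "need at least one peptide and one kinase")
  abort_if(length(peptides_per_kinase) != 2 || any(peptides_per_kinase < 1),
           "peptides_per_kinase must be a range of two counts >= 1")
  abort_if(peptides_per_kinase[1] > peptides_per_kinase[2],
           "peptides_per_kinase range is reversed")
  abort_if(peptides_per_kinase[2] > n_peptides,
           "peptides_per_kinase range exceeds n_peptides")
  abort_if(length(groups) < 1 || anyDuplicated(groups) > 0,
           "groups must be distinct labels")
  abort_if(n_chips < 1, "need at least one chip")
  abort_if(any(exposure_times <= 0) || is.unsorted(exposure_times, strictly = TRUE),
           "exposure_times must be strictly positive and strictly increasing")
  abort_if(noise_cv < 0, "noise_cv must be >= 0")
  abort_if(baseline_slope < 0 || low_signal_slope < 0, "slopes must be >= 0")
  abort_if(n_low_signal < 0 || n_low_signal > n_peptides,
           "n_low_signal out of range")
  for (g in names(active_kinases)) {
    abort_if(!g %in% groups, "active_kinases names a group not in `groups`: ", g)
    mult <- active_kinases[[g]]
    abort_if(is.null(names(mult)) || any(!nzchar(names(mult))),
             "active_kinases[[", g, "]] must be a named multiplier vector")
    abort_if(any(mult < 0), "activity multipliers must be >= 0")
  }
  structure(
    list(n_peptides = as.integer(n_peptides),
         n_kinases = as.integer(n_kinases),
         peptides_per_kinase = as.integer(peptides_per_kinase),
         groups = as.character(groups),
         n_chips = as.integer(n_chips),
         exposure_times = as.numeric(exposure_times),
         active_kinases = active_kinases,
         baseline_slope = baseline_slope,
         noise_cv = noise_cv,
         intercept = intercept,
         n_low_signal = as.integer(n_low_signal),
         low_signal_slope = low_signal_slope,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Peptide identifiers of a simulated array
#' @param config a [simulation_config()]
#' @return character vector of peptide ids
#' @export
peptide_ids <- function(config) {
  sprintf("pep_%03d", seq_len(config$n_peptides))
}

kinase_ids <- function(config) {
  sprintf("KIN_%02d", seq_len(config$n_kinases))
}

#' Generate a random kinase-to-peptide substrate map
#'
#' Each kinase is assigned a peptide set drawn without replacement from the
#' array; set sizes are uniform over `config$peptides_per_kinase`. Peptides
#' may be shared between kinases, emulating the many-to-many structure of
#' kinase-substrate mapping databases.
#'
#' @param config a [simulation_config()]
#' @return a `kinase_peptide_map`: data.frame with columns `kinase`,
#'   `peptide_id`, unique pairs
#' @export
generate_kinase_map <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  peps <- peptide_ids(config)
  kin <- kinase_ids(config)
  rng <- config$peptides_per_kinase
  map <- with_seed(config$seed, {
    sets <- lapply(kin, function(k) {
      size <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1L)
      sort(sample(peps, size))
    })
    data.frame(kinase = rep(kin, lengths(sets)),
               peptide_id = unlist(sets),
               stringsAsFactors = FALSE)
  })
  as_kinase_map(map)
}

# expected noise-free slope per (peptide, group): baseline scaled by the
# additively combined activity excesses of mapped active kinases
truth_slopes <- function(config, map) {
  peps <- peptide_ids(config)
  grid <- expand.grid(peptide_id = peps, group = config$groups,
                      stringsAsFactors = FALSE)
  grid$expected_slope <- config$baseline_slope
  for (g in names(config$active_kinases)) {
    mult <- config$active_kinases[[g]]
    missing <- setdiff(names(mult), unique(map$kinase))
    abort_if(length(missing) > 0,
             "active kinases absent from the map: ",
             paste(missing, collapse = ", "))
    excess <- setNames(rep(0, length(peps)), peps)
    for (k in names(mult)) {
      mapped <- map$peptide_id[map$kinase == k]
      excess[mapped] <- excess[mapped] + (mult[[k]] - 1)
    }
    sel <- grid$group == g
    grid$expected_slope[sel] <-
      pmax(0, config$baseline_slope * (1 + excess[grid$peptide_id[sel]]))
  }
  if (config$n_low_signal > 0) {
    low <- peps[seq(config$n_peptides - config$n_low_signal + 1,
                    config$n_peptides)]
    grid$expected_slope[grid$peptide_id %in% low] <- config$low_signal_slope
  }
  grid
}

#' Simulate a multi-exposure peptide-array intensity series
#'
#' Signal model: `intensity(p, g, c, t) = (intercept + slope_pg * t) * eps`
#' where `slope_pg` is the baseline phosphorylation rate scaled by the
#' additively combined activity excesses of kinases mapped to peptide `p`
#' and active in group `g`, and `eps` is multiplicative log-normal noise
#' with mean 1 and coefficient of variation `config$noise_cv`. Intensities
#' are floored at zero. One sample is generated per (group, chip) well.
#'
#' @param config a [simulation_config()]
#' @param map a kinase-to-peptide map, typically [generate_kinase_map()]
#' @return list with components
#'   * `series`: an `exposure_series` data.frame (`peptide_id`, `group`,
#'     `chip`, `exposure_ms`, `intensity`)
#'   * `truth`: a `synthetic_truth` list — `slopes` (noise-free slope per
#'     peptide and group), `active` (elevated kinases per group with
#'     multipliers), `low_signal_peptides`, `seed`
#' @export
#' @examples
#' cfg <- simulation_config(n_kinases = 5, noise_cv = 0, seed = 42)
#' sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
#' head(sim$series)
simulate_exposure_series <- function(config, map) {
  stopifnot(inherits(config, "simulation_config"))
  map <- as_kinase_map(map)
  slopes <- truth_slopes(config, map)
  grid <- expand.grid(peptide_id = peptide_ids(config),
                      group = config$groups,
                      chip = seq_len(config$n_chips),
                      exposure_ms = config$exposure_times,
                      stringsAsFactors = FALSE)
  key <- match(paste(grid$peptide_id, grid$group),
               paste(slopes$peptide_id, slopes$group))
  mu <- config$intercept + slopes$expected_slope[key] * grid$exposure_ms
  eps <- if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    with_seed(config$seed, rlnorm(nrow(grid), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog))
  } else 1
  grid$intensity <- pmax(0, mu * eps)
  active <- do.call(rbind, lapply(names(config$active_kinases), function(g) {
    mult <- config$active_kinases[[g]]
    data.frame(group = g, kinase = names(mult), multiplier = unname(mult),
               stringsAsFactors = FALSE)
  }))
  if (is.null(active))
    active <- data.frame(group = character(), kinase = character(),
                         multiplier = numeric(), stringsAsFactors = FALSE)
  low <- if (config$n_low_signal > 0)
    peptide_ids(config)[seq(config$n_peptides - config$n_low_signal + 1,
                            config$n_peptides)]
  else character()
  truth <- structure(list(slopes = slopes, active = active,
                          low_signal_peptides = low, seed = config$seed),
                     class = "synthetic_truth")
  list(series = as_exposure_series(grid), truth = truth)
}

#' Read a simulation configuration from a JSON file
#'
#' Keys are the argument names of [simulation_config()]; `active_kinases` is
#' an object of objects (`group -> {kinase: multiplier}`).
#'
#' @param path JSON file
#' @return a `simulation_config`
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  abort_if(length(unknown) > 0,
           "unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$active_kinases))
    raw$active_kinases <- lapply(raw$active_kinases, unlist)
  do.call(simulation_config, raw)
}
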