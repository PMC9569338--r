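test_that("config validation rejects invalid worlds", {
  expect_error(simulation_config(exposure_times = c(10, 10, 50)),
               "strictly")
  expect_error(simulation_config(exposure_times = c(-10, 20)), "strictly")
  expect_error(simulation_config(noise_cv = -0.1), "noise_cv")
  expect_error(simulation_config(peptides_per_kinase = c(5, 200)),
               "exceeds n_peptides")
  expect_error(simulation_config(
    active_kinases = list(nuclear = c(K1 = -2))), "multipliers")
  expect_error(simulation_config(
    active_kinases = list(elsewhere = c(K1 = 2))), "not in")
  # active kinase missing from the map is caught at simulation time
  cfg <- tiny_config(active_kinases = list(case = c(GHOST = 2)))
  expect_error(simulate_exposure_series(cfg, generate_kinase_map(cfg)),
               "absent from the map")
})

test_that("kinase map generation: coverage, sizes and determinism", {
  # one kinase covering the whole array
  cfg1 <- simulation_config(n_kinases = 1,
                            peptides_per_kinase = c(144, 144), seed = 3)
  map1 <- generate_kinase_map(cfg1)
  expect_setequal(map1$peptide_id, peptide_ids(cfg1))
  expect_equal(nrow(map1), 144)

  cfg <- simulation_config(n_kinases = 10, peptides_per_kinase = c(5, 15),
                           seed = 7)
  map <- generate_kinase_map(cfg)
  expect_identical(map, generate_kinase_map(cfg))
  sizes <- table(map$kinase)
  expect_length(sizes, 10)
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_true(all(map$peptide_id %in% peptide_ids(cfg)))
})

test_that("noise-free signal model is exactly linear with additive kinase effects", {
  map <- as_kinase_map(data.frame(
    kinase = c("KA", "KB", "KB"),
    peptide_id = c("pep_001", "pep_002", "pep_003")))
  cfg <- simulation_config(n_peptides = 3, n_kinases = 2,
                           peptides_per_kinase = c(1, 3),
                           groups = c("A", "B"), n_chips = 1,
                           active_kinases = list(A = c(KA = 2)),
                           baseline_slope = 1, intercept = 0, noise_cv = 0,
                           n_low_signal = 0, seed = 1)
  sim <- simulate_exposure_series(cfg, map)
  s <- sim$series
  at <- function(p, g, t) s$intensity[s$peptide_id == p & s$group == g &
                                        s$exposure_ms == t]
  expect_equal(at("pep_001", "A", 200), 400)
  expect_equal(at("pep_001", "B", 200), 200)
  expect_equal(at("pep_002", "A", 200), 200) # KB inactive everywhere

  # OLS recovers every truth slope exactly, R^2 = 1 for nonzero slopes
  sl <- fit_slopes(sim$series, scale_factor = 1)
  key <- paste(sim$truth$slopes$peptide_id, sim$truth$slopes$group)
  expect_equal(sl$slope,
               sim$truth$slopes$expected_slope[
                 match(paste(sl$peptide_id, sl$group), key)],
               tolerance = 1e-12)
  expect_true(all(sl$r_squared[sl$slope > 0] == 1))
})

test_that("multiplicative noise has the configured CV (Monte Carlo)", {
  cfg <- simulation_config(n_peptides = 1, n_kinases = 1,
                           peptides_per_kinase = c(1, 1), groups = "g",
                           n_chips = 1000, exposure_times = c(100, 200),
                           baseline_slope = 1, noise_cv = 0.05,
                           n_low_signal = 0, seed = 99)
  sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
  cell <- sim$series$intensity[sim$series$exposure_ms == 200]
  expect_length(cell, 1000)
  cv <- sd(cell) / mean(cell)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
  expect_equal(mean(cell), 200, tolerance = 0.01)
})

test_that("generator is deterministic and truth is reproducible", {
  cfg <- tiny_config(noise_cv = 0.05, seed = 21,
                     active_kinases = list(case = c(KIN_01 = 1.5)))
  map <- generate_kinase_map(cfg)
  a <- simulate_exposure_series(cfg, map)
  b <- simulate_exposure_series(cfg, map)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
})

test_that("null world: per-chip log2FC has median ~0 across peptides", {
  # no active kinases, noise_cv = 0.05, 144 peptides; 100 seeds
  medians <- vapply(1:100, function(s) {
    cfg <- simulation_config(groups = c("A", "B"), n_chips = 3,
                             noise_cv = 0.05, n_low_signal = 0, seed = s)
    sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
    m <- build_signal_matrix(fit_slopes(sim$series))
    fc <- log2fc(m, "A", "B")
    median(unlist(fc[paste0("lfc_", 1:3)])) # per-chip values, all chips
  }, numeric(1))
  expect_lt(abs(mean(medians)), 0.02)
  expect_gte(mean(abs(medians) < 0.02), 0.95)
})

test_that("effect propagation: exclusive peptides carry log2(multiplier) exactly", {
  cfg <- tiny_config(noise_cv = 0, seed = 5,
                     active_kinases = list(case = c(KIN_02 = 2^0.3)))
  map <- generate_kinase_map(cfg)
  sim <- simulate_exposure_series(cfg, map)
  m <- build_signal_matrix(fit_slopes(sim$series))
  fc <- log2fc(m, "case", "ctrl")
  exclusive <- setdiff(map$peptide_id[map$kinase == "KIN_02"],
                       map$peptide_id[map$kinase != "KIN_02"])
  expect_gt(length(exclusive), 0)
  expect_equal(fc$mean_log2fc[match(exclusive, fc$peptide_id)],
               rep(0.3, length(exclusive)), tolerance = 1e-9)
  expect_true(all(fc$classification[match(exclusive, fc$peptide_id)] == "up"))
})

test_that("low-signal peptides are injected with near-zero slope", {
  cfg <- simulation_config(n_low_signal = 3, noise_cv = 0, seed = 2)
  sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
  expect_length(sim$truth$low_signal_peptides, 3)
  tr <- sim$truth$slopes
  expect_true(all(
    tr$expected_slope[tr$peptide_id %in% sim$truth$low_signal_peptides] ==
      cfg$low_signal_slope))
})

test_that("simulation config round-trips through JSON", {
  cfg <- simulation_config(n_kinases = 6, seed = 17,
                           active_kinases = list(nuclear = c(KIN_01 = 1.8)))
  path <- withr::local_tempfile(fileext = ".json")
  cfgl <- unclass(cfg)
  # named multiplier vectors must serialize as JSON objects, not arrays
  cfgl$active_kinases <- lapply(cfgl$active_kinases, as.list)
  jsonlite::write_json(cfgl, path, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_simulation_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(bogus_key = 1), bad, auto_unbox = TRUE)
  expect_error(read_simulation_config(bad), "unknown config key")
})
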