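test_that("log2fc: per-chip values, replicate mean, classification", {
  m <- two_group_matrix(
    case_by_chip = list(c(4, 5), c(4, 5), c(4, 5)),
    ctrl_by_chip = list(c(2, 5), c(2, 5), c(2, 5)))
  fc <- log2fc(m, "case", "ctrl")
  r1 <- fc[fc$peptide_id == "p1", ]
  expect_equal(unlist(r1[paste0("lfc_", 1:3)], use.names = FALSE),
               rep(1, 3))
  expect_equal(r1$mean_log2fc, 1)
  expect_equal(r1$classification, "up")
  # identical signals -> all zero, unchanged
  r2 <- fc[fc$peptide_id == "p2", ]
  expect_equal(r2$mean_log2fc, 0)
  expect_equal(r2$classification, "unchanged")
})

test_that("log2fc mean is the mean of per-chip values; cutoff is honored", {
  m <- two_group_matrix(
    case_by_chip = list(2^0.25 * c(4, 4), 2^0.15 * c(4, 4), 2^0.20 * c(4, 4)),
    ctrl_by_chip = list(c(4, 4), c(4, 4), c(4, 4)))
  fc <- log2fc(m, "case", "ctrl", cutoff = 0.15)
  expect_equal(fc$mean_log2fc[1], mean(c(0.25, 0.15, 0.20)), tolerance = 1e-9)
  expect_equal(fc$classification[1], "up")
  expect_equal(log2fc(m, "case", "ctrl", cutoff = 0.25)$classification[1],
               "unchanged")
})

test_that("log2fc antisymmetry and scale invariance", {
  cfg <- tiny_config(noise_cv = 0.05, n_chips = 3, seed = 23,
                     active_kinases = list(case = c(KIN_01 = 1.6)))
  sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
  sl <- fit_slopes(sim$series)
  m <- build_signal_matrix(sl, floor = 1e-12)
  fwd <- log2fc(m, "case", "ctrl")
  rev <- log2fc(m, "ctrl", "case")
  expect_equal(fwd$mean_log2fc, -rev$mean_log2fc, tolerance = 1e-12)
  expect_equal(fwd$classification == "up", rev$classification == "down")

  scaled <- sim$series
  scaled$intensity <- scaled$intensity * 7
  m7 <- build_signal_matrix(fit_slopes(scaled), floor = 1e-12)
  expect_equal(log2fc(m7, "case", "ctrl")$mean_log2fc, fwd$mean_log2fc,
               tolerance = 1e-9)
})

test_that("chips missing a group are dropped with a warning", {
  sig <- list(case_1 = c(4, 4), ctrl_1 = c(2, 2), case_2 = c(8, 8))
  df <- make_slope_df(sig,
                      group_of = list(case_1 = "case", ctrl_1 = "ctrl",
                                      case_2 = "case"),
                      chip_of = list(case_1 = 1, ctrl_1 = 1, case_2 = 2))
  m <- build_signal_matrix(df)
  expect_warning(fc <- log2fc(m, "case", "ctrl"), "chip.*omitted")
  expect_equal(attr(fc, "chips"), 1)
  expect_error(log2fc(m, "case", "missing"), "absent")
})

test_that("signed-rank test matches exhaustive enumeration (n <= 12)", {
  # independent oracle: enumerate all sign patterns of the rank sum
  set.seed(42)
  for (n in c(8, 10, 12)) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 3)
      while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n), 3)
      ctrl <- abs(rnorm(n)) + 10 # keep both groups above the log2 floor
      m <- two_group_matrix(list(2^d * ctrl), list(ctrl),
                            peptides = paste0("pep", 1:n))
      gt <- global_test(m, c("case", "ctrl"), paired = TRUE)
      expect_equal(gt$p_value, enum_signed_rank_p(d), tolerance = 1e-12)
    }
  }
})

test_that("signed-rank edge rules: all-positive n = 10, ties at zero", {
  d <- seq(0.1, 1, by = 0.1) # all positive, n = 10
  ctrl <- rep(2, 10)
  m <- two_group_matrix(list(2^d * ctrl), list(ctrl),
                        peptides = paste0("pep", 1:10))
  gt <- global_test(m, c("case", "ctrl"), paired = TRUE)
  expect_equal(gt$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(gt$test, "signed_rank")

  # identical paired samples: zero differences dropped, p reported as 1
  m0 <- two_group_matrix(list(c(2, 3, 4)), list(c(2, 3, 4)))
  gt0 <- global_test(m0, c("case", "ctrl"), paired = TRUE)
  expect_equal(gt0$p_value, 1)

  expect_error(global_test(two_group_matrix(list(c(1, 2)), list(c(2, 1))),
                           c("case", "ctrl"), paired = TRUE),
               ">= 3 paired")
})

test_that("rank-sum test holds its nominal type-I error under the null", {
  set.seed(7)
  n <- 20
  rejections <- vapply(1:1000, function(i) {
    m <- two_group_matrix(list(abs(rnorm(n, 10, 2))),
                          list(abs(rnorm(n, 10, 2))),
                          peptides = paste0("pep", 1:n))
    global_test(m, c("case", "ctrl"), paired = FALSE)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("CV report: closed-form cells and simulated generator recovery", {
  sig <- list(s1 = c(10, 9), s2 = c(10, 10), s3 = c(10, 11))
  df <- make_slope_df(sig, group_of = list(s1 = "g", s2 = "g", s3 = "g"),
                      chip_of = list(s1 = 1, s2 = 2, s3 = 3))
  cv <- cv_report(df)
  expect_equal(cv$per_peptide$cv_pct[cv$per_peptide$peptide_id == "p1"], 0)
  expect_equal(cv$per_peptide$cv_pct[cv$per_peptide$peptide_id == "p2"], 10)
  expect_equal(cv$group_medians$median_cv_pct, 5)

  # zero-mean peptide excluded with a warning
  sig0 <- lapply(sig, function(x) c(x, 0))
  df0 <- make_slope_df(sig0, group_of = list(s1 = "g", s2 = "g", s3 = "g"),
                       chip_of = list(s1 = 1, s2 = 2, s3 = 3))
  expect_warning(cv0 <- cv_report(df0), "zero mean")
  expect_false("p3" %in% cv0$per_peptide$peptide_id)

  expect_error(cv_report(make_slope_df(list(s1 = 1:3),
                                       group_of = list(s1 = "g"),
                                       chip_of = list(s1 = 1))),
               ">= 2 chips")

  # generator with noise_cv = 0.05 lands near 5% median CV over 20 seeds
  med <- vapply(1:20, function(s) {
    cfg <- simulation_config(groups = "g", n_chips = 3, noise_cv = 0.05,
                             n_low_signal = 0, seed = 100 + s)
    sim <- simulate_exposure_series(cfg, generate_kinase_map(cfg))
    cv_report(fit_slopes(sim$series))$group_medians$median_cv_pct
  }, numeric(1))
  expect_gt(median(med), 4)
  expect_lt(median(med), 6)
})
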