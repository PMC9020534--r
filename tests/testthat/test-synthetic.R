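test_that("generator is deterministic: same seed and config give identical bytes", {
  cfg <- synthetic_series_config(n_strata = 3, n_waves = 5, noise_sd = 0.1,
                                 dhs_rounding = TRUE, seed = 99)
  s1 <- generate_series(cfg)
  s2 <- generate_series(cfg)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_survey_table(s1$surveys, f1)
  write_survey_table(s2$surveys, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed perturbs the noisy observables
  s3 <- generate_series(synthetic_series_config(n_strata = 3, n_waves = 5,
                                                noise_sd = 0.1,
                                                dhs_rounding = TRUE, seed = 100))
  expect_false(identical(s1$surveys$tfr, s3$surveys$tfr))
})

test_that("noiseless unrounded series invert to the exact truth", {
  for (seed in c(1, 7, 123)) {
    sim <- generate_series(synthetic_series_config(
      n_strata = 2, n_waves = 5, noise_sd = 0, seed = seed))
    rec <- complete_records(sim$surveys)
    expect_equal(rec$ip, sim$truth$ip, tolerance = 1e-12)
    expect_equal(rec$unwanted_tfr, sim$truth$fu, tolerance = 1e-12)
    expect_equal(rec$natural_tfr, sim$truth$fn, tolerance = 1e-12)
  }
})

test_that("derive mode solves a self-consistent forward model", {
  sim <- generate_series(synthetic_series_config(
    fn_base = "derive", u_trajectory = c(0.35, 0.6),
    ip_trajectory = c(0.55, 0.9), noise_sd = 0, seed = 3))
  # natural fertility consistent with prevalence through the contraception index
  expect_equal(sim$truth$fn, sim$truth$fo / (1 - 1.02 * sim$truth$u),
               tolerance = 1e-12)
  # and the observables still invert exactly
  rec <- complete_records(sim$surveys)
  expect_equal(rec$ip, sim$truth$ip, tolerance = 1e-12)
  # infeasible when prevalence implies more reduction than the index allows
  # (C <= 1 - Ip at the first wave)
  expect_error(generate_series(synthetic_series_config(
    fn_base = "derive", u_trajectory = c(0.5, 0.6),
    ip_trajectory = c(0.3, 0.9), seed = 3)), class = "CONFIG_INVALID")
})

test_that("a steep implementation rise dominates the recovered decomposition", {
  # trajectory shaped like the fastest-declining national series: wanted
  # fertility 4.4 -> 3.3 while the index climbs 0.43 -> 0.84
  sim <- generate_series(synthetic_series_config(
    n_waves = 4, year_range = c(2005, 2015),
    fw_trajectory = c(4.4, 3.3), ip_trajectory = c(0.43, 0.84),
    fn_base = c(7.4, 9.2), noise_sd = 0, seed = 12))
  rec <- complete_records(sim$surveys)
  r <- decompose_series(rec)
  expect_gt(r$pct_ip, r$pct_fw)
  expect_gt(r$pct_ip, 50)
})

test_that("rounding sensitivity brackets the index by corner enumeration", {
  rec <- data.frame(tfr = 3.9, wanted_tfr = 3.1, natural_tfr = 9.6)
  iv <- rounding_sensitivity(rec)
  ip_point <- implementation_index(9.6, 3.9, 3.1)
  expect_lte(iv[["lower"]], 0.87)
  expect_gte(iv[["upper"]], ip_point)
  expect_lte(iv[["lower"]], ip_point)

  # degenerate step collapses to the point value
  iv0 <- rounding_sensitivity(rec, grid_step = 0)
  expect_equal(unname(iv0), rep(ip_point, 2))

  # intervals nest monotonically in the step
  iv_wide <- rounding_sensitivity(rec, grid_step = 0.2)
  expect_lte(iv_wide[["lower"]], iv[["lower"]])
  expect_gte(iv_wide[["upper"]], iv[["upper"]])

  # corners really are extremal: dense random interior perturbations stay inside
  withr::with_seed(8, {
    h <- 0.05
    fo <- 3.9 + runif(2000, -h, h)
    fw <- 3.1 + runif(2000, -h, h)
    fn <- 9.6 + runif(2000, -h, h)
    ips <- (fn - fo) / (fn - fw)
    expect_true(all(ips >= iv[["lower"]] - 1e-12 & ips <= iv[["upper"]] + 1e-12))
  })
})

test_that("with table rounding alone, recovered indices stay inside the sensitivity interval", {
  ok <- vapply(1:300, function(seed) {
    sim <- generate_series(synthetic_series_config(
      n_waves = 3, noise_sd = 0, dhs_rounding = TRUE, seed = seed))
    rec <- complete_records(sim$surveys)
    all(vapply(seq_len(nrow(rec)), function(i) {
      iv <- rounding_sensitivity(rec[i, ])
      sim$truth$ip[i] >= iv[["lower"]] - 1e-12 &&
        sim$truth$ip[i] <= iv[["upper"]] + 1e-12
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("pathological battery triggers each record-level diagnostic exactly once", {
  rec <- complete_records(pathological_records())
  d <- diagnostics(rec)
  counts <- table(d$code)
  for (code in c("IP_BELOW_ZERO", "IP_ABOVE_ONE", "FN_LE_FW",
                 "C_NONPOSITIVE", "FN_U_INCONSISTENT")) {
    expect_equal(unname(counts[code]), 1L, label = code)
  }
  # supply below observed co-occurs with the negative index by construction
  expect_equal(unname(counts[["FN_LT_FO"]]), 1L)
})
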