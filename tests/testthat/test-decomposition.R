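test_that("components sum exactly to the fertility change over random record pairs", {
  rec1 <- random_records(5000, seed = 21, spill = 0.2)
  rec2 <- random_records(5000, seed = 22, spill = 0.2)
  c1 <- complete_records(rec1)
  c2 <- complete_records(rec2)
  for (i in seq_len(200)) { # row-wise API exercised on a subset
    r <- decompose_change(c1[i, ], c2[i, ])
    expect_equal(r$contrib_fw + r$contrib_fn + r$contrib_ip, r$delta_F,
                 tolerance = 1e-9)
  }
  # the identity vectorised over all 5000 pairs
  d_f <- c1$tfr - c2$tfr
  m_ip <- (c1$ip + c2$ip) / 2
  sum3 <- (c1$wanted_tfr - c2$wanted_tfr) * m_ip +
    (c1$ip - c2$ip) * ((c1$wanted_tfr + c2$wanted_tfr) / 2 -
                         (c1$natural_tfr + c2$natural_tfr) / 2) +
    (c1$natural_tfr - c2$natural_tfr) * (1 - m_ip)
  expect_equal(sum3, d_f, tolerance = 1e-9)
})

test_that("decomposition is antisymmetric and vanishes without change", {
  recs <- complete_records(random_records(50, seed = 33))
  for (i in 1:20) {
    ab <- decompose_change(recs[i, ], recs[i + 1, ])
    ba <- decompose_change(recs[i + 1, ], recs[i, ])
    expect_equal(unlist(ab[, c("delta_F", "contrib_fw", "contrib_fn", "contrib_ip")]),
                 -unlist(ba[, c("delta_F", "contrib_fw", "contrib_fn", "contrib_ip")]),
                 tolerance = 1e-12)
  }
  same <- decompose_change(recs[1, ], recs[1, ])
  expect_equal(same$delta_F, 0)
  expect_equal(same$contrib_fw, 0)
  expect_equal(same$contrib_fn, 0)
  expect_equal(same$contrib_ip, 0)
  # zero-change mediator contributes zero even when others move
  a <- complete_records(survey_aggregates(data.frame(
    country = "X", survey_label = c("2000", "2010"),
    tfr = c(6, 5), wanted_tfr = c(5, 4), natural_tfr = c(8, 8)
  )))
  r <- decompose_change(a[1, ], a[2, ])
  expect_equal(r$contrib_fn, 0)
})

test_that("percent contributions scale by the change and sum to 100", {
  recs <- complete_records(random_records(40, seed = 44))
  for (i in 1:15) {
    r <- decompose_change(recs[i, ], recs[i + 20, ])
    if (abs(r$delta_F) > 0.05) {
      expect_equal(r$pct_fw + r$pct_fn + r$pct_ip, 100, tolerance = 1e-6)
    }
  }
})

test_that("near-zero and zero fertility change flag unstable percentages", {
  recs <- complete_records(survey_aggregates(data.frame(
    country = "X", survey_label = c("2000", "2010"),
    tfr = c(5.00, 4.999), wanted_tfr = c(3.5, 3.0), natural_tfr = c(8, 8.5)
  )))
  r <- decompose_change(recs[1, ], recs[2, ])
  expect_true(abs(r$pct_ip) > 1000 || abs(r$pct_fw) > 100) # exploded scale
  d <- diagnostics(r)
  expect_equal(d$code, "UNSTABLE_PERCENT")
  expect_equal(d$severity, "warning")

  z <- decompose_change(recs[1, ], recs[1, ])
  expect_true(is.na(z$pct_fw))
  dz <- diagnostics(z)
  expect_equal(dz$severity[dz$code == "UNSTABLE_PERCENT"], "error")
})

test_that("records with error diagnostics are refused for decomposition", {
  bad <- complete_records(survey_aggregates(data.frame(
    country = "X", survey_label = c("2000", "2010"),
    tfr = c(5, 4), wanted_tfr = c(5, 3), natural_tfr = c(5, 8)
  )))
  expect_false(bad$decomposable[1])
  expect_error(decompose_change(bad[1, ], bad[2, ]), class = "NON_DECOMPOSABLE")
})

test_that("series decomposition pairs endpoints by default, consecutively on request", {
  recs <- complete_records(survey_aggregates(data.frame(
    country = "X", survey_label = c("2000", "2005", "2010"),
    tfr = c(6, 5.5, 5), wanted_tfr = c(5, 4.5, 4), natural_tfr = c(8, 8.2, 8.4)
  )))
  ep <- decompose_series(recs)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$pair_label, "2000 → 2010")
  expect_equal(ep$delta_F, 1)
  cons <- decompose_series(recs, pairs = "consecutive")
  expect_equal(nrow(cons), 2)
  expect_equal(cons$year1, c("2000", "2005"))

  single <- decompose_series(recs[1, ])
  expect_equal(nrow(single), 0)
  expect_gt(nrow(diagnostics(single)), 0)
})

test_that("printed decomposition rows are internally consistent and recomputable from the trend table", {
  t4 <- table4_printed()
  # printed components sum to the printed decline within half the last digit
  expect_true(all(abs(t4$fw + t4$fn + t4$ip - t4$delta) <= 0.005))

  ind <- table3_fixture()
  for (i in seq_len(nrow(t4))) {
    r1 <- ind[ind$country == t4$country[i] & ind$survey_label == t4$year1[i], ]
    r2 <- ind[ind$country == t4$country[i] & ind$survey_label == t4$year2[i], ]
    r <- decompose_change(r1, r2)
    # the identity is exact on our arithmetic ...
    expect_equal(r$contrib_fw + r$contrib_fn + r$contrib_ip, r$delta_F,
                 tolerance = 1e-9)
    # ... and each component recomputed from rounded printed inputs sits
    # within 0.07 of the component published from unrounded estimates
    expect_lt(abs(r$contrib_fw - t4$fw[i]), 0.07)
    expect_lt(abs(r$contrib_fn - t4$fn[i]), 0.07)
    expect_lt(abs(r$contrib_ip - t4$ip[i]), 0.07)
    expect_lt(abs(r$delta_F - t4$delta[i]), 0.03)
  }
})
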