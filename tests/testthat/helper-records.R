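# Random valid survey aggregates for property-style tests: Fn > Fw > 0,
# observed anywhere in a band around [Fw, Fn] so out-of-range indices occur.
random_records <- function(n, seed = 42, spill = 0) {
  withr::with_seed(seed, {
    fw <- runif(n, 2, 6)
    fn <- fw + runif(n, 0.5, 5)
    fo <- fw + runif(n, -spill, 1 + spill) * (fn - fw)
    fo <- pmax(fo, 0.1)
    survey_aggregates(data.frame(
      country = "sim", stratum = sprintf("s%05d", seq_len(n)),
      survey_label = "2010", tfr = fo, wanted_tfr = fw, natural_tfr = fn
    ))
  })
}

table3_fixture <- function() complete_records(east_africa_surveys())

# printed decomposition table: country, years, delta TFR, absolute and
# percent contributions (wanted, natural, implementation)
table4_printed <- function() {
  tibble::tibble(
    country = c("Kenya", "Rwanda", "Tanzania", "Uganda"),
    year1 = c("2003", "2005", "2004–05", "2000–01"),
    year2 = c("2014", "2014–15", "2015–16", "2011"),
    delta = c(1, 1.89, 0.49, 0.68),
    fw = c(0.451, 0.692, 0.207, 0.314),
    fn = c(-0.289, -0.642, -0.176, 0.026),
    ip = c(0.838, 1.843, 0.459, 0.342),
    pct_fw = c(45.1, 36.6, 42.2, 46),
    pct_fn = c(-28.9, -33.9, -36, 3.9),
    pct_ip = c(83.8, 97.4, 93.8, 50.1)
  )
}
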