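Package: fertdecomp
Title: Supply-Demand Fertility Analysis and Decomposition of Fertility Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the supply-demand framework of fertility analysis on
    aggregate survey estimates. From observed and wanted total fertility rates
    and contraceptive prevalence it computes natural fertility, the degree of
    fertility preference implementation index, and unwanted fertility; it
    exactly decomposes the change in fertility between two surveys into
    additive contributions of wanted fertility, natural fertility and
    preference implementation; and it generates synthetic multi-wave,
    multi-stratum survey series with known ground truth for validation.
    Ships the published four-country East African survey series as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
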