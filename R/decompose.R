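#' Decompose fertility change between two survey waves
#'
#' Splits the decline in observed fertility between an earlier and a later
#' survey exactly into three additive components, one per mediator of the
#' supply-demand framework:
#'
#' * wanted fertility:      `delta_Fw * mean(Ip)`
#' * implementation index:  `delta_Ip * (mean(Fw) - mean(Fn))`
#' * natural fertility:     `delta_Fn * (1 - mean(Ip))`
#'
#' where `delta_x = x(earlier) - x(later)` (so decline is positive) and the
#' means are arithmetic means of the two endpoint values — the only weighting
#' under which the three components sum to `delta_F` as an algebraic
#' identity, to machine precision. Positive components are forces of decline;
#' negative components pushed fertility up.
#'
#' The implementation index entering the decomposition is recomputed from
#' each record's own full-precision values, never read back from rounded
#' display output.
#'
#' @param rec1,rec2 single completed records ([complete_records()] rows),
#'   `rec1` the earlier survey.
#' @param stability_threshold absolute fertility change (births per woman)
#'   below which percent contributions are flagged `UNSTABLE_PERCENT`;
#'   default 0.05.
#' @return A one-row tibble with `pair_label`, `delta_F`, the three absolute
#'   contributions (`contrib_fw`, `contrib_fn`, `contrib_ip`), percent
#'   contributions (`pct_fw`, `pct_fn`, `pct_ip`), the endpoint means
#'   (`mean_ip`, `mean_fw`, `mean_fn`) and identifying columns; diagnostics
#'   via [diagnostics()].
#' @export
#' @examples
#' recs <- complete_records(survey_aggregates(data.frame(
#'   country = "Kenya", survey_label = c("2003", "2014"),
#'   tfr = c(4.9, 3.9), wanted_tfr = c(3.6, 3.1), natural_tfr = c(8.2, 9.6)
#' )))
#' decompose_change(recs[1, ], recs[2, ])
decompose_change <- function(rec1, rec2, stability_threshold = 0.05) {
  stopifnot(nrow(rec1) == 1, nrow(rec2) == 1)
  for (rec in list(rec1, rec2)) {
    if (!isTRUE(rec$decomposable)) {
      rlang::abort(
        paste0("record ", record_id(rec), " carries an error diagnostic and is not decomposable"),
        class = c("fertdecomp_error", "NON_DECOMPOSABLE")
      )
    }
  }

  d_f  <- rec1$tfr - rec2$tfr
  d_fw <- rec1$wanted_tfr - rec2$wanted_tfr
  d_fn <- rec1$natural_tfr - rec2$natural_tfr
  d_ip <- rec1$ip - rec2$ip
  m_ip <- (rec1$ip + rec2$ip) / 2
  m_fw <- (rec1$wanted_tfr + rec2$wanted_tfr) / 2
  m_fn <- (rec1$natural_tfr + rec2$natural_tfr) / 2

  out <- tibble::tibble(
    country = rec1$country,
    stratum = rec1$stratum,
    year1 = rec1$survey_label,
    year2 = rec2$survey_label,
    pair_label = paste(rec1$survey_label, "→", rec2$survey_label),
    delta_F = d_f,
    contrib_fw = d_fw * m_ip,
    contrib_ip = d_ip * (m_fw - m_fn),
    contrib_fn = d_fn * (1 - m_ip),
    mean_ip = m_ip, mean_fw = m_fw, mean_fn = m_fn
  )
  percent_contributions(out, stability_threshold = stability_threshold)
}

#' Percent contributions of the decomposition components
#'
#' Converts each absolute component to a percentage of the total fertility
#' change: `100 * contrib / delta_F`. When the total change is tiny the
#' percentages explode (published stratified tables contain values such as
#' 708% precisely where the TFR barely moved); they are still computed, but
#' an `UNSTABLE_PERCENT` warning diagnostic is attached below
#' `stability_threshold`, and exactly zero change yields `NA` percentages
#' with an error-severity diagnostic.
#'
#' @param result a decomposition tibble from [decompose_change()] (the
#'   percent columns, if present, are recomputed).
#' @inheritParams decompose_change
#' @return `result` with `pct_fw`, `pct_fn`, `pct_ip` filled; diagnostics
#'   carried over and extended.
#' @export
percent_contributions <- function(result, stability_threshold = 0.05) {
  prior <- diagnostics(result)
  ctx <- paste(result$country, result$stratum, result$pair_label, sep = "/")
  zero <- result$delta_F == 0
  pct <- function(x) ifelse(zero, NA_real_, 100 * x / result$delta_F)
  result$pct_fw <- pct(result$contrib_fw)
  result$pct_fn <- pct(result$contrib_fn)
  result$pct_ip <- pct(result$contrib_ip)

  diag <- bind_diagnostics(
    prior[prior$code != "UNSTABLE_PERCENT", , drop = FALSE],
    new_diagnostic(rep("UNSTABLE_PERCENT", sum(zero)), "error",
                   "zero fertility change: percent contributions undefined",
                   ctx[zero]),
    new_diagnostic(rep("UNSTABLE_PERCENT", sum(!zero & abs(result$delta_F) < stability_threshold)),
                   "warning",
                   "near-zero fertility change: percent contributions unstable",
                   ctx[!zero & abs(result$delta_F) < stability_threshold])
  )
  set_diagnostics(result, diag)
}

#' Decompose a multi-wave survey series
#'
#' Applies [decompose_change()] across an ordered series of completed
#' records for one stratum. The default pairs the first and last
#' decomposable surveys (published decade decompositions use window
#' endpoints); `pairs = "consecutive"` decomposes every successive pair.
#'
#' @param records completed records ([complete_records()]) for a single
#'   (country, stratum); sorted internally by `reference_year`.
#' @param pairs `"endpoint"` (default) or `"consecutive"`.
#' @inheritParams decompose_change
#' @return A tibble of decomposition results (zero rows, with a diagnostic,
#'   when fewer than two decomposable records are available).
#' @export
decompose_series <- function(records, pairs = c("endpoint", "consecutive"),
                             stability_threshold = 0.05) {
  pairs <- match.arg(pairs)
  rec <- dplyr::arrange(tibble::as_tibble(records), .data$reference_year)
  rec <- rec[rec$decomposable, , drop = FALSE]
  if (nrow(rec) < 2) {
    out <- decompose_change(.empty_pair(), .empty_pair())[0, ]
    return(set_diagnostics(out, new_diagnostic(
      "UNSTABLE_PERCENT", "warning",
      "fewer than two decomposable records: nothing to decompose",
      if (nrow(rec) == 1) record_id(rec) else NA_character_
    )))
  }
  idx <- if (pairs == "endpoint") {
    list(c(1L, nrow(rec)))
  } else {
    lapply(seq_len(nrow(rec) - 1L), function(i) c(i, i + 1L))
  }
  results <- lapply(idx, function(ij) {
    decompose_change(rec[ij[1], ], rec[ij[2], ],
                     stability_threshold = stability_threshold)
  })
  diag <- dplyr::bind_rows(lapply(results, diagnostics))
  set_diagnostics(dplyr::bind_rows(results), diag)
}

# template record used to materialise an empty result frame
.empty_pair <- function() {
  complete_records(survey_aggregates(data.frame(
    country = "x", survey_label = c("2000", "2010"),
    tfr = c(5, 4), wanted_tfr = c(3, 3), natural_tfr = c(8, 8)
  )))[1, ]
}
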