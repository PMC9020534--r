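#' Read aggregate survey estimates from CSV
#'
#' Reads a UTF-8 CSV with columns `country`, `survey_label`, `tfr`,
#' `wanted_tfr` and optionally `stratum`, `cpr`, `natural_tfr`, and
#' validates it through [survey_aggregates()]. Missing mandatory columns are
#' a hard error naming them; row-level problems (non-positive rates, neither
#' prevalence nor natural fertility, unparseable labels) are collected in
#' the `"problems"` attribute, not fatal.
#'
#' @param path path to the CSV file.
#' @return A tibble of validated survey aggregates.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path),
                 class = c("fertdecomp_error", "FILE_NOT_FOUND"))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  survey_aggregates(raw)
}

#' Write survey records or results to CSV at full precision
#'
#' Machine-readable output: full-precision values, no display rounding, so
#' that read -> write -> read round-trips exactly. Display rounding belongs
#' to the report builders only, and display tables are never an input.
#'
#' @param x a tibble of records or results.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' The published East African national survey series
#'
#' The four-country series of printed national estimates (Kenya, Rwanda,
#' Tanzania, Uganda; 23 survey waves, 1988-2016) of observed TFR, wanted
#' TFR and natural fertility, shipped as a packaged CSV fixture exactly as
#' printed (rates to one decimal). Contraceptive prevalence is not printed
#' in the source table and is left empty.
#'
#' @return A tibble of 23 validated survey aggregates.
#' @export
#' @examples
#' nrow(east_africa_surveys()) # 23
east_africa_surveys <- function() {
  read_survey_table(system.file("extdata", "east_africa_surveys.csv",
                                package = "fertdecomp", mustWork = TRUE))
}

fmt_half_up <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits),
                               format = "f", digits = digits))
}

ip_marker <- function(ip) {
  dplyr::case_when(is.na(ip) ~ "", ip < 0 ~ "*", ip > 1 ~ "**", TRUE ~ "")
}

new_report <- function(kind, rows, footnotes) {
  structure(list(kind = kind, rows = rows, footnotes = footnotes),
            class = "fert_report")
}

#' @export
print.fert_report <- function(x, ...) {
  cat(sprintf("<fert_report: %s, %d row(s)>\n", x$kind, nrow(x$rows)))
  print(x$rows, n = Inf)
  for (fn in x$footnotes) cat(fn, "\n")
  invisible(x)
}

#' Display table of derived indices
#'
#' Renders completed records the way the published trend table prints them:
#' rates to one decimal, the implementation index to two, half-up rounding,
#' rows ordered by country with the most recent survey first. Indices
#' outside the unit interval carry the conventional footnote markers
#' (`*` below zero, `**` above one) rather than being clamped.
#'
#' @param records completed records from [complete_records()].
#' @return A `fert_report` object; `$rows` is the display tibble (character
#'   columns), `$footnotes` the marker legend when any row needs it.
#' @export
build_indices_report <- function(records) {
  rec <- dplyr::arrange(tibble::as_tibble(records),
                        .data$country, .data$stratum,
                        dplyr::desc(.data$reference_year))
  rows <- tibble::tibble(
    country = rec$country,
    stratum = rec$stratum,
    survey = rec$survey_label,
    tfr = fmt_half_up(rec$tfr, 1),
    wanted_tfr = fmt_half_up(rec$wanted_tfr, 1),
    natural_tfr = fmt_half_up(rec$natural_tfr, 1),
    ip = paste0(fmt_half_up(rec$ip, 2), ip_marker(rec$ip))
  )
  marks <- ip_marker(rec$ip)
  footnotes <- c(
    if (any(marks == "*")) "* implementation index below zero",
    if (any(marks == "**")) "** implementation index above one"
  )
  new_report("indices", rows, footnotes %||% character())
}

#' Display table of decomposition results
#'
#' Renders decomposition results at the precision the published
#' decomposition table uses: absolute contributions to three decimals,
#' percentages to one. Results whose percentages were flagged unstable
#' carry their diagnostic codes in a `flags` column.
#'
#' @param results a tibble from [decompose_change()] / [decompose_series()].
#' @return A `fert_report` object.
#' @export
build_decomposition_report <- function(results) {
  res <- tibble::as_tibble(results)
  diag <- diagnostics(results)
  ctx <- paste(res$country, res$stratum, res$pair_label, sep = "/")
  flags <- vapply(ctx, function(id) {
    paste(unique(diag$code[diag$context == id]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  rows <- tibble::tibble(
    country = res$country,
    stratum = res$stratum,
    year1 = res$year1, year2 = res$year2,
    delta_tfr = fmt_half_up(res$delta_F, 2),
    contrib_fw = fmt_half_up(res$contrib_fw, 3),
    contrib_fn = fmt_half_up(res$contrib_fn, 3),
    contrib_ip = fmt_half_up(res$contrib_ip, 3),
    pct_fw = fmt_half_up(res$pct_fw, 1),
    pct_fn = fmt_half_up(res$pct_fn, 1),
    pct_ip = fmt_half_up(res$pct_ip, 1),
    flags = flags
  )
  new_report("decomposition", rows, character())
}
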