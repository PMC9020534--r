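#' Parse a survey label into a decimal reference year
#'
#' DHS reports label fieldwork periods either with a single year (`"2003"`)
#' or a split year with an en dash or hyphen (`"2014-15"`, `"2014–15"`).
#' Split labels are resolved to the midpoint of the two years
#' (`"2014-15"` -> 2014.5); single years map to themselves.
#'
#' @param x character vector of survey labels.
#' @return Numeric vector of decimal reference years; `NA` for labels that
#'   cannot be parsed.
#' @export
#' @examples
#' parse_survey_label(c("2003", "2014-15", "1988–89"))
parse_survey_label <- function(x) {
  x <- gsub("–", "-", trimws(as.character(x)))
  vapply(x, function(lab) {
    if (grepl("^\\d{4}$", lab)) return(as.numeric(lab))
    m <- regmatches(lab, regexec("^(\\d{4})-(\\d{2,4})$", lab))[[1]]
    if (length(m) == 3) {
      y1 <- as.numeric(m[2])
      y2 <- as.numeric(m[3])
      if (y2 < 100) y2 <- floor(y1 / 100) * 100 + y2
      return((y1 + y2) / 2)
    }
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble and validate aggregate survey records
#'
#' Normalises a data frame of printed survey estimates into the tibble the
#' rest of the pipeline consumes: one row per (country, stratum, survey
#' wave) with observed TFR (`tfr`), wanted TFR (`wanted_tfr`) and at least
#' one of contraceptive prevalence (`cpr`, proportion) or natural fertility
#' (`natural_tfr`). A `reference_year` column is derived from `survey_label`.
#'
#' Validation enforces: positive `tfr` and `wanted_tfr`; `cpr` in `[0, 1]`;
#' at least one of `cpr` / `natural_tfr` per row. Rows violating these are
#' dropped with a row-level problem recorded (retrievable via
#' `attr(x, "problems")`); validation problems are not diagnostics in the
#' [diagnostics()] sense, which concern the framework arithmetic.
#'
#' @param data a data frame with columns `country`, `survey_label`, `tfr`,
#'   `wanted_tfr` and optionally `stratum` (default `"national"`), `cpr`,
#'   `natural_tfr`.
#' @return A tibble of survey aggregates sorted by country, stratum and
#'   reference year, with attribute `"problems"` (character vector, possibly
#'   empty).
#' @export
#' @examples
#' survey_aggregates(data.frame(
#'   country = "Uganda", survey_label = "2011",
#'   tfr = 6.2, wanted_tfr = 4.4, natural_tfr = 8.9
#' ))
survey_aggregates <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("country", "survey_label", "tfr", "wanted_tfr")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = c("fertdecomp_error", "MISSING_COLUMNS")
    )
  }
  if (!"stratum" %in% names(data)) data$stratum <- "national"
  if (!"cpr" %in% names(data)) data$cpr <- NA_real_
  if (!"natural_tfr" %in% names(data)) data$natural_tfr <- NA_real_

  out <- tibble::tibble(
    country = as.character(data$country),
    stratum = dplyr::coalesce(as.character(data$stratum), "national"),
    survey_label = as.character(data$survey_label),
    reference_year = parse_survey_label(data$survey_label),
    tfr = as.numeric(data$tfr),
    wanted_tfr = as.numeric(data$wanted_tfr),
    cpr = as.numeric(data$cpr),
    natural_tfr = as.numeric(data$natural_tfr)
  )

  rid <- record_id(out)
  problems <- character()
  bad <- rep(FALSE, nrow(out))

  flag <- function(cond, msg) {
    cond <- !is.na(cond) & cond
    if (any(cond)) {
      problems <<- c(problems, paste0(rid[cond], ": ", msg))
      bad <<- bad | cond
    }
  }
  flag(is.na(out$tfr) | out$tfr <= 0, "observed TFR must be positive")
  flag(is.na(out$wanted_tfr) | out$wanted_tfr <= 0, "wanted TFR must be positive")
  flag(!is.na(out$cpr) & (out$cpr < 0 | out$cpr > 1),
       "contraceptive prevalence must be a proportion in [0, 1]")
  flag(is.na(out$cpr) & is.na(out$natural_tfr),
       "at least one of cpr, natural_tfr is required")
  flag(is.na(out$reference_year), "survey_label could not be parsed to a year")

  out <- out[!bad, , drop = FALSE]
  out <- dplyr::arrange(out, .data$country, .data$stratum, .data$reference_year)
  attr(out, "problems") <- problems
  out
}

record_id <- function(rec) {
  paste(rec$country, rec$stratum, rec$survey_label, sep = "/")
}

#' @importFrom rlang .data
NULL
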