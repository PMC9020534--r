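#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn %||%
NULL

# Enumerated diagnostic codes; everything attached to a record or a
# decomposition result must carry one of these.
DIAGNOSTIC_CODES <- c(
  "IP_BELOW_ZERO", "IP_ABOVE_ONE", "FN_LE_FW", "FN_LT_FO",
  "C_NONPOSITIVE", "FN_U_INCONSISTENT", "UNSTABLE_PERCENT"
)

new_diagnostic <- function(code, severity, message, context = NA_character_) {
  stopifnot(all(code %in% DIAGNOSTIC_CODES), all(severity %in% c("warning", "error")))
  tibble::tibble(
    code = as.character(code), severity = as.character(severity),
    message = as.character(message), context = as.character(context)
  )
}

empty_diagnostics <- function() {
  new_diagnostic(character(), character(), character(), character())
}

bind_diagnostics <- function(...) {
  dplyr::bind_rows(empty_diagnostics(), ...)
}

#' Diagnostics attached to a result
#'
#' Record completion ([complete_records()]) and decomposition
#' ([decompose_change()], [decompose_series()]) never silently clamp or drop
#' anomalous values; instead they attach coded diagnostics. `diagnostics()`
#' retrieves them as a tibble with columns `code`, `severity` (`"warning"` or
#' `"error"`), `message` and `context` (the record identifier).
#'
#' The codes are: `IP_BELOW_ZERO` / `IP_ABOVE_ONE` (implementation index
#' outside the nominal unit interval, reported as computed), `FN_LE_FW`
#' (natural fertility does not exceed wanted fertility, index undefined),
#' `FN_LT_FO` (natural fertility below observed fertility), `C_NONPOSITIVE`
#' (contraceptive prevalence so high the contraception index is not
#' positive), `FN_U_INCONSISTENT` (supplied natural fertility disagrees with
#' the prevalence-derived value), `UNSTABLE_PERCENT` (percent contributions
#' computed over a near-zero fertility change).
#'
#' @param x an object returned by a `fertdecomp` pipeline step.
#' @return A tibble of diagnostics (zero rows if none were raised).
#' @export
#' @examples
#' recs <- survey_aggregates(data.frame(
#'   country = "X", survey_label = "2010",
#'   tfr = 5, wanted_tfr = 5, natural_tfr = 5
#' ))
#' diagnostics(complete_records(recs))
diagnostics <- function(x) {
  attr(x, "diagnostics") %||% empty_diagnostics()
}

set_diagnostics <- function(x, diag) {
  attr(x, "diagnostics") <- diag
  x
}
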