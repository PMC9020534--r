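#' Complete survey records with derived supply-demand indices
#'
#' For each survey aggregate, fills natural fertility (from contraceptive
#' prevalence when not supplied directly), then the preference implementation
#' index and unwanted fertility. Nothing is clamped: out-of-range indices are
#' returned as computed with warning diagnostics, matching how published
#' applications of the framework report them. Records that hit an undefined
#' quantity (non-positive contraception index, supply not exceeding demand)
#' are retained with `NA` derived values, an error-severity diagnostic, and
#' `decomposable = FALSE`.
#'
#' When both prevalence and natural fertility are supplied, the supplied
#' natural fertility wins (printed tables report it directly) but is checked
#' against the prevalence-derived value; a relative discrepancy beyond
#' `fn_tol` raises an `FN_U_INCONSISTENT` warning diagnostic.
#'
#' @param records a tibble from [survey_aggregates()].
#' @param coef contraception-index coefficient, default 1.02.
#' @param fn_tol relative tolerance for the consistency check between
#'   supplied and prevalence-derived natural fertility, default 0.05.
#' @param denom_tol denominator tolerance below which the implementation
#'   index is treated as undefined (`FN_LE_FW`), default `1e-6`.
#' @return The input tibble with added columns `contraception` (the index C),
#'   `natural_tfr` (filled), `ip`, `unwanted_tfr` and `decomposable`;
#'   diagnostics via [diagnostics()].
#' @export
#' @examples
#' recs <- survey_aggregates(data.frame(
#'   country = "Tanzania", survey_label = "2015-16",
#'   tfr = 5.2, wanted_tfr = 4.5, natural_tfr = 8.6
#' ))
#' complete_records(recs)$ip # 0.829..., printed as 0.83
complete_records <- function(records, coef = 1.02, fn_tol = 0.05,
                             denom_tol = 1e-6) {
  rec <- tibble::as_tibble(records)
  n <- nrow(rec)
  rid <- record_id(rec)
  diag <- list()
  add_diag <- function(idx, code, severity, message) {
    if (length(idx) > 0) {
      diag[[length(diag) + 1]] <<- new_diagnostic(code, severity,
                                                  message, rid[idx])
    }
  }

  c_idx <- contraception_index(rec$cpr, coef = coef, check = FALSE)
  fn_from_u <- ifelse(!is.na(c_idx) & c_idx > 0, rec$tfr / c_idx, NA_real_)

  bad_c <- which(!is.na(c_idx) & c_idx <= 0 & is.na(rec$natural_tfr))
  add_diag(bad_c, "C_NONPOSITIVE", "error",
           "contraception index not positive; natural fertility undefined")
  # prevalence beyond the validity boundary but F_n supplied directly: the
  # supplied value carries the record, the index C is still reported as NA
  c_idx[!is.na(c_idx) & c_idx <= 0] <- NA_real_

  fn <- ifelse(is.na(rec$natural_tfr), fn_from_u, rec$natural_tfr)

  both <- which(!is.na(rec$natural_tfr) & !is.na(fn_from_u))
  inconsistent <- both[abs(rec$natural_tfr[both] - fn_from_u[both]) /
                         fn_from_u[both] > fn_tol]
  add_diag(inconsistent, "FN_U_INCONSISTENT", "warning",
           "supplied natural fertility disagrees with prevalence-derived value")

  undefined <- which(is.na(fn))
  le_fw <- which(!is.na(fn) & fn <= rec$wanted_tfr + denom_tol)
  add_diag(le_fw, "FN_LE_FW", "error",
           "natural fertility does not exceed wanted fertility; implementation index undefined")

  lt_fo <- which(!is.na(fn) & !(seq_len(n) %in% le_fw) & fn < rec$tfr)
  add_diag(lt_fo, "FN_LT_FO", "warning",
           "natural fertility below observed fertility")

  ok <- !is.na(fn) & !(seq_len(n) %in% le_fw)
  ip <- rep(NA_real_, n)
  ip[ok] <- (fn[ok] - rec$tfr[ok]) / (fn[ok] - rec$wanted_tfr[ok])
  fu <- rep(NA_real_, n)
  fu[ok] <- (fn[ok] - rec$wanted_tfr[ok]) * (1 - ip[ok])

  add_diag(which(!is.na(ip) & ip < 0), "IP_BELOW_ZERO", "warning",
           "implementation index below zero; reported unclamped")
  add_diag(which(!is.na(ip) & ip > 1), "IP_ABOVE_ONE", "warning",
           "implementation index above one; reported unclamped")

  rec$contraception <- c_idx
  rec$natural_tfr <- fn
  rec$ip <- ip
  rec$unwanted_tfr <- fu

  diag <- dplyr::bind_rows(empty_diagnostics(), diag)
  err_ids <- unique(diag$context[diag$severity == "error"])
  rec$decomposable <- !(rid %in% err_ids)

  set_diagnostics(rec, diag)
}
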