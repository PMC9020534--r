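#' Round half-up (half away from zero)
#'
#' The survey tables this package reproduces round rates to one decimal and
#' indices to two with ties going away from zero; base [round()] rounds ties
#' to even, so it cannot reproduce them. Internal computation is always full
#' precision — this helper is for display and for matching printed values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-away-from-zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.875, 2) # 0.88, where round() gives 0.88 or 0.87
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the small offset keeps decimal ties (stored fractionally below .5 in
  # binary) on the away-from-zero side
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Contraception index
#'
#' The proportional reduction of natural fertility attributable to deliberate
#' birth control: `C = 1 - 1.02 * U`, where `U` is the proportion of married
#' women currently using contraception. The 1.02 coefficient is the standard
#' empirical adjustment for use-effectiveness and exposure; it is exposed as
#' an argument to document its provenance, not as an invitation to tune.
#'
#' @param u contraceptive prevalence, proportion in `[0, 1]`.
#' @param coef adjustment coefficient, default `1.02`.
#' @param check if `TRUE` (default), a non-positive index (prevalence at or
#'   beyond `1/coef`, about 0.9804) raises a classed error `C_NONPOSITIVE`,
#'   since natural fertility is then undefined. With `check = FALSE` the raw
#'   value is returned for callers that collect diagnostics themselves.
#' @return `1 - coef * u`, dimensionless in `(0, 1]` for valid prevalence.
#' @export
#' @examples
#' contraception_index(0)    # 1: no contraception, no reduction
#' contraception_index(0.5)  # 0.49
contraception_index <- function(u, coef = 1.02, check = TRUE) {
  stopifnot(is.numeric(u), all(is.na(u) | (u >= 0 & u <= 1)))
  c_idx <- 1 - coef * u
  if (check && any(!is.na(c_idx) & c_idx <= 0)) {
    rlang::abort(
      sprintf("contraception index is not positive at prevalence %.4f; natural fertility undefined",
              u[which(!is.na(c_idx) & c_idx <= 0)[1]]),
      class = c("fertdecomp_error", "C_NONPOSITIVE")
    )
  }
  c_idx
}

#' Natural fertility from observed fertility and contraceptive prevalence
#'
#' Inflates the observed total fertility rate by the contraception index:
#' `F_n = F_o / C`. This is the fertility that would prevail absent deliberate
#' birth control — not total fecundity, which is a different (larger)
#' quantity. It is always at least `F_o`, with equality only at zero
#' prevalence.
#'
#' @param tfr observed total fertility rate, births per woman, positive.
#' @param u contraceptive prevalence, proportion in `[0, 1]`.
#' @inheritParams contraception_index
#' @return Natural fertility, births per woman.
#' @export
#' @examples
#' natural_fertility(3.9, 0)      # 3.9
#' natural_fertility(5.0, 0.25)   # 6.711...
natural_fertility <- function(tfr, u, coef = 1.02, check = TRUE) {
  stopifnot(is.numeric(tfr), all(is.na(tfr) | tfr > 0))
  tfr / contraception_index(u, coef = coef, check = check)
}

#' Fertility preference implementation index
#'
#' The degree to which excess supply of births (natural minus wanted
#' fertility) is averted: `I_p = (F_n - F_o) / (F_n - F_w)`. A value of 1
#' means observed fertility equals wanted fertility (no unwanted births);
#' 0 means observed equals natural fertility (no implementation at all).
#'
#' The index is *not* clamped: empirical estimates outside `[0, 1]` occur in
#' published sub-national series and are returned as computed, with a
#' warning-severity diagnostic attached by [complete_records()]. Here the raw
#' value is returned; only the undefined case errors.
#'
#' @param f_n natural fertility, births per woman.
#' @param f_o observed total fertility rate, births per woman.
#' @param f_w wanted total fertility rate, births per woman.
#' @param tol denominator tolerance: `f_n <= f_w + tol` raises a classed
#'   `FN_LE_FW` error (supply does not exceed demand, index undefined)
#'   instead of returning an unbounded value. Default `1e-6`.
#' @param check if `FALSE`, returns `NA` instead of erroring on an undefined
#'   denominator.
#' @return The implementation index, dimensionless.
#' @export
#' @examples
#' implementation_index(8.9, 6.2, 4.4) # 0.60
#' implementation_index(7.8, 5.7, 4.8) # 0.70
implementation_index <- function(f_n, f_o, f_w, tol = 1e-6, check = TRUE) {
  stopifnot(is.numeric(f_n), is.numeric(f_o), is.numeric(f_w))
  bad <- !is.na(f_n) & !is.na(f_w) & (f_n <= f_w + tol)
  if (check && any(bad)) {
    rlang::abort(
      sprintf("natural fertility (%.3f) does not exceed wanted fertility (%.3f): implementation index undefined",
              f_n[which(bad)[1]], f_w[which(bad)[1]]),
      class = c("fertdecomp_error", "FN_LE_FW")
    )
  }
  out <- (f_n - f_o) / (f_n - f_w)
  out[bad] <- NA_real_
  out
}

#' Unwanted fertility
#'
#' `F_u = (F_n - F_w) * (1 - I_p)`: the part of observed fertility exceeding
#' the demand for births. With the index computed from the same record,
#' `F_w + F_u` reproduces `F_o` exactly (the accounting identity).
#'
#' @inheritParams implementation_index
#' @param i_p implementation index.
#' @return Unwanted fertility, births per woman.
#' @export
#' @examples
#' unwanted_fertility(8.9, 4.4, 0.6) # 1.8; 4.4 + 1.8 = 6.2 observed
unwanted_fertility <- function(f_n, f_w, i_p) {
  (f_n - f_w) * (1 - i_p)
}

#' Observed fertility from the supply-demand forward model
#'
#' The convex combination `F = F_w * I_p + F_n * (1 - I_p)` (for an index in
#' the unit interval). This is the exact algebraic inverse of
#' [implementation_index()] and the forward model used by the synthetic
#' series generator.
#'
#' @inheritParams unwanted_fertility
#' @return Observed total fertility rate, births per woman.
#' @export
#' @examples
#' observed_fertility(4.4, 8.9, 0.6) # 6.2
observed_fertility <- function(f_w, f_n, i_p) {
  f_w * i_p + f_n * (1 - i_p)
}

#' Wanted-fertility shortcut from want-no-more proportions (flagged)
#'
#' An alternative estimator of wanted fertility from the proportion of women
#' who want more children and the proportion of women in union aged 40-49 who
#' want no more births, evaluated literally as the source prints it:
#' `p_want_more + 1.09 - w_m_40_49`. The printed formula is internally
#' inconsistent (the estimand appears on both sides in the source, and the
#' units do not resolve), so this function always emits a warning and is
#' never used by any pipeline default; it exists so the printed arithmetic
#' can be inspected.
#'
#' @param p_want_more proportion of women who want more children, in `[0, 1]`.
#' @param w_m_40_49 proportion of women in union aged 40-49 who want no more
#'   births, in `[0, 1]`.
#' @return The literal value `p_want_more + 1.09 - w_m_40_49`.
#' @export
#' @examples
#' suppressWarnings(wanted_fertility_from_want_no_more(0.5, 0.5)) # 1.09
wanted_fertility_from_want_no_more <- function(p_want_more, w_m_40_49) {
  stopifnot(all(p_want_more >= 0 & p_want_more <= 1),
            all(w_m_40_49 >= 0 & w_m_40_49 <= 1))
  rlang::warn(
    paste("wanted_fertility_from_want_no_more() evaluates a shortcut formula that is",
          "internally inconsistent as published; treat its output as indicative only"),
    class = "fertdecomp_eq_shortcut_warning"
  )
  p_want_more + 1.09 - w_m_40_49
}
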