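#' Configuration for the synthetic survey-series generator
#'
#' Describes a multi-wave, multi-stratum series of aggregate survey
#' estimates with known ground truth. The defaults emulate a national East
#' African series over 2000-2015: wanted fertility declining from 5.0 to 3.5
#' births per woman, contraceptive prevalence rising from 0.10 to 0.45, a
#' natural fertility level drifting from 8 to 9 births per woman, and an
#' implementation index rising 0.45 to 0.85 along a logistic (plateau-then-
#' rise) path. Reported rates can carry additive Gaussian noise and be
#' rounded to one decimal as DHS tables print them.
#'
#' @param n_strata number of strata (regions/subgroups), default 1.
#' @param n_waves surveys per stratum, at least 2; default 4.
#' @param year_range first and last reference years, default `c(2000, 2015)`.
#' @param fw_trajectory start and end wanted TFR, default `c(5.0, 3.5)`.
#' @param u_trajectory start and end contraceptive prevalence, default
#'   `c(0.10, 0.45)`; used when `fn_base = "derive"` and to report `cpr`.
#' @param fn_base either a length-2 numeric (start/end natural fertility,
#'   default `c(8, 9)`, prevalence then implied) or `"derive"` (natural
#'   fertility derived from `u_trajectory`, observed fertility solved from
#'   the forward model).
#' @param ip_trajectory start and end true implementation index, default
#'   `c(0.45, 0.85)`.
#' @param trajectory_shape `"logistic"` (default; mimics the plateau-then-
#'   rise paths of observed national series) or `"linear"`.
#' @param noise_sd standard deviation of additive measurement noise on
#'   reported observed and wanted TFR, births per woman; default 0.1 (the
#'   published series carry no variance statements, so this is a documented
#'   stand-in). Noise is truncated so rates stay positive.
#' @param stratum_sd standard deviation of per-stratum level offsets on the
#'   wanted and natural fertility trajectories, default 0.3; drawn once per
#'   seed.
#' @param dhs_rounding round reported rates to 1 decimal (prevalence to 3)
#'   as DHS tables do; default `FALSE`.
#' @param seed integer seed; identical seed and configuration give
#'   bitwise-identical output.
#' @return A `synthetic_series_config` object (validated list).
#' @export
synthetic_series_config <- function(n_strata = 1, n_waves = 4,
                                    year_range = c(2000, 2015),
                                    fw_trajectory = c(5.0, 3.5),
                                    u_trajectory = c(0.10, 0.45),
                                    fn_base = c(8, 9),
                                    ip_trajectory = c(0.45, 0.85),
                                    trajectory_shape = c("logistic", "linear"),
                                    noise_sd = 0.1, stratum_sd = 0.3,
                                    dhs_rounding = FALSE, seed = 1L) {
  trajectory_shape <- match.arg(trajectory_shape)
  cfg <- list(
    n_strata = as.integer(n_strata), n_waves = as.integer(n_waves),
    year_range = as.numeric(year_range),
    fw_trajectory = as.numeric(fw_trajectory),
    u_trajectory = as.numeric(u_trajectory),
    fn_base = if (identical(fn_base, "derive")) "derive" else as.numeric(fn_base),
    ip_trajectory = as.numeric(ip_trajectory),
    trajectory_shape = trajectory_shape,
    noise_sd = as.numeric(noise_sd), stratum_sd = as.numeric(stratum_sd),
    dhs_rounding = isTRUE(dhs_rounding), seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_strata >= 1, cfg$n_waves >= 2,
    length(cfg$year_range) == 2, diff(cfg$year_range) > 0,
    length(cfg$fw_trajectory) == 2, all(cfg$fw_trajectory > 0),
    length(cfg$u_trajectory) == 2,
    all(cfg$u_trajectory >= 0 & cfg$u_trajectory < 1 / 1.02),
    length(cfg$ip_trajectory) == 2,
    cfg$noise_sd >= 0, cfg$stratum_sd >= 0
  )
  if (is.numeric(cfg$fn_base)) {
    stopifnot(length(cfg$fn_base) == 2, all(cfg$fn_base > 0))
    if (any(cfg$fn_base <= cfg$fw_trajectory)) {
      rlang::abort("natural fertility trajectory must exceed wanted fertility at every wave",
                   class = c("fertdecomp_error", "CONFIG_INVALID"))
    }
  }
  structure(cfg, class = "synthetic_series_config")
}

#' @export
print.synthetic_series_config <- function(x, ...) {
  cat("<synthetic_series_config>\n")
  cat(sprintf("  %d stratum/a x %d waves over %g-%g (%s trajectories)\n",
              x$n_strata, x$n_waves, x$year_range[1], x$year_range[2],
              x$trajectory_shape))
  cat(sprintf("  Fw %g->%g, Ip %g->%g, Fn %s, noise_sd %g, rounding %s, seed %d\n",
              x$fw_trajectory[1], x$fw_trajectory[2],
              x$ip_trajectory[1], x$ip_trajectory[2],
              if (identical(x$fn_base, "derive")) "derived from U"
              else paste0(x$fn_base[1], "->", x$fn_base[2]),
              x$noise_sd, x$dhs_rounding, x$seed))
  invisible(x)
}

# interpolation along [0, 1]; logistic is rescaled to hit both endpoints
.interp <- function(from, to, frac, shape) {
  if (shape == "linear") return(from + (to - from) * frac)
  s <- stats::plogis(8 * (frac - 0.5))
  s <- (s - stats::plogis(-4)) / (stats::plogis(4) - stats::plogis(-4))
  from + (to - from) * s
}

#' Generate a synthetic aggregate survey series with known ground truth
#'
#' Chooses true mediator trajectories per stratum (wanted fertility,
#' natural fertility, implementation index), computes observed fertility
#' through the forward model `F = Fw*Ip + Fn*(1 - Ip)`, applies measurement
#' noise and optional 1-decimal rounding, and returns both the noisy
#' observables (in the [survey_aggregates()] schema) and the noiseless
#' truth. With zero noise and no rounding, [complete_records()] recovers the
#' true index and unwanted fertility to machine precision — the pipeline is
#' an exact inversion on valid inputs.
#'
#' @param config a [synthetic_series_config()].
#' @return A list with elements `surveys` (validated aggregate records) and
#'   `truth` (tibble of true `fw`, `fn`, `ip`, `fo`, `fu`, `u` per stratum
#'   and wave).
#' @export
#' @examples
#' sim <- generate_series(synthetic_series_config(noise_sd = 0, seed = 7))
#' max(abs(complete_records(sim$surveys)$ip - sim$truth$ip)) # ~1e-16
generate_series <- function(config) {
  stopifnot(inherits(config, "synthetic_series_config"))
  withr::with_seed(config$seed, .generate_series_impl(config))
}

.generate_series_impl <- function(cfg) {
  years <- seq(cfg$year_range[1], cfg$year_range[2], length.out = cfg$n_waves)
  frac <- (years - years[1]) / diff(range(years))
  truth <- list()
  for (s in seq_len(cfg$n_strata)) {
    off_fw <- if (cfg$n_strata > 1) stats::rnorm(1, 0, cfg$stratum_sd) else 0
    off_fn <- if (cfg$n_strata > 1) stats::rnorm(1, 0, cfg$stratum_sd) else 0
    fw <- .interp(cfg$fw_trajectory[1], cfg$fw_trajectory[2], frac,
                  cfg$trajectory_shape) + off_fw
    ip <- .interp(cfg$ip_trajectory[1], cfg$ip_trajectory[2], frac,
                  cfg$trajectory_shape)
    u <- .interp(cfg$u_trajectory[1], cfg$u_trajectory[2], frac, "linear")
    if (identical(cfg$fn_base, "derive")) {
      # consistent solution of the forward model with Fn = Fo / C(U):
      # Fo = Fw*Ip / (1 - (1 - Ip)/C), valid only while C > 1 - Ip
      c_idx <- 1 - 1.02 * u
      if (any(c_idx <= 1 - ip)) {
        rlang::abort("derived natural fertility invalid: prevalence too low for the implementation index",
                     class = c("fertdecomp_error", "CONFIG_INVALID"))
      }
      fo <- fw * ip / (1 - (1 - ip) / c_idx)
      fn <- fo / c_idx
    } else {
      fn <- .interp(cfg$fn_base[1], cfg$fn_base[2], frac,
                    cfg$trajectory_shape) + off_fn
      fo <- observed_fertility(fw, fn, ip)
      u <- (1 - fo / fn) / 1.02
    }
    if (any(fn <= fw)) {
      rlang::abort("stratum trajectory violates Fn > Fw; reduce stratum_sd or widen the gap",
                   class = c("fertdecomp_error", "CONFIG_INVALID"))
    }
    truth[[s]] <- tibble::tibble(
      stratum = sprintf("stratum_%02d", s), year = years,
      fw = fw, fn = fn, ip = ip, fo = fo,
      fu = unwanted_fertility(fn, fw, ip), u = u
    )
  }
  truth <- dplyr::bind_rows(truth)

  noise <- function(x) {
    if (cfg$noise_sd == 0) return(x)
    pmax(x + stats::rnorm(length(x), 0, cfg$noise_sd), 0.1)
  }
  rnd <- function(x, d) if (cfg$dhs_rounding) round_half_up(x, d) else x
  obs <- tibble::tibble(
    country = "synthetic", stratum = truth$stratum,
    survey_label = as.character(round(truth$year)),
    tfr = rnd(noise(truth$fo), 1),
    wanted_tfr = rnd(noise(truth$fw), 1),
    cpr = rnd(truth$u, 3),
    natural_tfr = rnd(truth$fn, 1)
  )
  list(surveys = survey_aggregates(obs), truth = truth)
}

#' Sensitivity of the implementation index to table rounding
#'
#' Published tables print rates rounded to a fixed unit (0.1 births per
#' woman), so an index recomputed from printed values can differ from one
#' computed on unrounded estimates. This quantifies the worst case exactly:
#' the index `(Fn - Fo)/(Fn - Fw)` is monotone in each argument, so its
#' range over all perturbations of `Fo`, `Fw`, `Fn` within half a rounding
#' unit is attained at the 8 corners, which are enumerated directly.
#'
#' @param record a one-row completed record (or any row with `tfr`,
#'   `wanted_tfr`, `natural_tfr`).
#' @param grid_step the printed rounding unit for rates, default 0.1;
#'   perturbations span half this. `0` gives a degenerate interval.
#' @param denom_tol corners with `Fn <= Fw + denom_tol` (index undefined)
#'   are excluded from the range.
#' @return Named numeric `c(lower, upper)` bounding the index over the
#'   rounding neighbourhood.
#' @export
#' @examples
#' rec <- data.frame(tfr = 3.9, wanted_tfr = 3.1, natural_tfr = 9.6)
#' rounding_sensitivity(rec) # brackets 0.877
rounding_sensitivity <- function(record, grid_step = 0.1, denom_tol = 1e-6) {
  stopifnot(nrow(record) == 1, grid_step >= 0)
  h <- grid_step / 2
  d <- if (h == 0) 0 else c(-h, h)
  corners <- expand.grid(do = d, dw = d, dn = d)
  fo <- record$tfr + corners$do
  fw <- record$wanted_tfr + corners$dw
  fn <- record$natural_tfr + corners$dn
  ok <- fn > fw + denom_tol
  if (!any(ok)) {
    rlang::abort("index undefined over the entire rounding neighbourhood",
                 class = c("fertdecomp_error", "FN_LE_FW"))
  }
  ip <- (fn[ok] - fo[ok]) / (fn[ok] - fw[ok])
  c(lower = min(ip), upper = max(ip))
}

#' Pathological records exercising every record-level diagnostic
#'
#' A small deterministic battery of crafted survey aggregates, each designed
#' to trigger exactly one anomaly of the kind observed in published
#' stratified series (indices below zero and above one, supply below
#' demand, prevalence beyond the validity boundary, inconsistent inputs),
#' plus a near-stationary pair whose decomposition triggers the unstable-
#' percentage flag. Useful for testing diagnostic handling end to end.
#'
#' @return A tibble of survey aggregates; strata are named for the
#'   diagnostic they provoke. The `unstable_pct` stratum has two waves whose
#'   fertility change is below the default stability threshold.
#' @export
pathological_records <- function() {
  survey_aggregates(tibble::tibble(
    country = "pathological",
    stratum = c("ip_below_zero", "ip_above_one", "fn_le_fw",
                "c_nonpositive", "fn_u_inconsistent",
                "unstable_pct", "unstable_pct"),
    survey_label = c("2010", "2010", "2010", "2010", "2010", "2000", "2010"),
    tfr = c(6.5, 4.0, 5.0, 5.0, 5.0, 5.00, 4.99),
    wanted_tfr = c(4.0, 4.5, 5.0, 3.5, 3.5, 3.5, 3.49),
    cpr = c(NA, NA, NA, 0.99, 0.30, NA, NA),
    natural_tfr = c(6.0, 8.0, 5.0, NA, 8.8, 8.0, 8.0)
  ))
}
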