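## Noncompartmental analysis of pre-filter concentration-time profiles.
## The data layer samples in minutes; everything here converts to hours on
## entry so that rate constants come out in 1/h and clearances in L/h.

#' Linear-up/log-down trapezoidal AUC
#'
#' Integrates a concentration-time profile with the linear trapezoid on
#' rising or flat segments (or when either endpoint is zero) and the
#' logarithmic trapezoid \eqn{(C_i - C_{i+1})\,\Delta t / \ln(C_i/C_{i+1})}
#' on strictly decreasing positive segments. The log rule is exact for
#' mono-exponential decline, so a one-compartment bolus profile is integrated
#' to machine precision on any sampling grid.
#'
#' @param time Sampling times in hours, strictly increasing.
#' @param conc Concentrations (any unit; the AUC inherits unit x h).
#' @return The AUC from the first to the last sampling time.
#' @examples
#' tt <- c(0, 10, 20, 30, 45, 60) / 60
#' auc_linuplogdown(tt, 100 * exp(-0.9 * tt)) # (100/0.9) * (1 - exp(-0.9))
#' @export
auc_linuplogdown <- function(time, conc) {
  if (length(time) != length(conc)) abort("`time` and `conc` lengths differ.")
  if (length(time) < 2) abort("AUC needs at least 2 points.")
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing.")
  if (any(conc < 0)) abort("Concentrations must be non-negative.")
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  dt <- diff(time)
  linear <- c2 >= c1 | c1 == 0 | c2 == 0
  seg <- ifelse(linear,
                (c1 + c2) / 2 * dt,
                (c1 - c2) * dt / log(c1 / c2))
  sum(seg)
}

#' Terminal elimination rate constant from the log-linear tail
#'
#' Least-squares fit of \eqn{\ln C} against time over a terminal window.
#' Zero (BLQ) concentrations are excluded before the fit. Two selection
#' rules are available: `"after_cmax"` (default) uses every positive point
#' strictly after the observed peak, appropriate for mono-exponential
#' profiles on a short rich schedule; `"best_r2"` scans terminal windows of
#' at least 3 points (excluding the peak) and keeps the one with the largest
#' adjusted r-squared. A fixed window size can be forced with `n_points`.
#'
#' @param time Sampling times in hours.
#' @param conc Concentrations (ng/mL).
#' @param method Window selection rule, `"after_cmax"` or `"best_r2"`.
#' @param n_points Optional fixed number of terminal points to use.
#' @return One-row tibble: `lambda_z` (1/h), `lambda_z_r2` (adjusted
#'   r-squared of the fit), `lambda_z_points`. A non-positive slope yields
#'   `lambda_z = NA` (flagged; extrapolation refuses downstream).
#' @export
fit_lambda_z <- function(time, conc, method = c("after_cmax", "best_r2"),
                         n_points = NULL) {
  method <- match.arg(method)
  keep <- conc > 0
  time <- time[keep]
  conc <- conc[keep]
  if (length(conc) < 3) {
    abort("lambda_z estimation needs at least 3 positive concentrations.")
  }
  fit_window <- function(idx) {
    f <- lm(log(conc[idx]) ~ time[idx])
    # noiseless profiles trip summary.lm's "essentially perfect fit" warning
    s <- suppressWarnings(summary(f))
    list(slope = unname(coef(f)[2]),
         adj_r2 = if (length(idx) > 2) s$adj.r.squared else s$r.squared,
         n = length(idx))
  }
  i_max <- which.max(conc)
  if (!is.null(n_points)) {
    if (n_points < 3 || n_points > length(conc)) {
      abort("`n_points` must be between 3 and the number of positive points.")
    }
    w <- fit_window(seq(length(conc) - n_points + 1L, length(conc)))
  } else if (method == "after_cmax") {
    idx <- which(seq_along(conc) > i_max)
    if (length(idx) < 3) {
      abort("Fewer than 3 positive points after Cmax; cannot fit lambda_z.")
    }
    w <- fit_window(idx)
  } else {
    n <- length(conc)
    starts <- seq(i_max + 1L, n - 2L)
    if (!length(starts) || starts[1] > n - 2L) {
      abort("Fewer than 3 positive points after Cmax; cannot fit lambda_z.")
    }
    fits <- lapply(starts, function(s) fit_window(seq(s, n)))
    w <- fits[[which.max(vapply(fits, `[[`, numeric(1), "adj_r2"))]]
  }
  lz <- -w$slope
  if (!is.finite(lz) || lz <= 0) {
    warn("Terminal slope is non-negative; lambda_z flagged as NA.")
    lz <- NA_real_
  }
  tibble::tibble(lambda_z = lz, lambda_z_r2 = w$adj_r2,
                 lambda_z_points = w$n)
}

## internal: NCA on one profile (time in minutes, conc ng/mL, dose mg)
nca_profile <- function(time_min, conc, dose_mg = NA_real_,
                        lambda_method = "after_cmax", n_points = NULL) {
  ord <- order(time_min)
  time_h <- time_min[ord] / 60
  conc <- conc[ord]
  lz <- fit_lambda_z(time_h, conc, method = lambda_method,
                     n_points = n_points)
  pos <- conc > 0
  c_max <- max(conc)
  c_last <- conc[max(which(pos))]
  auc_last <- auc_linuplogdown(time_h, conc)
  auc_inf <- if (is.na(lz$lambda_z)) NA_real_ else
    auc_last + c_last / lz$lambda_z
  cl <- if (!is.na(dose_mg) && !is.na(auc_inf)) {
    dose_mg / ng_per_ml_to_mg_per_l(auc_inf)   # mg / (mg.h/L) = L/h
  } else NA_real_
  vz <- if (!is.na(cl) && !is.na(lz$lambda_z)) cl / lz$lambda_z else NA_real_
  tibble::tibble(
    c_max = c_max, c_last = c_last,
    lambda_z = lz$lambda_z,
    t_half = log(2) / lz$lambda_z,
    auc_0_last = auc_last,
    auc_0_inf = auc_inf,
    auc_0_24 = 24 * auc_last,
    cl = cl, vz = vz,
    lambda_z_points = lz$lambda_z_points,
    lambda_z_r2 = lz$lambda_z_r2,
    dose_mg = dose_mg
  )
}

#' Noncompartmental analysis of every experiment in a sample table
#'
#' Runs NCA on the pre-filter series of the requested analyte for each
#' experiment: peak and last concentrations, terminal rate constant and
#' half-life, AUC from time zero to the last sample by the linear-up/log-down
#' rule, extrapolated AUC to infinity (`auc_0_last + c_last / lambda_z`), the
#' 24-h proportional AUC (`24 * auc_0_last`, the profiles spanning 1 h), and
#' -- when the dose is known -- clearance `dose / auc_0_inf` and terminal
#' volume `cl / lambda_z`. Doses are taken from a `dose_mg` column if present
#' or from the `dose_mg` argument; without a dose the AUCs are still reported
#' and `cl`/`vz` are `NA`.
#'
#' @param data Tidy sample table (see [sample_columns]).
#' @param analyte Analyte to analyse; default `"apixaban"`.
#' @param dose_mg Optional dose override: a single value recycled to all
#'   experiments, or a named vector keyed by `experiment_id`.
#' @param lambda_method,n_points Passed to [fit_lambda_z()].
#' @return A tibble with one row per experiment carrying the circuit
#'   configuration columns and the NCA parameters; units are ng/mL, 1/h, h,
#'   ng.h/mL, L/h and L.
#' @export
nca <- function(data, analyte = "apixaban", dose_mg = NULL,
                lambda_method = c("after_cmax", "best_r2"), n_points = NULL) {
  check_samples(data)
  lambda_method <- match.arg(lambda_method)
  pre <- dplyr::filter(data, .data$site == "pre_filter",
                       .data$analyte == .env$analyte)
  if (!nrow(pre)) abort(paste0("No pre_filter series for analyte ", analyte))
  cfg_cols <- c("experiment_id", "replicate_id", "mode", "filter",
                "effluent_flow_L_h", "dilution_split")
  pre |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cfg_cols))) |>
    dplyr::group_modify(function(d, key) {
      dose <- if (!is.null(dose_mg)) {
        if (!is.null(names(dose_mg))) {
          unname(dose_mg[key$experiment_id])
        } else dose_mg[1]
      } else if ("dose_mg" %in% names(d)) {
        unique(d$dose_mg)[1]
      } else NA_real_
      nca_profile(d$time_min, d$conc_ng_mL, dose_mg = dose,
                  lambda_method = lambda_method, n_points = n_points)
    }) |>
    dplyr::ungroup()
}
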