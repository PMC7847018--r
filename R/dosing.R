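## Target-exposure dose optimization: predict transmembrane clearance from
## the regression on circuit covariates, add non-renal clearance, match the
## target 24-h exposure, and round to practical twice-daily regimens.

#' Dosing policy
#'
#' The fixed quantities behind the dose recommendations: non-renal clearance
#' imputed from phase 2/3 apixaban studies (2.52 L/h, assumed constant;
#' residual renal function taken as negligible on CRRT), the 24-h exposure
#' target matching steady-state 5 mg BID dosing in healthy subjects
#' (2103.8 ng.h/mL = 2.1038 mg.h/L), the 2.5 mg tablet increment, BID
#' administration and a 10 mg single-dose cap preserving linear
#' absorption/PK.
#'
#' @param cl_nr Non-renal clearance, L/h.
#' @param target_auc_24 Target 24-h AUC, ng.h/mL.
#' @param tablet_increment Rounding increment, mg.
#' @param doses_per_day Administrations per day (2 = BID).
#' @param max_single_dose Largest allowed single dose, mg; must be a
#'   multiple of the increment.
#' @return A list of class `dosing_policy`.
#' @export
dosing_policy <- function(cl_nr = 2.52, target_auc_24 = 2103.8,
                          tablet_increment = 2.5, doses_per_day = 2,
                          max_single_dose = 10) {
  vals <- c(cl_nr, target_auc_24, tablet_increment, doses_per_day,
            max_single_dose)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All dosing-policy fields must be strictly positive.")
  }
  if (abs(max_single_dose / tablet_increment -
          round(max_single_dose / tablet_increment)) > 1e-9) {
    abort("`max_single_dose` must be a multiple of `tablet_increment`.")
  }
  structure(list(cl_nr = cl_nr, target_auc_24 = target_auc_24,
                 tablet_increment = tablet_increment,
                 doses_per_day = doses_per_day,
                 max_single_dose = max_single_dose),
            class = "dosing_policy")
}

## published regression of CL_TM (L/h) on filter code and flow rate (L/h)
.published_coefs <- c(intercept = 1.469, filter_code = -0.821, flow = 0.612)

#' Predict transmembrane clearance from the circuit-covariate regression
#'
#' Evaluates CL_TM = b0 + b1 x filter_code + b2 x flow_rate. By default the
#' published coefficients (intercept 1.469 L/h, filter -0.821 L/h per code
#' step, flow 0.612 L/h per L/h) are used; alternatively pass a
#' [backward_stepwise()] fit whose model contains `filter_code` and
#' `flow` terms. The value is carried unrounded downstream; only reports
#' round for display.
#'
#' @param filter Filter name ("HF1400"/"M150") or numeric code (1/2).
#' @param flow_rate Effluent flow rate, L/h; values outside \[0.5, 5\] warn
#'   (extrapolation beyond the fitted range).
#' @param fit Optional `crrt_stepfit`; default uses the published
#'   coefficients.
#' @return Predicted CL_TM, L/h (vectorised).
#' @examples
#' predict_cl_tm("HF1400", 2)   # 1.872
#' predict_cl_tm(2, 0.5)        # 0.133
#' @export
predict_cl_tm <- function(filter, flow_rate, fit = NULL) {
  code <- if (is.numeric(filter)) {
    if (any(!filter %in% c(1, 2))) abort("Filter code must be 1 or 2.")
    filter
  } else filter_code(filter)
  if (any(flow_rate < 0.5 | flow_rate > 5)) {
    warn("Flow rate outside the fitted 0.5-5 L/h range; extrapolating.")
  }
  b <- if (is.null(fit)) {
    .published_coefs
  } else {
    if (!inherits(fit, "crrt_stepfit")) abort("`fit` must be a crrt_stepfit.")
    cf <- coef(fit$model)
    needed <- c("(Intercept)", "filter_code", "flow")
    if (!all(needed %in% names(cf))) {
      abort("`fit` must retain terms `filter_code` and `flow`.")
    }
    c(intercept = unname(cf["(Intercept)"]),
      filter_code = unname(cf["filter_code"]),
      flow = unname(cf["flow"]))
  }
  unname(b["intercept"] + b["filter_code"] * code + b["flow"] * flow_rate)
}

#' Exact total daily dose matching the target exposure
#'
#' TDD (mg/day) = target AUC (converted to mg.h/L) x total clearance, with
#' CL_T = CL_TM + CL_NR.
#'
#' @param cl_tm Transmembrane clearance, L/h (>= 0).
#' @param policy A [dosing_policy()].
#' @return Exact total daily dose, mg/day (vectorised).
#' @examples
#' optimal_tdd(0.9545)  # 7.31 mg at the default policy
#' @export
optimal_tdd <- function(cl_tm, policy = dosing_policy()) {
  if (any(cl_tm < 0)) abort("`cl_tm` must be >= 0.")
  (policy$target_auc_24 / 1000) * (cl_tm + policy$cl_nr)
}

#' Round an exact daily dose to a practical regimen
#'
#' The single dose is the exact TDD divided by the administrations per day,
#' rounded to the nearest tablet increment with exact midpoints rounded
#' DOWN (the conservative direction for an anticoagulant), floored at one
#' increment. Exceeding the single-dose cap is an error, since linear PK is
#' no longer assured above it.
#'
#' @param tdd_exact Exact total daily dose, mg/day (> 0).
#' @param policy A [dosing_policy()].
#' @return One-row tibble: `single_dose` (mg) and `label` (e.g. "5 mg BID").
#' @export
round_regimen <- function(tdd_exact, policy = dosing_policy()) {
  if (any(tdd_exact <= 0)) abort("`tdd_exact` must be > 0.")
  per_dose <- tdd_exact / policy$doses_per_day
  k <- ceiling(per_dose / policy$tablet_increment - 0.5)  # half rounds down
  k <- pmax(k, 1)
  single <- k * policy$tablet_increment
  if (any(single > policy$max_single_dose + 1e-9)) {
    abort(paste0("Rounded single dose exceeds the ", policy$max_single_dose,
                 " mg cap beyond which linear PK is not assured."))
  }
  suffix <- if (policy$doses_per_day == 2) "BID" else
    paste0("x", policy$doses_per_day, "/day")
  tibble::tibble(single_dose = single,
                 label = paste0(format_mg(single), " mg ", suffix))
}

## "2.5", "5", "7.5" -- no trailing zeros
format_mg <- function(x) {
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 2))
}

#' Dose-recommendation table across flow rates
#'
#' For each flow rate and both filter types: predicted CL_TM (from the
#' regression), CL_T = CL_TM + CL_NR, the exact TDD matching the target AUC,
#' the rounded single dose, and a combined regimen label spanning the range
#' of the two per-filter rounded doses. All intermediate values are carried
#' unrounded; printed columns are display-rounded only by [write_report()].
#'
#' @param flow_rates Flow grid, L/h. Default 0.5 to 5 by 0.5.
#' @param policy A [dosing_policy()].
#' @param fit Optional `crrt_stepfit` passed to [predict_cl_tm()].
#' @return Tibble of class `crrt_dose_table`, one row per flow rate:
#'   `flow_rate`, `cl_tm_hf1400`, `cl_tm_m150`, `cl_nr`, `cl_t_hf1400`,
#'   `cl_t_m150`, `target_auc`, `tdd_hf1400`, `tdd_m150`,
#'   `dose_hf1400`, `dose_m150`, `regimen`.
#' @examples
#' dose_table()$regimen
#' @export
dose_table <- function(flow_rates = seq(0.5, 5, by = 0.5),
                       policy = dosing_policy(), fit = NULL) {
  if (!length(flow_rates)) abort("`flow_rates` must be non-empty.")
  cl_hf <- predict_cl_tm(1, flow_rates, fit)
  cl_m <- predict_cl_tm(2, flow_rates, fit)
  tdd_hf <- optimal_tdd(cl_hf, policy)
  tdd_m <- optimal_tdd(cl_m, policy)
  reg_hf <- round_regimen(tdd_hf, policy)
  reg_m <- round_regimen(tdd_m, policy)
  suffix <- if (policy$doses_per_day == 2) "BID" else
    paste0("x", policy$doses_per_day, "/day")
  regimen <- purrr::map2_chr(reg_hf$single_dose, reg_m$single_dose,
    function(a, b) {
      lo <- min(a, b); hi <- max(a, b)
      if (lo == hi) paste0(format_mg(lo), " mg ", suffix) else
        paste0(format_mg(lo), "\u2013", format_mg(hi), " mg ", suffix)
    })
  out <- tibble::tibble(
    flow_rate = flow_rates,
    cl_tm_hf1400 = cl_hf, cl_tm_m150 = cl_m,
    cl_nr = policy$cl_nr,
    cl_t_hf1400 = cl_hf + policy$cl_nr, cl_t_m150 = cl_m + policy$cl_nr,
    target_auc = policy$target_auc_24,
    tdd_hf1400 = tdd_hf, tdd_m150 = tdd_m,
    dose_hf1400 = reg_hf$single_dose, dose_m150 = reg_m$single_dose,
    regimen = regimen
  )
  class(out) <- c("crrt_dose_table", class(out))
  out
}
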