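## Sieving/saturation coefficients and transmembrane clearance.

#' Sieving and saturation coefficients
#'
#' `sieving_coefficient()` is the convective ratio SC = C_uf / C_pre used
#' during CVVH; `saturation_coefficient()` is the diffusive ratio
#' SA = 2 C_dialysate / (C_pre + C_post) used during CVVHD. Both are
#' vectorised and unitless.
#'
#' @param c_uf,c_pre,c_post,c_d Concentrations (same unit throughout).
#' @return Numeric vector of coefficients.
#' @examples
#' sieving_coefficient(61.4, 100)         # 0.614
#' saturation_coefficient(54, 100, 80)    # 0.6
#' @export
sieving_coefficient <- function(c_uf, c_pre) {
  if (any(c_pre <= 0, na.rm = TRUE)) {
    abort("Sieving coefficient undefined: pre-filter concentration must be > 0.")
  }
  c_uf / c_pre
}

#' @rdname sieving_coefficient
#' @export
saturation_coefficient <- function(c_d, c_pre, c_post) {
  if (any(c_pre + c_post <= 0, na.rm = TRUE)) {
    abort("Saturation coefficient undefined: C_pre + C_post must be > 0.")
  }
  2 * c_d / (c_pre + c_post)
}

#' Transmembrane clearance from a sieving/saturation coefficient
#'
#' For CVVHD, CL = SA x Q_d always. For CVVH the default convention is
#' CL = SC x Q_uf; with `dilution_corrected = TRUE` the pre-dilution
#' correction CL = SC x Q_uf x Q_b / (Q_b + Q_rep,pre) is applied, where
#' Q_rep,pre = dilution_split x Q_uf. The uncorrected convention is the
#' default because the published per-configuration clearances equal
#' SC x flow for every CVVH configuration, including 100% pre-dilution;
#' both conventions are available behind the explicit flag.
#'
#' @param sc_sa Sieving (CVVH) or saturation (CVVHD) coefficient.
#' @param mode "CVVH" or "CVVHD" (vectorised).
#' @param effluent_flow Effluent flow, L/h.
#' @param dilution_split Pre-filter replacement fraction (CVVH), NA for CVVHD.
#' @param blood_flow Blood flow, L/h; only used by the correction.
#' @param dilution_corrected Apply the pre-dilution correction factor?
#' @return Clearance in L/h.
#' @examples
#' cl_transmembrane(0.614, "CVVH", 2, dilution_split = 0)   # 1.228
#' cl_transmembrane(0.601, "CVVHD", 4)                      # 2.404
#' @export
cl_transmembrane <- function(sc_sa, mode, effluent_flow, dilution_split = NA,
                             blood_flow = .default_blood_flow,
                             dilution_corrected = FALSE) {
  if (any(!mode %in% .modes)) abort("`mode` must be CVVH or CVVHD.")
  base <- sc_sa * effluent_flow
  if (!dilution_corrected) return(base)
  q_rep <- ifelse(mode == "CVVH" & !is.na(dilution_split),
                  dilution_split * effluent_flow, 0)
  ifelse(mode == "CVVH",
         base * blood_flow / (blood_flow + q_rep),
         base)
}

#' Per-experiment SC/SA and transmembrane clearance (coefficient method)
#'
#' Pairs effluent (and, for CVVHD, post-filter) samples with the pre-filter
#' sample drawn at the same time, computes SC or SA at each paired time,
#' averages them into one per-experiment coefficient, and multiplies by the
#' effluent flow via [cl_transmembrane()].
#'
#' @param data Tidy sample table.
#' @param analyte Analyte to analyse (default `"apixaban"`).
#' @param dilution_corrected Apply the CVVH pre-dilution correction?
#' @param blood_flow Blood flow, L/h.
#' @return Tibble with one row per experiment: configuration columns,
#'   `sc_sa`, `cl_tm` (L/h), `method = "by_SC_SA"`, `dilution_corrected`.
#' @export
clearance_scsa <- function(data, analyte = "apixaban",
                           dilution_corrected = FALSE,
                           blood_flow = .default_blood_flow) {
  check_samples(data)
  d <- dplyr::filter(data, .data$analyte == .env$analyte)
  if (!nrow(d)) abort(paste0("No samples for analyte ", analyte))
  cfg_cols <- c("experiment_id", "replicate_id", "mode", "filter",
                "effluent_flow_L_h", "dilution_split")
  wide <- d |>
    dplyr::select(dplyr::all_of(cfg_cols), "site", "time_min", "conc_ng_mL") |>
    tidyr::pivot_wider(names_from = "site", values_from = "conc_ng_mL")
  if (!"effluent" %in% names(wide)) abort("No effluent samples found.")
  per_time <- wide |>
    dplyr::filter(!is.na(.data$effluent), !is.na(.data$pre_filter)) |>
    dplyr::mutate(sc_sa = dplyr::if_else(
      .data$mode == "CVVHD",
      saturation_coefficient(.data$effluent, .data$pre_filter,
                             .data$post_filter),
      sieving_coefficient(.data$effluent, .data$pre_filter)
    ))
  per_time |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cfg_cols))) |>
    dplyr::summarise(sc_sa = mean(.data$sc_sa), n_times = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      cl_tm = cl_transmembrane(.data$sc_sa, .data$mode,
                               .data$effluent_flow_L_h, .data$dilution_split,
                               blood_flow = blood_flow,
                               dilution_corrected = dilution_corrected),
      method = "by_SC_SA",
      dilution_corrected = dilution_corrected
    )
}

#' Per-experiment transmembrane clearance by AUC
#'
#' The primary clearance method: noncompartmental AUC to infinity of the
#' pre-filter profile, with CL_TM = dose / AUC. In this closed in vitro
#' system the circuit is the only elimination route, so total clearance and
#' transmembrane clearance coincide.
#'
#' @inheritParams nca
#' @return Tibble with one row per experiment: configuration columns,
#'   `cl_tm` (L/h), `auc_0_inf`, `auc_0_24` (ng.h/mL), `method = "by_AUC"`.
#' @export
clearance_auc <- function(data, analyte = "apixaban", dose_mg = NULL, ...) {
  res <- nca(data, analyte = analyte, dose_mg = dose_mg, ...)
  if (all(is.na(res$cl))) {
    abort("AUC-based clearance needs the dose (`dose_mg` column or argument).")
  }
  res |>
    dplyr::transmute(
      .data$experiment_id, .data$replicate_id, .data$mode, .data$filter,
      .data$effluent_flow_L_h, .data$dilution_split,
      sc_sa = NA_real_, cl_tm = .data$cl,
      auc_0_inf = .data$auc_0_inf, auc_0_24 = .data$auc_0_24,
      method = "by_AUC", dilution_corrected = NA
    )
}

#' Sieving-coefficient variants under the conventions in circulation
#'
#' During CVVH the sieving coefficient has been computed against different
#' pre-filter references across the literature: the undiluted (reservoir)
#' concentration, the diluted filter-inlet concentration, the diluted
#' concentration re-scaled by the dilution correction factor
#' (Q_b + Q_rep)/Q_b, or the mean of pre- and post-filter values. This
#' helper evaluates every variant the supplied concentrations permit;
#' variants whose inputs are missing are dropped.
#'
#' @param c_uf Effluent concentration.
#' @param c_pre_undiluted,c_pre_diluted Pre-filter concentration measured
#'   before/after the replacement-fluid junction.
#' @param c_post_undiluted,c_post_diluted Post-filter analogues.
#' @param q_rep_pre Pre-filter replacement flow, L/h.
#' @param blood_flow Blood flow, L/h.
#' @return Tibble with columns `variant`, `sc`.
#' @export
sc_variants <- function(c_uf, c_pre_undiluted = NA, c_pre_diluted = NA,
                        c_post_undiluted = NA, c_post_diluted = NA,
                        q_rep_pre = 0, blood_flow = .default_blood_flow) {
  if (is.na(c_uf)) abort("`c_uf` is required.")
  if (is.na(c_pre_undiluted) && is.na(c_pre_diluted)) {
    abort("At least one pre-filter concentration is required.")
  }
  cf <- (blood_flow + q_rep_pre) / blood_flow
  out <- tibble::tibble(
    variant = c("pre_undiluted", "pre_diluted", "pre_diluted_corrected",
                "mean_pre_post_undiluted", "mean_pre_post_diluted"),
    sc = c(
      c_uf / c_pre_undiluted,
      c_uf / c_pre_diluted,
      c_uf / (c_pre_diluted * cf),
      2 * c_uf / (c_pre_undiluted + c_post_undiluted),
      2 * c_uf / (c_pre_diluted + c_post_diluted)
    )
  )
  dplyr::filter(out, !is.na(.data$sc))
}
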