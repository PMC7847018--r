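## Hemofilter adsorption and plasma protein binding.

#' Percent of dose adsorbed to the circuit over time
#'
#' For a closed-circuit experiment (effluent rerouted to the reservoir, so
#' the circuit has no elimination route), the fraction of dose unaccounted
#' for in the reservoir at each sampling time is attributed to adsorption:
#' \deqn{\%(t) = 100 \,[1 - C(t) V / \mathrm{dose}]} with C in ng/mL, V in L
#' and dose in mg (the 1000-fold unit factor is handled internally).
#' Measurement noise can push recovery above 100\%; negative percentages are
#' preserved in the profile (with a warning) and only clipped to zero by
#' [adsorption_summary()].
#'
#' @param data Tidy sample table containing `site == "reservoir"` rows.
#' @param dose_mg Dose added to the reservoir at time zero, mg (> 0).
#'   Taken from a `dose_mg` column when omitted.
#' @param volume_L Measured reservoir + circuit volume, L (> 0).
#' @param analyte Analyte, default `"apixaban"`.
#' @return Tibble of class `crrt_adsorption`: one row per reservoir sample
#'   with `experiment_id`, `filter`, `time_min`, `conc_ng_mL`, `percent`.
#' @export
adsorption_percent <- function(data, dose_mg = NULL, volume_L,
                               analyte = "apixaban") {
  check_samples(data)
  if (missing(volume_L) || volume_L <= 0) {
    abort("`volume_L` must be a positive reservoir volume in L.")
  }
  d <- dplyr::filter(data, .data$site == "reservoir",
                     .data$analyte == .env$analyte)
  if (!nrow(d)) abort("No reservoir samples found.")
  if (is.null(dose_mg)) {
    if (!"dose_mg" %in% names(d)) abort("Provide `dose_mg`.")
  } else {
    d$dose_mg <- dose_mg
  }
  if (any(d$dose_mg <= 0)) abort("`dose_mg` must be > 0.")
  out <- d |>
    dplyr::mutate(
      recovered_mg = .data$conc_ng_mL * volume_L / 1000,
      percent = 100 * (1 - .data$recovered_mg / .data$dose_mg)
    ) |>
    dplyr::arrange(.data$experiment_id, .data$time_min) |>
    dplyr::select(dplyr::any_of(c("experiment_id", "replicate_id", "filter",
                                  "time_min", "conc_ng_mL", "percent")))
  if (any(out$percent < 0)) {
    warn("Recovered mass exceeds the dose at some times; negative adsorption reported (measurement noise).")
  }
  class(out) <- c("crrt_adsorption", class(out))
  out
}

#' Summarise an adsorption profile
#'
#' @param profile Output of [adsorption_percent()].
#' @return One row per experiment with `percent_peak` (maximum over time) and
#'   `percent_final` (last sampling time); negative values are clipped to 0
#'   here, never in the profile itself.
#' @export
adsorption_summary <- function(profile) {
  profile |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("experiment_id", "replicate_id", "filter")))) |>
    dplyr::summarise(
      percent_peak = max(pmax(.data$percent, 0)),
      percent_final = pmax(.data$percent[which.max(.data$time_min)], 0),
      .groups = "drop"
    )
}

#' Fraction of drug bound to plasma protein
#'
#' From paired total and ultrafiltrate (unbound) concentrations of contrived
#' plasma samples, the bound percentage is `100 (total - unbound) / total`.
#'
#' @param data Data frame with columns `total_ng_mL` and `unbound_ng_mL`
#'   (extra columns such as `sample_id` or a concentration `level` are kept).
#' @param tolerance Relative amount by which `unbound` may exceed `total`
#'   before an error is raised (assay noise allowance). Default 0.05.
#' @return The input with a `fraction_bound` percentage column appended.
#' @examples
#' protein_binding(data.frame(total_ng_mL = 100, unbound_ng_mL = 29.19))
#' @export
protein_binding <- function(data, tolerance = 0.05) {
  if (!all(c("total_ng_mL", "unbound_ng_mL") %in% names(data))) {
    abort("`data` needs columns total_ng_mL and unbound_ng_mL.")
  }
  if (any(data$total_ng_mL <= 0)) abort("`total_ng_mL` must be > 0.")
  if (any(data$unbound_ng_mL < 0)) abort("`unbound_ng_mL` must be >= 0.")
  if (any(data$unbound_ng_mL > data$total_ng_mL * (1 + tolerance))) {
    abort("Unbound concentration exceeds total beyond tolerance.")
  }
  dplyr::mutate(tibble::as_tibble(data),
                fraction_bound = 100 * (.data$total_ng_mL - .data$unbound_ng_mL) /
                  .data$total_ng_mL)
}

#' Summarise protein-binding fractions
#'
#' @param data Output of [protein_binding()]; if a `level` column is present
#'   the intra-assay CV is computed within each concentration level.
#' @return Tibble with `mean_bound`, `sd_bound` and `intra_assay_cv` (percent
#'   CV of the fraction bound within level, averaged across levels).
#' @export
protein_binding_summary <- function(data) {
  if (!"fraction_bound" %in% names(data)) data <- protein_binding(data)
  cv_by <- if ("level" %in% names(data)) {
    data |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(cv = 100 * sd(.data$fraction_bound) /
                         mean(.data$fraction_bound), .groups = "drop")
  } else {
    tibble::tibble(cv = 100 * sd(data$fraction_bound) /
                     mean(data$fraction_bound))
  }
  tibble::tibble(
    mean_bound = mean(data$fraction_bound),
    sd_bound = sd(data$fraction_bound),
    intra_assay_cv = mean(cv_by$cv)
  )
}
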