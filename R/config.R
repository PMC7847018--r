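## Circuit configuration and the tidy sample-table contract.

#' Columns of the tidy sample table
#'
#' One row per measured sample. `dose_mg` is optional but required for
#' AUC-based clearance; additional columns are carried through untouched.
#'
#' @format Character vector of required column names.
#' @export
sample_columns <- c(
  "experiment_id", "replicate_id", "mode", "filter", "effluent_flow_L_h",
  "dilution_split", "analyte", "site", "time_min", "conc_ng_mL"
)

.sites <- c("pre_filter", "post_filter", "effluent", "reservoir",
            "ultrafiltrate_protein")
.modes <- c("CVVH", "CVVHD")

#' Describe one CRRT circuit configuration
#'
#' Captures the knobs of a single run: mode (convective CVVH or diffusive
#' CVVHD), hemofilter, blood flow, effluent flow (ultrafiltration rate for
#' CVVH, dialysate rate for CVVHD) and, for CVVH, the fraction of replacement
#' fluid infused pre-filter (1 = 100/0%, 0.5 = 50/50%, 0 = 0/100%).
#'
#' @param mode "CVVH" or "CVVHD".
#' @param filter "HF1400" or "M150".
#' @param effluent_flow Effluent flow rate, L/h (> 0).
#' @param dilution_split Pre-filter fraction of replacement fluid in \[0, 1\];
#'   must be `NA` for CVVHD.
#' @param blood_flow Blood flow rate, L/h. Default 12 (200 mL/min).
#' @param hematocrit Fractional hematocrit, carried as metadata. Default 0.369.
#' @return A one-row tibble with the resolved configuration, including
#'   `q_rep_pre_L_h = dilution_split * effluent_flow` and `filter_code`.
#' @examples
#' circuit_config("CVVH", "HF1400", 2, dilution_split = 0.5)
#' @export
circuit_config <- function(mode, filter, effluent_flow, dilution_split = NA,
                           blood_flow = .default_blood_flow,
                           hematocrit = .default_hematocrit) {
  mode <- match.arg(mode, .modes)
  filter <- match.arg(filter, c("HF1400", "M150"))
  if (!is.numeric(effluent_flow) || effluent_flow <= 0) {
    abort("`effluent_flow` must be a positive flow in L/h.")
  }
  if (mode == "CVVHD") {
    if (!is.na(dilution_split)) {
      abort("`dilution_split` does not apply to CVVHD; leave it NA.")
    }
    q_rep <- 0
  } else {
    if (is.na(dilution_split) || dilution_split < 0 || dilution_split > 1) {
      abort("CVVH needs `dilution_split` in [0, 1].")
    }
    q_rep <- dilution_split * effluent_flow
  }
  tibble::tibble(
    mode = mode, filter = filter, filter_code = filter_code(filter),
    blood_flow_L_h = blood_flow, effluent_flow_L_h = effluent_flow,
    dilution_split = dilution_split, q_rep_pre_L_h = q_rep,
    hematocrit = hematocrit
  )
}

## internal: stop unless `data` carries the tidy sample schema
check_samples <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of samples.")
  missing <- setdiff(sample_columns, names(data))
  if (length(missing)) {
    abort(paste0("Sample table is missing required column(s): ",
                 paste(missing, collapse = ", ")), call = call)
  }
  invisible(data)
}

#' Validate a sample table against the experiment invariants
#'
#' Checks every experiment in a tidy sample table against the structural
#' invariants the pipeline assumes: non-negative concentrations, strictly
#' increasing sampling times within each series, exactly one pre-filter series
#' per analyte, paired-site times forming a subset of the pre-filter times,
#' positive effluent flow, a dilution split inside \[0, 1\] for CVVH and
#' absent for CVVHD, and known mode/filter/site labels. Findings are returned
#' as data, not raised as errors, so a whole file can be screened at once.
#'
#' @param data Tidy sample table (see [sample_columns]).
#' @return A tibble with columns `experiment_id`, `invariant`, `detail`;
#'   zero rows when the table is clean.
#' @export
validate_experiment <- function(data) {
  check_samples(data)
  findings <- list()
  note <- function(id, invariant, detail) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(experiment_id = id, invariant = invariant, detail = detail)
  }

  bad_mode <- dplyr::filter(data, !.data$mode %in% .modes)
  for (id in unique(bad_mode$experiment_id)) {
    note(id, "mode", paste0("unknown mode: ",
                            paste(unique(bad_mode$mode), collapse = ", ")))
  }
  bad_site <- dplyr::filter(data, !.data$site %in% .sites)
  for (id in unique(bad_site$experiment_id)) {
    note(id, "site", paste0("unknown site: ",
                            paste(unique(bad_site$site), collapse = ", ")))
  }

  by_exp <- split(data, data$experiment_id)
  for (id in names(by_exp)) {
    d <- by_exp[[id]]
    if (any(d$conc_ng_mL < 0, na.rm = TRUE)) {
      note(id, "non_negative_concentration",
           "concentrations must be >= 0 ng/mL")
    }
    if (any(d$effluent_flow_L_h <= 0, na.rm = TRUE)) {
      note(id, "positive_effluent_flow", "effluent flow must be > 0 L/h")
    }
    is_cvvhd <- any(d$mode == "CVVHD")
    if (is_cvvhd && any(!is.na(d$dilution_split))) {
      note(id, "dilution_split_cvvhd",
           "dilution_split must be absent (NA) when mode is CVVHD")
    }
    if (!is_cvvhd &&
        any(d$dilution_split < 0 | d$dilution_split > 1, na.rm = TRUE)) {
      note(id, "dilution_split_range", "dilution_split must lie in [0, 1]")
    }

    series <- split(d, interaction(d$analyte, d$site, drop = TRUE))
    for (nm in names(series)) {
      tt <- series[[nm]]$time_min
      if (length(tt) > 1 && any(diff(tt) <= 0)) {
        note(id, "strictly_increasing_times",
             paste0("series ", nm, " has non-increasing times"))
      }
    }
    for (an in unique(d$analyte)) {
      da <- d[d$analyte == an, , drop = FALSE]
      n_pre <- sum(da$site == "pre_filter")
      if (n_pre == 0 && any(da$site %in% c("post_filter", "effluent"))) {
        note(id, "one_pre_filter_series",
             paste0("analyte ", an, " has paired sites but no pre_filter series"))
      }
      pre_t <- da$time_min[da$site == "pre_filter"]
      for (s in c("post_filter", "effluent")) {
        st <- da$time_min[da$site == s]
        if (length(st) && length(pre_t) && !all(st %in% pre_t)) {
          note(id, "paired_times_subset",
               paste0(s, " times for ", an,
                      " are not a subset of pre_filter times"))
        }
      }
    }
  }
  if (!length(findings)) {
    return(tibble::tibble(experiment_id = character(), invariant = character(),
                          detail = character()))
  }
  dplyr::bind_rows(findings)
}
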