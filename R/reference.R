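## Published summary values for apixaban during in vitro CRRT, bundled as
## plain tibbles. These are per-configuration means reported by the source
## in vitro study (duplicate experiments per cell; raw per-sample data are
## not public). They parameterise the simulator's default study design and
## serve as comparison values in tests and reports; they are never used
## inside the estimators themselves.

#' Published per-configuration sieving/saturation coefficients
#'
#' Mean sieving coefficient (CVVH) or saturation coefficient (CVVHD) and the
#' corresponding transmembrane clearance (coefficient x flow) for apixaban
#' and the urea control, for every circuit configuration of the 24-run
#' in vitro study.
#'
#' @return Tibble: `mode`, `filter`, `effluent_flow_L_h`, `dilution_split`,
#'   `analyte`, `sc_sa`, `cl_tm`.
#' @export
apixaban_scsa_reference <- function() {
  apix <- tibble::tribble(
    ~mode, ~filter, ~effluent_flow_L_h, ~dilution_split, ~sc_sa, ~cl_tm,
    "CVVH", "HF1400", 2, 0.5, 0.608, 1.22,
    "CVVH", "HF1400", 2, 1.0, 0.531, 1.06,
    "CVVH", "HF1400", 2, 0.0, 0.614, 1.23,
    "CVVH", "HF1400", 4, 0.5, 0.622, 2.49,
    "CVVHD", "HF1400", 2, NA, 0.622, 1.24,
    "CVVHD", "HF1400", 4, NA, 0.601, 2.40,
    "CVVH", "M150", 2, 0.5, 0.612, 1.22,
    "CVVH", "M150", 2, 1.0, 0.581, 1.16,
    "CVVH", "M150", 2, 0.0, 0.603, 1.21,
    "CVVH", "M150", 4, 0.5, 0.540, 2.16,
    "CVVHD", "M150", 2, NA, 0.619, 1.24,
    "CVVHD", "M150", 4, NA, 0.555, 2.22
  )
  urea <- tibble::tribble(
    ~mode, ~filter, ~effluent_flow_L_h, ~dilution_split, ~sc_sa, ~cl_tm,
    "CVVH", "HF1400", 2, 0.5, 1.00, 2.00,
    "CVVH", "HF1400", 2, 1.0, 0.99, 1.98,
    "CVVH", "HF1400", 2, 0.0, 1.09, 2.17,
    "CVVH", "HF1400", 4, 0.5, 1.12, 4.47,
    "CVVHD", "HF1400", 2, NA, 1.23, 2.46,
    "CVVHD", "HF1400", 4, NA, 1.38, 5.53,
    "CVVH", "M150", 2, 0.5, 1.08, 2.15,
    "CVVH", "M150", 2, 1.0, 1.01, 2.02,
    "CVVH", "M150", 2, 0.0, 1.08, 2.16,
    "CVVH", "M150", 4, 0.5, 1.00, 3.98,
    "CVVHD", "M150", 2, NA, 1.19, 2.38,
    "CVVHD", "M150", 4, NA, 1.27, 5.09
  )
  dplyr::bind_rows(
    dplyr::mutate(apix, analyte = "apixaban", .before = "sc_sa"),
    dplyr::mutate(urea, analyte = "urea", .before = "sc_sa")
  )
}

#' Published per-configuration AUC-based transmembrane clearances
#'
#' Mean noncompartmental (AUC-based) transmembrane clearance of apixaban for
#' each of the twelve circuit configurations; these are the default per-cell
#' true clearances of [study_design()].
#'
#' @return Tibble: `mode`, `filter`, `effluent_flow_L_h`, `dilution_split`,
#'   `cl_tm_auc` (L/h).
#' @export
apixaban_cl_auc_reference <- function() {
  tibble::tribble(
    ~mode, ~filter, ~effluent_flow_L_h, ~dilution_split, ~cl_tm_auc,
    "CVVH", "HF1400", 2, 0.5, 1.9,
    "CVVH", "HF1400", 2, 1.0, 1.7,
    "CVVH", "HF1400", 2, 0.0, 1.9,
    "CVVH", "HF1400", 4, 0.5, 3.3,
    "CVVHD", "HF1400", 2, NA, 1.7,
    "CVVHD", "HF1400", 4, NA, 2.2,
    "CVVH", "M150", 2, 0.5, 1.6,
    "CVVH", "M150", 2, 1.0, 1.3,
    "CVVH", "M150", 2, 0.0, 1.1,
    "CVVH", "M150", 4, 0.5, 2.1,
    "CVVHD", "M150", 2, NA, 0.9,
    "CVVHD", "M150", 4, NA, 1.6
  )
}
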