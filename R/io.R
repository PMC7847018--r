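## CSV interchange. One row per measured sample; UTF-8, '.' decimal, comma
## separator, fixed header (see `sample_columns`). All computation is full
## precision; display rounding lives only in write_report().

.numeric_sample_cols <- c("effluent_flow_L_h", "dilution_split", "time_min",
                          "conc_ng_mL")

#' Read a tidy sample table from CSV
#'
#' Validates the header against [sample_columns] (a missing column is an
#' error naming it), parses the numeric columns (an unparseable number is an
#' error naming the row), and returns the rows sorted into a canonical order
#' so that reading is insensitive to row shuffling. Extra columns (e.g.
#' `dose_mg`) are preserved.
#'
#' @param path CSV file path.
#' @return Tidy sample tibble.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(sample_columns, names(raw))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  num_cols <- intersect(c(.numeric_sample_cols, "dose_mg"), names(raw))
  for (col in num_cols) {
    parsed <- suppressWarnings(readr::parse_double(raw[[col]],
                                                   na = c("", "NA")))
    probs <- readr::problems(parsed)
    if (nrow(probs)) {
      abort(paste0("Column `", col, "` has unparseable value(s) at row(s): ",
                   paste(probs$row, collapse = ", ")))
    }
    raw[[col]] <- as.numeric(parsed)
  }
  raw |>
    dplyr::arrange(.data$experiment_id, .data$analyte, .data$site,
                   .data$time_min)
}

#' @rdname read_samples
#' @param data Tidy sample tibble to write.
#' @export
write_samples <- function(data, path) {
  check_samples(data)
  readr::write_csv(data, path)
  invisible(path)
}

## column sets and printed precision per report layout
.report_layouts <- list(
  nca = list(
    required = c("experiment_id", "c_max", "c_last", "lambda_z", "t_half",
                 "vz", "cl", "auc_0_inf", "auc_0_last", "auc_0_24"),
    digits = c(c_max = 1, c_last = 1, lambda_z = 1, t_half = 1, vz = 1,
               cl = 2, auc_0_inf = 1, auc_0_last = 1, auc_0_24 = 1)
  ),
  clearance = list(
    required = c("experiment_id", "mode", "filter", "effluent_flow_L_h",
                 "sc_sa", "cl_tm"),
    digits = c(sc_sa = 3, cl_tm = 2)
  ),
  marginal_means = list(
    required = c("emmean", "lower.CL", "upper.CL"),
    digits = c(emmean = 2, lower.CL = 2, upper.CL = 2, SE = 3)
  ),
  regression = list(
    required = c("term", "estimate", "conf.low", "conf.high", "p.value"),
    digits = c(estimate = 3, conf.low = 3, conf.high = 3, p.value = 3)
  ),
  dosing = list(
    required = c("flow_rate", "cl_tm_hf1400", "cl_tm_m150", "cl_nr",
                 "cl_t_hf1400", "cl_t_m150", "target_auc", "tdd_hf1400",
                 "tdd_m150", "regimen"),
    digits = c(flow_rate = 1, cl_tm_hf1400 = 2, cl_tm_m150 = 2, cl_nr = 2,
               cl_t_hf1400 = 2, cl_t_m150 = 2, target_auc = 1,
               tdd_hf1400 = 2, tdd_m150 = 2)
  )
)

## fixed-decimal display with decimal half-away-from-zero rounding (the
## convention of the published tables); the epsilon guards against binary
## representation of exact decimal halves (e.g. 4.795 at 2 digits)
fmt_fixed <- function(x, digits) {
  sprintf("%.*f", digits, x + sign(x) * 1e-9)
}

#' Write a result table at its printed precision
#'
#' Formats a result tibble the way the corresponding report table is
#' printed (three decimals for sieving/saturation coefficients, two for
#' clearances and doses, one for concentrations and AUCs) and optionally
#' writes it as CSV. Layouts: `"nca"` (per-experiment PK parameters),
#' `"clearance"` (SC/SA and CL_TM), `"marginal_means"`, `"regression"`,
#' `"dosing"` (the flow-rate dose grid). The layout's required columns must
#' be present; computation never happens here, only formatting.
#'
#' @param results Result tibble from the corresponding pipeline step (a
#'   `crrt_anova`/`crrt_stepfit` object is also accepted for the
#'   `marginal_means`/`regression` layouts).
#' @param layout One of `"nca"`, `"clearance"`, `"marginal_means"`,
#'   `"regression"`, `"dosing"`.
#' @param path Optional CSV output path.
#' @return The formatted (character-column) tibble, invisibly if `path` is
#'   given.
#' @export
write_report <- function(results, layout = c("nca", "clearance",
                                             "marginal_means", "regression",
                                             "dosing"),
                         path = NULL) {
  layout <- match.arg(layout)
  if (inherits(results, "crrt_anova") && layout == "marginal_means") {
    results <- results$emmeans
  }
  if (inherits(results, "crrt_stepfit") && layout == "regression") {
    results <- results$coefficients
  }
  if (!is.data.frame(results) || !nrow(results)) {
    abort("`results` must be a non-empty data frame; nothing written.")
  }
  spec <- .report_layouts[[layout]]
  missing <- setdiff(spec$required, names(results))
  if (length(missing)) {
    abort(paste0("Layout `", layout, "` needs column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(results)
  for (col in intersect(names(spec$digits), names(out))) {
    out[[col]] <- ifelse(
      is.na(out[[col]]), NA_character_,
      fmt_fixed(out[[col]], spec$digits[[col]]))
  }
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}
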