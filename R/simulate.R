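## Circuit simulator: synthetic experiments with known true parameters.
## Open-circuit runs follow the one-compartment structure the analysis
## assumes (well-mixed reservoir, mono-exponential washout); closed-circuit
## runs add a reversible single-site (Langmuir-type) filter-binding sink.

.open_schedule <- c(0, 10, 20, 30, 45, 60)           # min, pre-filter
.paired_schedule <- c(10, 30)                        # min, post/effluent
.closed_schedule <- c(0, 10, 20, 30, 45, 60, 90, 105, 120, 150, 180)

## mean-unbiased multiplicative lognormal noise with the given CV
noisy <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
}

#' Simulate one open-circuit clearance experiment
#'
#' The reservoir is a single well-mixed compartment of volume `volume_L`
#' eliminated only through the circuit, so the pre-filter concentration is
#' \eqn{C(t) = C_0 e^{-(CL/V)t}} with \eqn{C_0 = dose/V}. Effluent samples
#' are `sc_true x C_pre` (CVVH) or saturate the pre/post mean at `sc_true`
#' (CVVHD); post-filter samples follow the single-pass mass balance
#' `C_post = C_pre (1 - CL / Q_plasma)` with plasma flow
#' `Q_plasma = Q_b (1 - hematocrit)`. Multiplicative lognormal noise with
#' coefficient of variation `noise_cv` is applied independently to every
#' reported sample. Urea (sieving near unity) is generated alongside as the
#' control solute.
#'
#' @param config One-row configuration from [circuit_config()].
#' @param cl_true True transmembrane clearance, L/h; must not exceed plasma
#'   flow (extraction fraction below 1).
#' @param sc_true True sieving/saturation coefficient; default
#'   `cl_true / effluent_flow`, the uncorrected convention, so both
#'   clearance methods target the same value.
#' @param dose_mg Dose added to the reservoir; default targets a peak of
#'   0.104 mg/L (the mean peak after a single oral 5 mg dose in healthy
#'   adults).
#' @param volume_L Reservoir + circuit prime volume; default 1.19 L.
#' @param noise_cv Assay noise CV (fraction). Default 0.05.
#' @param seed Optional integer seed (local to this call).
#' @param schedule,paired_times Sampling times, minutes.
#' @param urea Also generate the urea control solute?
#' @param urea_sc True urea sieving/saturation coefficient. Default 1.
#' @param urea_conc0 Initial urea concentration, ng/mL. Default 75 mg/L.
#' @param experiment_id,replicate_id Labels for the output rows.
#' @return Tidy sample tibble (see [sample_columns]) with a `dose_mg`
#'   column.
#' @export
simulate_open_circuit <- function(config, cl_true, sc_true = NULL,
                                  dose_mg = NULL, volume_L = 1.19,
                                  noise_cv = 0.05, seed = NULL,
                                  schedule = .open_schedule,
                                  paired_times = .paired_schedule,
                                  urea = TRUE, urea_sc = 1,
                                  urea_conc0 = 75000,
                                  experiment_id = "exp1",
                                  replicate_id = "r1") {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(is.data.frame(config), nrow(config) == 1)
  if (cl_true <= 0) abort("`cl_true` must be > 0.")
  q_plasma <- config$blood_flow_L_h * (1 - config$hematocrit)
  if (cl_true >= q_plasma) {
    abort("`cl_true` implies an extraction fraction >= 1 (exceeds plasma flow).")
  }
  if (is.null(sc_true)) sc_true <- cl_true / config$effluent_flow_L_h
  if (is.null(dose_mg)) dose_mg <- 0.104 * volume_L
  if (!all(paired_times %in% schedule)) {
    abort("`paired_times` must be a subset of `schedule`.")
  }

  one_analyte <- function(analyte, c0, cl, coef) {
    t_h <- schedule / 60
    c_pre <- c0 * exp(-(cl / volume_L) * t_h)
    extract <- 1 - cl / q_plasma
    pt_h <- paired_times / 60
    c_pre_paired <- c0 * exp(-(cl / volume_L) * pt_h)
    c_post <- c_pre_paired * extract
    c_eff <- if (config$mode == "CVVH") {
      coef * c_pre_paired
    } else {
      coef * (c_pre_paired + c_post) / 2
    }
    dplyr::bind_rows(
      tibble::tibble(site = "pre_filter", time_min = schedule,
                     conc_ng_mL = noisy(c_pre, noise_cv)),
      tibble::tibble(site = "post_filter", time_min = paired_times,
                     conc_ng_mL = noisy(c_post, noise_cv)),
      tibble::tibble(site = "effluent", time_min = paired_times,
                     conc_ng_mL = noisy(c_eff, noise_cv))
    ) |>
      dplyr::mutate(analyte = analyte, .before = 1)
  }

  c0_apix <- mg_per_l_to_ng_per_ml(dose_mg / volume_L)
  rows <- one_analyte("apixaban", c0_apix, cl_true, sc_true)
  if (urea) {
    cl_urea <- urea_sc * config$effluent_flow_L_h
    if (cl_urea >= q_plasma) cl_urea <- 0.95 * q_plasma
    rows <- dplyr::bind_rows(rows,
                             one_analyte("urea", urea_conc0, cl_urea, urea_sc))
  }
  tibble::tibble(
    experiment_id = experiment_id, replicate_id = replicate_id,
    mode = config$mode, filter = config$filter,
    effluent_flow_L_h = config$effluent_flow_L_h,
    dilution_split = config$dilution_split,
    analyte = rows$analyte, site = rows$site, time_min = rows$time_min,
    conc_ng_mL = rows$conc_ng_mL, dose_mg = dose_mg
  )
}

#' Reversible-binding kinetic parameters for a target bound fraction
#'
#' Adsorption is modeled as reversible single-site (Langmuir-type) binding
#' to the filter: `dA/dt = k_on C (A_max - A) - k_off A` with the reservoir
#' depleted correspondingly. Given a desired equilibrium bound fraction
#' `fraction_eq` (of the dose), the off-rate consistent with `a_max` and
#' `k_on` is `k_off = k_on C_eq (A_max - A_eq) / A_eq`.
#'
#' @param fraction_eq Equilibrium bound fraction of the dose, in (0, 1).
#' @param dose_mg Dose, mg.
#' @param volume_L Reservoir volume, L.
#' @param a_max Binding capacity, mg. Default: the dose (no saturation
#'   observed at study concentrations).
#' @param k_on On-rate, 1/h per (mg/L). Default 300, placing equilibrium
#'   within the first ~10 minutes as observed for both filters.
#' @return List with `a_max`, `k_on`, `k_off`.
#' @export
adsorption_kinetics <- function(fraction_eq, dose_mg, volume_L = 1.19,
                                a_max = dose_mg, k_on = 300) {
  if (fraction_eq <= 0 || fraction_eq >= 1) {
    abort("`fraction_eq` must lie strictly between 0 and 1.")
  }
  a_eq <- fraction_eq * dose_mg
  if (a_eq >= a_max) abort("`a_max` must exceed the equilibrium bound mass.")
  c_eq <- (dose_mg - a_eq) / volume_L
  list(a_max = a_max, k_on = k_on,
       k_off = k_on * c_eq * (a_max - a_eq) / a_eq)
}

#' Simulate one closed-circuit adsorption experiment
#'
#' Effluent is rerouted to the reservoir so the circuit has no elimination
#' route; the only sink is reversible filter binding. The coupled system
#' `dC/dt = (-k_on C (A_max - A) + k_off A) / V`,
#' `dA/dt = k_on C (A_max - A) - k_off A` (C in mg/L, A in mg) is integrated
#' over 180 min and sampled at the closed-circuit schedule; total mass
#' `C V + A` is conserved to integrator tolerance.
#'
#' @param filter Filter label carried into the output.
#' @param dose_mg Dose, mg; default targets a 0.104 mg/L initial
#'   concentration.
#' @param volume_L Reservoir volume, L.
#' @param a_max,k_on,k_off Binding parameters (see [adsorption_kinetics()]).
#' @param noise_cv Assay noise CV. Default 0.
#' @param seed Optional integer seed.
#' @param schedule Sampling times, minutes.
#' @param experiment_id,replicate_id Labels.
#' @return Tidy sample tibble with `site == "reservoir"` rows and a
#'   `dose_mg` column (mode "CVVH", effluent flow 2 L/h, 50/50% split: the
#'   circuit settings used for the adsorption runs).
#' @export
simulate_closed_circuit <- function(filter = "HF1400", dose_mg = NULL,
                                    volume_L = 1.19, a_max, k_on, k_off,
                                    noise_cv = 0, seed = NULL,
                                    schedule = .closed_schedule,
                                    experiment_id = "ads1",
                                    replicate_id = "r1") {
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(dose_mg)) dose_mg <- 0.104 * volume_L
  if (a_max == 0 && k_on > 0) {
    abort("`a_max` = 0 with a positive on-rate leaves nothing to bind to.")
  }
  rhs <- function(t, y, p) {
    flux <- p$k_on * y[1] * (p$a_max - y[2]) - p$k_off * y[2]
    list(c(-flux / p$volume, flux))
  }
  sol <- deSolve::ode(
    y = c(C = dose_mg / volume_L, A = 0),
    times = sort(unique(c(0, schedule / 60))),
    func = rhs,
    parms = list(k_on = k_on, k_off = k_off, a_max = a_max,
                 volume = volume_L),
    rtol = 1e-10, atol = 1e-12
  )
  sol <- as.data.frame(sol)
  idx <- match(schedule / 60, sol$time)
  conc <- mg_per_l_to_ng_per_ml(sol$C[idx])
  tibble::tibble(
    experiment_id = experiment_id, replicate_id = replicate_id,
    mode = "CVVH", filter = filter, effluent_flow_L_h = 2,
    dilution_split = 0.5, analyte = "apixaban", site = "reservoir",
    time_min = schedule, conc_ng_mL = noisy(conc, noise_cv),
    dose_mg = dose_mg, bound_mg = sol$A[idx]
  )
}

#' Simulate ultrafiltration protein-binding samples
#'
#' @param fraction_bound True bound percentage in \[0, 100\].
#' @param totals Total concentrations of the contrived samples, ng/mL.
#'   Default: duplicates at the simulated peak (104 ng/mL) and half-peak.
#' @param noise_cv Assay noise CV applied to the unbound measurement.
#' @param seed Optional integer seed.
#' @return Tibble with `sample_id`, `level`, `total_ng_mL`, `unbound_ng_mL`,
#'   ready for [protein_binding()].
#' @export
simulate_protein_binding <- function(fraction_bound,
                                     totals = c(104, 104, 52, 52),
                                     noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (fraction_bound < 0 || fraction_bound > 100) {
    abort("`fraction_bound` must lie in [0, 100].")
  }
  tibble::tibble(
    sample_id = paste0("pb", seq_along(totals)),
    level = factor(totals),
    total_ng_mL = totals,
    unbound_ng_mL = noisy(totals * (1 - fraction_bound / 100), noise_cv)
  )
}

#' The 24-run study design
#'
#' Twelve condition cells x two replicates: for each filter (HF1400, M150),
#' CVVH at 2 L/h with 100/0%, 50/50% and 0/100% replacement-fluid splits and
#' at 4 L/h with 50/50%, plus CVVHD at 2 and 4 L/h. Per-cell true
#' clearances default to the published per-configuration means
#' ([apixaban_cl_auc_reference()]), so downstream inference has a known
#' generating structure.
#'
#' @param cl_true Optional numeric vector of 12 per-cell true clearances
#'   (L/h) in the row order of the returned design.
#' @return Tibble with one row per experiment (24 rows): `experiment_id`,
#'   `replicate_id`, `mode`, `filter`, `effluent_flow_L_h`,
#'   `dilution_split`, `cl_true`.
#' @export
study_design <- function(cl_true = NULL) {
  cells <- dplyr::bind_rows(
    tidyr::expand_grid(filter = c("HF1400", "M150"),
                       mode = "CVVH",
                       cond = list(tibble::tibble(
                         effluent_flow_L_h = c(2, 2, 2, 4),
                         dilution_split = c(0.5, 1, 0, 0.5)))) |>
      tidyr::unnest("cond"),
    tidyr::expand_grid(filter = c("HF1400", "M150"),
                       mode = "CVVHD",
                       effluent_flow_L_h = c(2, 4)) |>
      dplyr::mutate(dilution_split = NA_real_)
  ) |>
    dplyr::arrange(.data$filter, .data$mode)
  if (is.null(cl_true)) {
    cells <- dplyr::left_join(
      cells, apixaban_cl_auc_reference(),
      by = c("mode", "filter", "effluent_flow_L_h", "dilution_split")
    ) |>
      dplyr::rename(cl_true = "cl_tm_auc")
  } else {
    if (length(cl_true) != nrow(cells)) {
      abort("`cl_true` must supply one clearance per design cell (12).")
    }
    cells$cl_true <- cl_true
  }
  out <- tidyr::expand_grid(cells, replicate_id = c("r1", "r2"))
  out$experiment_id <- paste0(
    out$mode, "_", out$filter, "_", out$effluent_flow_L_h, "Lh",
    ifelse(is.na(out$dilution_split), "",
           paste0("_", 100 * out$dilution_split, "pre")),
    "_", out$replicate_id
  )
  dplyr::select(out, "experiment_id", "replicate_id", "mode", "filter",
                "effluent_flow_L_h", "dilution_split", "cl_true")
}

#' Generate a full synthetic study
#'
#' Runs [simulate_open_circuit()] for every experiment in a design and
#' binds the results into one tidy sample table ready for the downstream
#' pipeline. All randomness flows from `seed`; the true parameters are
#' attached as the `"truth"` attribute (retrievable with [study_truth()]).
#'
#' @param design Design tibble from [study_design()] (or any tibble with its
#'   columns). Duplicate experiment ids are an error.
#' @param noise_cv Assay noise CV. Default 0.05.
#' @param seed Optional integer seed for the whole study.
#' @param volume_L,dose_mg,... Passed to [simulate_open_circuit()].
#' @return Tidy sample tibble covering all experiments.
#' @export
generate_study <- function(design = study_design(), noise_cv = 0.05,
                           seed = NULL, volume_L = 1.19, dose_mg = NULL,
                           ...) {
  if (anyDuplicated(design$experiment_id)) {
    abort("Duplicate experiment ids in `design`.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  samples <- purrr::pmap_dfr(
    dplyr::select(design, "experiment_id", "replicate_id", "mode", "filter",
                  "effluent_flow_L_h", "dilution_split", "cl_true"),
    function(experiment_id, replicate_id, mode, filter, effluent_flow_L_h,
             dilution_split, cl_true) {
      cfg <- circuit_config(mode, filter, effluent_flow_L_h,
                            dilution_split = dilution_split)
      simulate_open_circuit(cfg, cl_true = cl_true, dose_mg = dose_mg,
                            volume_L = volume_L, noise_cv = noise_cv,
                            experiment_id = experiment_id,
                            replicate_id = replicate_id, ...)
    }
  )
  attr(samples, "truth") <- design
  samples
}

#' @rdname generate_study
#' @param samples Output of [generate_study()].
#' @export
study_truth <- function(samples) attr(samples, "truth")
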