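# Fixtures built in code: noiseless one-compartment profiles and small
# sample tables used across test files.

paper_schedule <- c(0, 10, 20, 30, 45, 60)  # min

# mono-exponential pre-filter profile as a bare vector pair (time in hours)
mono_profile <- function(c0 = 100, k = 0.9, times_min = paper_schedule) {
  t_h <- times_min / 60
  list(time = t_h, conc = c0 * exp(-k * t_h))
}

# one noiseless open-circuit experiment as a tidy sample table
noiseless_experiment <- function(mode = "CVVH", filter = "HF1400",
                                 flow = 2, split = 0, cl_true = 1.9,
                                 volume = 2, dose = 0.208, ...) {
  cfg <- circuit_config(mode, filter, flow,
                        dilution_split = if (mode == "CVVH") split else NA)
  simulate_open_circuit(cfg, cl_true = cl_true, volume_L = volume,
                        dose_mg = dose, noise_cv = 0, ...)
}
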