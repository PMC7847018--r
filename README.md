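# crrtpk

Pharmacokinetics and dialytic clearance analysis for **in vitro continuous
renal replacement therapy (CRRT)** experiments, built around apixaban as the
study drug.

Critically ill patients on CRRT need anticoagulation, but the dialytic
removal of direct oral anticoagulants is poorly characterised. In vitro
circuit experiments — a blood reservoir pumped through a hemofilter in
hemofiltration (CVVH) or hemodialysis (CVVHD) mode — let the transmembrane
clearance CL\_TM be measured precisely across filter types, flow rates and
replacement-fluid dilution schemes, and translated into dose
recommendations. `crrtpk` implements that full analysis for
pharmacokineticists and clinical-pharmacology researchers working with tidy
concentration–time tables.

## What it computes

- **Noncompartmental analysis** of pre-filter profiles: terminal slope
  λz from the log-linear tail, t½ = ln 2/λz, AUC by the
  *linear-up/log-down* trapezoid (exact for mono-exponential decline),
  AUC₀₋∞ = AUC₀₋last + C_last/λz, CL = Dose/AUC₀₋∞, Vz = CL/λz.
- **Dialytic coefficients**: sieving coefficient SC = C_uf/C_pre (CVVH)
  and saturation coefficient SA = 2·C_dialysate/(C_pre + C_post) (CVVHD),
  averaged over the paired sampling times.
- **Transmembrane clearance** two ways: the primary AUC route
  (CL\_TM = Dose/AUC₀₋∞) and the coefficient route CL\_TM = SC·Q_uf or
  SA·Q_d, with the pre-dilution correction
  CL\_CVVH = SC·Q_uf·Q_b/(Q_b + Q_rep) available behind an explicit flag
  (off by default; see the vignette). `sc_variants()` enumerates the
  sieving-coefficient conventions in circulation.
- **Adsorption and protein binding**: percent of dose bound to the filter
  from closed-circuit mass balance, 100·(1 − C·V/dose), and fraction bound
  from ultrafiltration pairs, 100·(total − unbound)/total.
- **Inference**: pooled t-tests, factorial ANOVA (Type II, effect-coded)
  with estimated marginal means and Tukey HSD contrasts, and
  backward-stepwise regression of CL\_TM on circuit covariates with VIF
  diagnostics.
- **Dose optimization**: CL\_T = CL\_TM + CL\_NR (non-renal clearance
  2.52 L/h), total daily dose TDD = target AUC₀₋₂₄ × CL\_T
  (target 2103.8 ng·h/mL, the steady-state exposure of 5 mg twice daily),
  rounded to 2.5 mg tablets (midpoints down) into BID regimens.
- **Simulation**: a circuit generator with known true clearance, sieving,
  adsorption kinetics and assay noise, reproducing the 24-run study design
  (2 modes × 2 filters × flow/dilution settings × duplicates) for
  end-to-end validation.

## Worked example

Simulate the 24-run study at 5% assay noise, estimate per-experiment
clearance by AUC, regress it on the circuit covariates, and build the dose
table:

```r
library(crrtpk)

samples <- generate_study(noise_cv = 0.05, seed = 42)
cl <- clearance_auc(samples)          # one row per experiment
fit <- backward_stepwise(code_covariates(cl), "cl_tm",
                         c("mode_code", "filter_code", "flow", "dilution"))
fit
#> Backward-stepwise fit: cl_tm ~ mode_code + filter_code + flow
#> # A tibble: 4 × 7
#>   term        estimate std.error statistic       p.value conf.low conf.high
#> 1 (Intercept)    2.20     0.234       9.43 0.00000000841    1.71      2.69
#> 2 mode_code     -0.493    0.107      -4.61 0.000171        -0.717    -0.270
#> 3 filter_code   -0.702    0.0978     -7.18 0.000000594     -0.906    -0.498
#> 4 flow           0.482    0.0536      8.99 0.0000000183     0.370     0.594
#> adjusted R2 = 0.855 (alpha = 0.05; dropped: dilution)
```

Filter type (HF1400 = 1, M150 = 2) and flow rate carry most of the signal:
switching to the M150 filter lowers CL\_TM by ~0.7 L/h and each extra L/h of
effluent flow adds ~0.48 L/h, with adjusted R² 0.855. (The simulated truth
is the published per-configuration means, which also embed a mode effect —
retained here; the dilution split carries none and is dropped.)

The dose table, using the published regression coefficients
(CL\_TM = 1.469 − 0.821·filter + 0.612·flow):

```r
dose_table()[c(1, 4, 10), c("flow_rate", "cl_tm_hf1400", "cl_tm_m150",
                            "tdd_hf1400", "tdd_m150", "regimen")]
#>   flow_rate cl_tm_hf1400 cl_tm_m150 tdd_hf1400  tdd_m150      regimen
#> 1       0.5        0.954      0.133   7.308601  5.581381   2.5 mg BID
#> 2       2.0        1.872      1.051   9.239890  7.512670     5 mg BID
#> 3       5.0        3.708      2.887  13.102466 11.375247 5–7.5 mg BID
```

At 0.5 L/h a 2.5 mg BID regimen matches the exposure target; at the common
2 L/h setting the standard 5 mg BID label dose suffices; only at 5 L/h with
the high-clearance HF1400 filter does the recommendation rise to 7.5 mg
BID. `write_report(dose_table(), "dosing", "table.csv")` emits the grid at
printed precision; `autoplot()` methods plot dose tables, adsorption
profiles and regression fits.

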