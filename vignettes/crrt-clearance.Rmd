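---
title: "Dialytic clearance of apixaban in vitro: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dialytic clearance of apixaban in vitro: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crrtpk)
```

`crrtpk` analyses in vitro continuous renal replacement therapy (CRRT)
experiments: a stirred blood reservoir is pumped through a hemofilter in
hemofiltration (CVVH) or hemodialysis (CVVHD) mode, the drug is dosed into
the reservoir, and serial pre-filter, post-filter and effluent samples are
drawn. This vignette describes the models behind each pipeline stage, the
parameters that matter, what the bundled simulator does and does not
emulate, and the numerical conventions.

## The kinetic model

The circuit is treated as a single well-mixed compartment of volume $V$
whose only elimination route is the filter. A bolus dose $D$ then gives

$$C(t) = \frac{D}{V} e^{-(CL_{TM}/V)\,t},$$

so the pre-filter profile is mono-exponential and the terminal slope
estimates $\lambda_z = CL_{TM}/V$. Samples are recorded in minutes
(0, 10, 20, 30, 45, 60 for open-circuit runs); all PK arithmetic converts
to hours exactly once, at the entry to `nca()` and the clearance
functions, so rate constants are in 1/h and clearances in L/h.
Concentrations are carried in ng/mL; because dose is in mg, AUCs (ng·h/mL)
are divided by 1000 where clearance is formed:
$CL = D / (AUC_{0-\infty}/1000)$.

### Noncompartmental analysis

* **AUC** uses the linear-up/log-down trapezoid: linear rule on rising or
  flat segments or when either endpoint is zero, logarithmic rule
  $(C_i - C_{i+1})\Delta t / \ln(C_i/C_{i+1})$ on strictly decreasing
  positive segments. The log rule integrates a mono-exponential segment
  exactly, so on profiles of the assumed shape the AUC is exact on any
  sampling grid — this is verified to machine precision in the tests.
* **$\lambda_z$ selection.** With six samples over one hour there is no
  room for multi-phase fitting, so the default window is *every positive
  point after the observed peak* (`after_cmax`). A `best_r2` mode scans
  terminal windows of at least three points and keeps the best adjusted
  $r^2$, for profiles with early nonlinearity. Zero (below-quantitation)
  concentrations are excluded from the log fit but retained as linear
  endpoints in the AUC, which is standard NCA practice. A non-positive
  terminal slope yields `lambda_z = NA` and downstream quantities that
  need extrapolation refuse rather than extrapolate.
* Derived parameters: $AUC_{0-\infty} = AUC_{0-last} + C_{last}/\lambda_z$,
  $t_{1/2} = \ln 2/\lambda_z$, $V_z = CL/\lambda_z$, and
  $AUC_{0-24} = 24 \times AUC_{0-last}$ (the 1-h in vitro exposure scaled
  to a day; profiles are sampled over exactly one hour).

### Coefficients and transmembrane clearance

Sieving (convective) and saturation (diffusive) coefficients are the
empirical ratios

$$SC = C_{uf}/C_{pre}, \qquad
  SA = 2\,C_{dialysate}/(C_{pre}+C_{post}),$$

computed at each paired sampling time (10 and 30 min) and averaged into
one per-experiment value. Clearance by the coefficient route is
$CL_{TM} = SA \cdot Q_d$ for CVVHD and, for CVVH, either

* $CL_{TM} = SC \cdot Q_{uf}$ (**default**), or
* $CL_{TM} = SC \cdot Q_{uf} \cdot Q_b/(Q_b + Q_{rep,pre})$ with
  `dilution_corrected = TRUE`, where $Q_{rep,pre}$ is the pre-filter
  replacement flow.

The default is uncorrected because the published per-configuration
clearances equal $SC \times$ flow for *every* CVVH configuration including
100% pre-dilution; whether the underlying coefficients were already
dilution-corrected upstream is not decidable from the published summaries,
so both conventions sit behind an explicit flag and
`sc_variants()` enumerates the conventions found across the literature
(undiluted/diluted pre-filter reference, with/without the correction
factor, pre/post-filter mean).

### Adsorption and protein binding

Closed-circuit runs (effluent returned to the reservoir) have no
elimination route, so unrecovered mass is attributed to filter binding:

$$\%(t) = 100\,\bigl[1 - C(t)\,V/D\bigr].$$

The published form of this equation places the dose in the numerator,
which contradicts both its own percent scale and the accompanying text
definition (dose added minus amount recovered); the text definition is
implemented. Assay noise can push recovery above the dose; negative
percentages are preserved in profiles (with a warning) and clipped to zero
only in `adsorption_summary()`, keeping the noise visible where it occurs.
Because the summation scope in the published equation is ambiguous, the
package reports per-time values plus peak and final summaries and leaves
aggregation to the caller.

Protein binding is $100\,( \text{total} - \text{unbound})/\text{total}$
from ultrafiltration pairs, with a 5% default tolerance for unbound
marginally exceeding total before an error is raised.

## The statistical layer

* `two_sample_t()` is the classical pooled-variance t-test; degenerate
  zero-variance input resolves to $p = 1$ (equal means) or $p = 0$
  (unequal) by convention rather than error.
* `factorial_anova()` effect-codes the factors (sum-to-zero contrasts) and
  uses **Type II** sums of squares: the study design is balanced except
  that the point of dilution was varied only at 2 L/h, and Type II keeps
  main-effect tests clean under exactly that kind of imbalance (in the
  balanced sub-designs Types I/II/III coincide). Estimated marginal means
  with t-based intervals come from the least-squares fit; Tukey HSD
  contrasts use the studentized-range distribution with the residual mean
  square of the fitted model as the error term — the model residual is the
  only error estimate available once cells with $n = 2$ are involved.
  A constant response returns every $F = 0$ and adjusted $R^2 = 0$ by
  convention; a saturated model (no residual df) is an error naming the
  interaction to drop.
* `backward_stepwise()` removes, at each step, the covariate with the
  largest $p > \alpha$ (default 0.05) and refits until all retained
  covariates satisfy $p \le \alpha$. Ties are broken by removing the
  covariate listed *last* in the candidate order, making builds
  deterministic. Covariates are numerically coded — filter HF1400 = 1,
  M150 = 2 (matching the published coding); mode CVVH = 1, CVVHD = 2;
  dilution as the pre-filter fraction, with CVVHD coded 0 since it has no
  replacement fluid at all. In a zero-residual (perfect) fit the usual
  t-statistics are 0/0: a term whose estimate is nonzero is kept, one
  contributing nothing is removed first. An empty final model returns the
  intercept-only fit with a warning. VIF and tolerance = 1/VIF are
  reported for multi-term fits.

## Dose optimization

The exposure-matching chain is deliberately free of intermediate rounding:

$$CL_{TM}(q, f) = 1.469 - 0.821 f + 0.612 q \;\text{(L/h)}, \qquad
  CL_T = CL_{TM} + CL_{NR},$$
$$TDD = \frac{\text{target } AUC_{0-24}}{1000} \times CL_T \;\text{(mg/day)}.$$

Defaults in `dosing_policy()`: $CL_{NR} = 2.52$ L/h (non-renal clearance
imputed from phase 2/3 apixaban studies, assumed constant; residual renal
function taken as zero for CRRT patients, but exposed as a policy field),
target $AUC_{0-24} = 2103.8$ ng·h/mL (steady-state exposure of 5 mg twice
daily in healthy subjects; the target is treated as ng·h/mL ≡ µg·h/L — the
published unit label "mg·h/L" is inconsistent with its own downstream
arithmetic), 2.5 mg tablet increment, twice-daily dosing, 10 mg single-dose
cap (above which dissolution-limited absorption breaks linear PK). Single
doses round to the nearest increment with **exact midpoints rounded down**
— the conservative direction for an anticoagulant, and consistent with the
published grid's only near-midpoint cell. Display rounding (two decimals
for clearances and doses, three for coefficients) lives solely in
`write_report()` and rounds decimal halves away from zero, the convention
of the published tables.

Carrying the published three-decimal regression coefficients through this
chain reproduces the published dosing grid cell-for-cell at two decimals
with a single exception (the HF1400 total daily dose at 4 L/h computes to
11.81 against a printed 11.82), which indicates the original computation
used higher-precision coefficients than were printed; the package keeps
the printed coefficients as its defaults.

## What the simulator emulates — and what it does not

`simulate_open_circuit()` draws from the exact analytic solution of the
one-compartment model (no integrator), adds effluent samples as
$sc_{true} \times C_{pre}$ (CVVH) or saturating the pre/post mean (CVVHD),
and post-filter samples from the single-pass mass balance
$C_{post} = C_{pre}(1 - CL/Q_{plasma})$ with plasma flow
$Q_{plasma} = Q_b(1 - \text{hematocrit})$ — the plasma-flow form is a
package choice, since the generation of post-filter concentrations is not
specified by the study. Defaults mirror the study conditions: blood flow
12 L/h (200 mL/min), hematocrit 0.369, reservoir volume 1.19 L (1 L blood
plus ≈0.19 L circuit prime; the mixed volume is never stated, so it is a
parameter), dose 0.104 mg/L × V targeting the mean healthy-adult peak after
a 5 mg dose, urea at 75 mg/L as control solute with sieving near unity.
Assay noise is multiplicative lognormal, mean-unbiased, default CV 5%
(assay acceptance was ≤15% CV; observed intra-assay CVs ranged ~1–10%).
By default `sc_true = cl_true / Q_{effluent}`, the uncorrected convention,
so the AUC and coefficient routes of the pipeline target the same value.

`simulate_closed_circuit()` models filter binding as reversible
single-site (Langmuir-type) kinetics,

$$\frac{dA}{dt} = k_{on} C (A_{max} - A) - k_{off} A, \qquad
  \frac{dC}{dt} = -\frac{1}{V}\frac{dA}{dt},$$

integrated with `deSolve` at tolerances 1e-10/1e-12 so that total mass
$CV + A$ is conserved to better than 1e-8. This is the simplest mechanism
consistent with the reported phenomenology (early peak, reversibility, no
saturation evidence); `adsorption_kinetics()` solves for the off-rate
giving a requested equilibrium bound fraction, and the default on-rate
(300 h⁻¹ per mg/L) places equilibration within the first ~10 minutes, as
observed for both filters.

The 24-run `study_design()` uses the published per-configuration mean
clearances as its true values. Three features of the real data are *not*
emulated, so passing tests bound estimator error, not biological fidelity:

1. **Between-replicate variance.** Duplicate runs differ only by assay
   noise; the real duplicates showed per-cell clearance SDs up to
   ~0.7 L/h, far larger than 5% assay noise, which is unknowable from the
   published summaries ($n = 2$ per cell). Model-fit statistics on
   synthetic data are therefore tighter than on the raw data.
2. **Method discrepancy.** The generator makes the AUC and
   coefficient-based clearances agree by construction; in the real data
   the two methods diverged (notably, AUC-based clearance did not scale
   proportionally with flow).
3. **Covariate structure.** The published per-configuration means embed a
   genuine CRRT-mode effect (CVVHD cells are consistently lower at equal
   filter and flow), so a stepwise selection on data generated from them
   retains mode along with filter and flow at low noise — whereas the
   original selection on the raw data, with its much larger replicate
   variance, dropped mode. Recovery tests therefore compare against the
   coefficients of the generating projection, not the published ones.

All randomness flows from a single seed; two simulations with the same
specification are byte-identical.

## Problem sizes in the test suite

The suite validates estimator exactness at zero noise, property-style
invariants over fixed-seed grids (20 random sampling grids for AUC
additivity), Monte-Carlo unbiasedness with 200 replicates for $\lambda_z$
and protein binding, clearance recovery with 200 simulated experiments,
and end-to-end regression recovery over 100 simulated 24-run studies —
sizes chosen to keep Monte-Carlo standard errors a few-fold below the
asserted tolerances.

## Known limitations

* No membrane physics: SC/SA are empirical ratios, not transport models;
  no filter aging, clotting, or temperature effects.
* No blood-vs-plasma partitioning beyond carrying hematocrit as metadata.
* One-compartment, bolus-only PK; no absorption phase, no population
  variability.
* Closed-circuit adsorption estimates inherit the in vitro arrangement's
  bias toward maximal drug–filter contact; interpret magnitudes with care.
* The dose recommendations are exposure-matching arithmetic, not clinical
  decision support; no pharmacodynamic (anti-Xa) modeling is attempted.
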