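# nsdfrac

Compartment-specific quantification of nucleotide sugar donors (NSDs) by
digitonin fractionation — as a simulated, fully testable R workflow.

NSDs (UDP-Gal, UDP-GlcNAc, GDP-Man, GDP-Fuc, CMP-Sia) are made in the
cytoplasm (CP) and consumed in the Golgi apparatus (GA) during antibody
N-glycosylation, so whole-cell measurements hide the donor supply that
actually limits glycan processing. The workflow this package models
separates the two pools by titrating digitonin — which perforates the
cholesterol-rich plasma membrane selectively — and quantifies each
fraction by standard-addition LC-MS/MS, back-calculated to amol/cell.
`nsdfrac` is aimed at bioprocess and glycoengineering groups who want to
design, sanity-check or teach such a workflow before (or instead of)
running it on cells.

## The models at its core

* **Release sigmoid.** The released share of a cytoplasmic pool at
  digitonin concentration *x* (µg/mL) is the four-parameter logistic
  *y(x) = a + b / (1 + exp((c − x)/d))*. `release_fit()` estimates
  (a, b, c, d) by Levenberg–Marquardt least squares and returns a classed
  model object with `print`, `summary`, `coef`, `predict`, `plot`,
  `residuals` and `simulate` methods; `invert_sigmoid()` is the exact
  closed-form inverse.
* **Design point.** Literature compartment concentrations and volumes
  give relative amounts *nᵢ = cᵢVᵢ* and shares *rᵢ = nᵢ/Σn* (GA 62% /
  CP 38% with the defaults); `select_operating_digitonin()` inverts the
  fitted curve at the CP share and rounds *down* on the available
  concentration grid to protect the organelle fraction.
* **Standard addition.** `stdadd_fit()` regresses peak area on spiked
  concentration; the native vial concentration is intercept/slope, and
  `back_calculate_per_cell()` converts it through the sample's
  `dilution_chain()` to amol/cell (1 nM × 1 µL = 1000 amol, exact), with
  detection-limit flags against the 12 nM median MDL.
* **QC.** Atkinson energy charge (NTP + 0.5·NDP)/(NTP+NDP+NMP),
  triphosphate fraction, method preservation ratios, and the Q10
  cold-processing budget *t_cold = t_warm · 2^(ΔT/10)*.
* **Glycans.** Glucose-unit normalization of HILIC retention times,
  library assignment, and the arm-normalized galactosylation index
  *I_G = 100·(2·FA2G2 + FA2G1) / (2·(FA2 + FA2G1 + FA2G2))*.

A synthetic-data generator (`make_ground_truth()`,
`simulate_titration()`, `simulate_standard_addition()`,
`simulate_degradation()`, `simulate_pulse_timecourse()`,
`simulate_glycan_profiles()`) produces every input with the statistical
structure the analysis assumes, so the entire chain runs and is tested
without instrument data.

## Worked example

```r
library(nsdfrac)
report <- run_pipeline(sim_config(seed = 1))
report
```

```
Compartment-specific NSD workflow run (seed 1, noise CV 0.1)

Release sigmoid: midpoint 87.6 ug/mL, R^2 = 0.9767
Compartment model: GA 62% / CP 38% of total 1.43
Design point: exact 80.5 ug/mL -> 50 ug/mL on grid
QC: EC preservation 63.0%, triphosphate fraction pass

Quantification (amol/cell):
           analyte compartment amount_amol_per_cell mdl_flag
       UDP-Glc/Gal          CP              255.419     pass
       UDP-Glc/Gal          GA             2509.896     pass
 UDP-GlcNAc/GalNAc          CP              103.578     pass
 UDP-GlcNAc/GalNAc          GA             1401.987     pass
           CMP-Sia          CP                8.281     pass
           CMP-Sia          GA               96.657     pass
           GDP-Fuc          CP                3.899     pass
           GDP-Fuc          GA               64.807     pass
           GDP-Man          CP                1.118     pass
           GDP-Man          GA               10.708     pass

Galactosylation index per pulse condition (%):
   A    B    C 
68.8 77.2 88.1 
```

Reading it: the release curve fitted on the simulated triplicate
titration has its half-release at 87.6 µg/mL digitonin; inverting it at
the 38% cytoplasmic share of the literature compartment model gives
80.5 µg/mL, rounded down to the 50 µg/mL stock — the operating
concentration. The quantification table shows each analyte's recovered
CP and GA pools in amol/cell (at 10% measurement noise they scatter
around the generator's ground truth; with `noise_cv = 0` they match it
exactly). The QC line confirms the calibrated method contrast
(evaporation preserves 63% of the lyophilized energy charge;
lyophilization keeps >54% triphosphate). The indices show
galactose-supplemented pulsing (condition C) driving arm galactosylation
to 88%, above the medium-only (A) and fructose (B) conditions. Pass
`out_dir =` to write every stage table as CSV plus a run manifest.

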