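# nirsox

Tissue oximetry from continuous-wave near-infrared spectroscopy (CW-NIRS),
built for longitudinal monitoring of the tissue around bone implants
(biodegradable magnesium alloy vs. titanium vs. sham surgery).

CW-NIRS measures only attenuation, so absolute chromophore concentrations
are unobservable. nirsox implements the differential route: the modified
Beer–Lambert law

```
OD(λ) = −ln(I/I₀) = Σᵢ εᵢ(λ) Cᵢ · DPF(λ) · d + G
```

where the unknown geometry offset `G` cancels in the difference between two
acquisitions, leaving a linear system for the hemoglobin concentration
changes (ΔHbO₂, ΔHb). A configurable, explicitly flagged baseline
assumption then anchors a semi-quantitative tissue oxygen saturation,
StO₂ = 100·HbO₂/(HbO₂+Hb).

The package provides:

- **`chromophore_set` / `default_chromophores()`** — hemoglobin extinction
  coefficients (mM⁻¹cm⁻¹, natural-log basis) on a 650–1000 nm grid, shipped
  as a plain-text table.
- **MBLL core** — `compute_od()`, `delta_od()` (wavelength snapping, boxcar
  band extraction), `solve_concentration_changes()` (closed-form 2×2 and
  least-squares N-wavelength, condition-number guarded), `compute_sto2()`,
  `sto2_timeseries()`.
- **Synthetic study generator** — `study_design()` / `simulate_study()`
  emulate the implant experiment (15 rats, two limbs, days 0–45, planted
  group trajectories, a skin-rash case, per-limb geometry offsets, 1%
  multiplicative noise) with ground truth carried alongside, plus lossless
  plain-text study I/O (`write_study()` / `read_study()`).
- **Spectral PCA** — SNV normalization, column-centered sign-stable PCA,
  robust outlier flagging with explicit exclusion, permutation tests on
  score-space centroid distances, and timepoint-similarity comparisons.
- **Pipeline** — `run_config()` / `run_pipeline()` / `write_report()` and a
  CLI (`inst/scripts/nirs_pipeline.R`) with `simulate`, `analyze`, and
  `report` subcommands.

## Worked example

```r
library(nirsox)

report <- run_pipeline(run_config(seed = 1))
report
#> <study_report> nirsox 0.1.0, seed 1
#>   acquisitions: 180 in, 164 analyzed, 16 excluded as outliers
#>   group StO2 summary (mean +/- sd, %):
#>     Mg    d0: 69.6+/-1.2  d1: 62.4+/-8.4  d3: 71.3+/-15.4  d7: 68.6+/-2.9  d14: 68.7+/-2.3  d45: 70.2+/-1.3
#>     sham  d0: 70.1+/-1.1  d1: 65.5+/-1.6  d3: 65.1+/-1.3  d7: 65.1+/-2.0  d14: 65.9+/-0.5  d45: 66.1+/-1.5
#>     Ti    d0: 69.6+/-1.4  d1: 65.3+/-1.7  d3: 66.4+/-5.1  d7: 67.1+/-4.6  d14: 67.3+/-5.7  d45: 67.5+/-4.8
#>   skin-rash separation (days 3-14): distance 7.22, permutation p = 0.001
#>   day 0 vs day 45 score-space distance: Mg 0.339, Ti 4.11, sham 2.99
```

The report shows the three planted signatures the analysis is built to
recover: the magnesium group's strongly inflated saturation spread at days
1–3 (gas formation during early corrosion), the rash subject separating in
PCA score space at days 3–14, and magnesium spectra returning closest to
their day-0 state by day 45.

One subject's saturation series:

```r
ts <- sto2_timeseries(report$study, "Mg1", "left")
ts[, c("timepoint", "dHbO2_mM", "dHb_mM", "sto2")]
#>   timepoint  dHbO2_mM    dHb_mM sto2
#> 1         0 -2.32e-03  1.85e-03 68.0
#> 2         1 -1.84e-02  1.84e-02 51.6
#> 3         3  1.97e-02 -1.96e-02 89.6
#> 4         7 -1.40e-03 -4.96e-05 69.6
#> 5        14  6.28e-04 -1.11e-03 71.0
#> 6        45 -2.65e-05 -4.88e-05 70.0
```

From the command line:

```sh
Rscript inst/scripts/nirs_pipeline.R simulate --out study_dir --seed 7
Rscript inst/scripts/nirs_pipeline.R analyze --study study_dir --out report_dir --seed 7
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat")'
```

`tests/testthat/test-acceptance.R` holds the end-to-end property checks:
exact noise-free round trips, G-cancellation, solver equivalence, noisy
recovery calibration, the three scenario recoveries, PCA identities, and
closed-form anchors.

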