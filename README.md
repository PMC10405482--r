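# bbbpatlak

Quantification of subtle blood–brain-barrier (BBB) leakage from
dual-time-resolution dynamic contrast-enhanced (DCE) MRI, for studies of
cerebral small vessel disease (cSVD). The package implements the full
measurement chain — spoiled gradient-echo (SPGR) signal inversion, Patlak
pharmacokinetic fitting, histogram noise correction — plus the group /
plasma-VEGFA statistical layer, and a seeded synthetic-cohort generator so
the entire pipeline runs and is tested without any patient data.

Intended users: imaging scientists who need a transparent, testable
reference implementation of low-leakage DCE-MRI analysis, and
methodologists studying the behaviour of the histogram noise correction.

## The model

Tissue gadolinium concentration under slow, effectively unidirectional
transfer follows the Patlak model

    C_t(t) = K_i · ∫₀ᵗ C_p(τ) dτ + v_p · C_p(t)

where `C_p` is the vascular input function (VIF, sampled in the superior
sagittal sinus), `K_i` (min⁻¹) the leakage rate and `v_p` the
intravascular fraction. Concentration is obtained per voxel by inverting
the SPGR signal equation against the pre-contrast baseline and the T1 map,
`C = (R1(t) − R1(0)) / r1`. `(K_i, v_p)` are estimated voxel-wise by
ordinary least squares; negative `K_i` estimates are retained.

Within each tissue mask (NAWM — normal-appearing white matter, and WMH —
white matter hyperintensities) a symmetric `K_i` histogram is composed and
noise-corrected by mirroring the negative half onto the positive half and
subtracting (floored at zero per bin). The corrected histogram yields the
two subject-level biomarkers:

* **mean K_i** — count-weighted average of the surviving bins;
* **v_L** — fractional leakage volume, the remaining area under the
  corrected histogram relative to the tissue volume.

The statistical layer reports standardized-beta OLS regressions of each
MRI measure on group (control = 0 / patient = 1) and on plasma VEGFA
(within a group, after upper-tail IQR outlier removal), univariable and
age/sex-adjusted.

## Worked example

```r
library(bbbpatlak)

protocol <- acquisition_protocol()                     # 3 T SPGR, dual-time
config   <- simulation_config(n_patients = 4, n_controls = 4)
cohort   <- simulate_cohort(config, protocol)          # in memory
fitted   <- fit_cohort(cohort, protocol)
fitted[, c("subject_id", "group", "vegfa", "ki_nawm", "vl_nawm", "vl_wmh")]
```

```
  subject_id   group vegfa ki_nawm vl_nawm vl_wmh
1    sub-001 patient 43.48   1.246   0.381  0.516
2    sub-002 patient 14.75   0.928   0.359  0.590
3    sub-003 patient 17.57   0.815   0.329  0.390
4    sub-004 patient  8.40   0.780   0.249  0.392
5    sub-005 control 19.36   1.146   0.236  0.481
6    sub-006 control 19.32   1.073   0.281  0.667
7    sub-007 control  6.36   0.781   0.252  0.630
8    sub-008 control 13.65   0.998   0.382  0.444
```

`ki_nawm` is the noise-corrected mean leakage rate in NAWM in
10⁻³ min⁻¹ (white-matter values cluster around 1×10⁻³ min⁻¹); `vl_nawm`
and `vl_wmh` are the fractions of tissue voxels with detectable leakage
after the histogram correction. In this draw the patients' NAWM leakage
volume (mean 0.33) already sits above the controls' (0.29), the direction
the generator configures. `run_table1(fitted)` turns this into group
means ± SEM and standardized betas; `run_table2(fitted, "patient")` gives
the VEGFA associations.

## The analysis workflow

The `analysis/` scripts run the study end to end at the default size
(20 patients + 20 controls, 24×24×12 grids):

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic cohort -> scratch/cohort
Rscript analysis/02_fit_leakage.R       # per-subject K_i / v_L -> results/cohort_fitted.csv
Rscript analysis/03_group_report.R      # group + VEGFA tables -> results/reports/
Rscript analysis/04_calibration.R       # estimator calibration -> results/calibration.csv
```

All stages are deterministic given the configuration seed: rerunning the
chain reproduces every CSV byte for byte.

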