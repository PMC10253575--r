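# aortastiff

Simulation and analysis bench for **aortic stiffness quantification from
time-resolved aortic flow-rate curves**, of the kind produced by 4D-flow
MRI pipelines, plus the case–control statistics used to evaluate stiffness
measures diagnostically.

Aortic pulse wave velocity (PWV) — the speed at which the flow waveform
travels along the aorta — rises with wall stiffness. Measuring it from
volumetric flow MRI means estimating transit times of a few milliseconds
from curves acquired at ~34 ms temporal resolution, which is only possible
with estimators that read timing below the sample grid. This package
implements that chain end to end:

* **`synthetic data`** — parametric aortic centerline with 8 anatomical
  landmarks, gamma-variate flow waveforms propagated at a known
  ground-truth PWV (`Q_i(t) = a_i Q(t − d_i/PWV)`), acquisition emulation
  (34 ms sampling, view-shared to 50 phases, additive noise at a stated
  SNR), lumen areas and central pressures consistent with a subject's true
  distensibility, and a Gaussian-copula two-group cohort simulator whose
  marginals and pooled cross-method correlations are calibrated to
  published case–control values.
* **`transit times`** — a cross-wavelet phase estimator (analytic Morlet;
  per-cell phase converted to delay via the local instantaneous frequency;
  inverse-variance `ω²|W_a W̄_b|` weighting; coarse-to-fine phase
  unwrapping across scales), a classical intersecting-tangent foot-to-foot
  estimator, and a sub-sample normalized cross-correlation of the systolic
  complex.
* **`stiffness measures`** — multi-plane PWV from a delay-vs-distance
  least-squares fit with outlier rejection (PWV = 1/slope), two-plane PWV
  = length/transit-time, aortic distensibility ΔA/(A_min·PP) averaged over
  the ascending and descending sites, and panel assembly with per-measure
  missingness.
* **`cohort statistics`** — Shapiro–Wilk–gated t/Wilcoxon comparisons,
  Fisher's exact test, Spearman/Pearson correlation matrices, empirical
  ROC with trapezoidal AUC (= Mann–Whitney U/(n₁n₂)) and Youden-optimal
  thresholds, and a full study report.
* **`reproducible runs`** — `run_study()` writes `subjects.csv`,
  `panel.csv`, `report.json/txt` and a digest manifest; a thin CLI wrapper
  lives in `inst/scripts/aortastiff.R`.

## Worked example

Recover a known PWV from simulated curves at realistic acquisition
settings, then run the case–control analysis on a calibrated cohort:

```r
library(aortastiff)

cl     <- make_centerline(300, 200, seed = 1)          # 300 mm aorta
params <- waveform_params()                            # 1 s cycle, peak 400 mL/s
dense  <- propagate_waveform(params, cl, n_planes = 40, true_PWV = 12)
curves <- sample_and_noise(dense, effective_dt = 0.034, n_phases = 50,
                           snr_db = 20, seed = 2)
tt  <- plane_delays(curves, method = "wavelet")
fit <- pwv_from_delays(tt$arc_lengths, tt$delay,
                       reference = tt$reference_plane_index)
print(fit)
#> PWV 11.61 m/s (40 planes, residual SD 0.95 ms)
```

The true value is 12 m/s; the estimate from one noisy 50-phase realization
lands within 4%, with millisecond-level residual scatter around the
delay-distance line.

```r
spec   <- cohort_spec(copula = calibrate_copula(cohort_spec(), seed = 1))
cohort <- simulate_cohort(spec, seed = 3, mode = "A")   # 35 patients / 18 controls
report <- study_report(data.frame(group = cohort$group,
  cf_PWV = cohort$meas_cf_PWV, PWV_2D = cohort$meas_PWV_2D,
  PWV_4D = cohort$meas_PWV_4D, distensibility = cohort$meas_distensibility))
print(report)
#> Case-control study report (35 patients / 18 controls)
#>
#> Group comparisons:
#> cf_PWV: 12.33 ± 2.35 vs 9.65 ± 1.12 (t test, p = 3.143e-05)
#> PWV_2D: 11.52 ± 2.98 vs 8.23 ± 1.49 (t test, p = 5.46e-05)
#> PWV_4D: 16.30 [14.31-17.63] vs 8.54 [6.91-10.09] (wilcoxon test, p = 1.07e-09)
#> distensibility: 1.98 [1.42-2.47] vs 1.38 [1.08-2.06] (wilcoxon test, p = 0.0586)
#>
#> ROC analysis (cases vs controls):
#>   cf_PWV          AUC 0.84, threshold 10.54, sens 77.1%, spec 83.3%
#>   PWV_2D          AUC 0.83, threshold 10.43, sens 68.6%, spec 100.0%
#>   PWV_4D          AUC 0.95, threshold 13.60, sens 88.6%, spec 94.4%
#>   distensibility  AUC 0.34, threshold 6.49, sens 100.0%, spec 5.6%
#>
#> Correlation matrix:
#>                cf_PWV PWV_2D PWV_4D distensibility
#> cf_PWV           1.00   0.37   0.57           0.00
#> PWV_2D           0.37   1.00   0.57           0.00
#> PWV_4D           0.57   0.57   1.00          -0.12
#> distensibility   0.00   0.00  -0.12           1.00
```

In this single simulated cohort the multi-plane PWV separates groups best
(AUC 0.95, threshold 13.6 m/s), the pressure-based measures are weaker,
and distensibility — whose two group distributions nearly coincide — is
uninformative, as its near-null design implies. Individual cohorts of
n = 53 scatter considerably; replicate-averaged behavior is what the
acceptance script below measures.

The end-to-end runner writes all tables plus a manifest:

```r
run_study(default_config(), seed = 1, out_dir = "out/")
```

## Layout

```
R/                      implementation (geometry, waveforms, estimators,
                        cohort simulation, statistics, I/O)
tests/testthat/         unit, property and study-level tests
scripts/acceptance.R    replicate-averaged summary recomputation
inst/scripts/           command-line wrapper
inst/extdata/           default YAML configuration
vignettes/              methods vignette (models, numerical choices)
```
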