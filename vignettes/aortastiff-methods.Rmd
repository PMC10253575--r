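---
title: "Aortic stiffness from simulated 4D-flow waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic stiffness from simulated 4D-flow waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortastiff)
```

## The problem

Aortic stiffness is a marker of vascular aging and atherosclerotic disease.
Its reference clinical measure is the carotid-to-femoral pulse wave velocity
(cf PWV) from applanation tonometry; MRI offers three further measures that
focus on the central aorta: aortic distensibility from cine lumen areas and
central pulse pressure, two-plane PWV from a single slice crossing the
ascending and descending aorta, and multi-plane ("4D") PWV from flow-rate
curves sampled in many planes along the aortic centerline. The 4D measure is
attractive in stiff, diseased aortas precisely where it is hardest to
compute: the stiffer the wall, the faster the wave, the smaller the
transit times relative to the acquisition's temporal resolution
(around 34 ms for a typical 4D-flow protocol, view-shared to 50 displayed
cardiac phases).

This package implements the full quantification chain downstream of image
reconstruction — transit-time estimation, PWV fitting, distensibility, and
the case–control statistics — together with a synthetic-data generator that
produces every input with known ground truth. Since no subject-level data
are deposited for this class of study, the generator is not a fixture but
the package's measurement bench: it lets every estimator be validated
against the truth that produced its input.

## The forward model

A subject's flow waveform is a gamma-variate systolic pulse

$$Q(t) = Q_\text{base} + (Q_\text{peak}-Q_\text{base})
  \left(\frac{t-t_0}{\alpha\beta}\right)^{\alpha}
  e^{\,\alpha - (t-t_0)/\beta}, \qquad t \ge t_0,$$

with shape $\alpha = 3$, peaking at `time_to_peak` (default 150 ms) after a
100 ms upslope, plus an optional smaller, broader copy in early diastole.
Any smooth single-peaked pulse with a well-defined upslope would serve; the
gamma variate is standard for hemodynamic bolus shapes and has analytically
controllable peak time and width.

The aortic geometry is a smooth candy-cane curve (ascending limb, arch,
descending limb, slight out-of-plane bow) rescaled to a requested arc
length (200–450 mm, default 300 mm). Eight anatomical landmarks — aortic
valve, sinotubular junction, ascending aorta at the cine-slice level,
brachiocephalic bifurcation, isthmus, descending aorta at the cine-slice
level, diaphragmatic aorta, coeliac trunk — sit at fixed arc-length
fractions (0, 0.04, 0.18, 0.30, 0.42, 0.55, 0.80, 1.0). Only their ordering
matters downstream: they select the planes used by the two-plane PWV and
bound the plane extent of the multi-plane fit. Published pipelines differ
on whether analysis planes stop at the diaphragm or extend to the coeliac
trunk, so the most distal plane is a parameter (`plane_extent`, default
the coeliac trunk — the most distal landmark, matching the use of the last
abdominal plane as the reference).

Propagation is a pure delay-and-attenuate model: the plane at arc length
$d_i$ carries $Q_i(t) = (1-\lambda)^{d_i}\, Q(t - d_i/\mathrm{PWV})$,
evaluated on a 1 ms grid before any resampling, with delays wrapping
periodically within the cardiac cycle. Acquisition is emulated by sampling
at `effective_dt` (default 34 ms), linear periodic interpolation to
`n_phases` (default 50) uniform phases — a deliberately simple stand-in
for proprietary view-sharing reconstruction that reproduces the one
property that matters to the estimators, the 34 ms information loss — and
additive white Gaussian noise at a stated SNR (signal power defined as the
variance of the noise-free resampled curve; the default 20 dB means a
noise SD of one tenth of the signal SD).

What the generator does *not* emulate: velocity-to-flow integration errors,
segmentation bias, heart-rate variability within an exam, reflected waves,
and PWV varying along the aorta. Passing recovery tests on this bench
therefore demonstrates correctness of the estimation chain under the
stated noise and sampling conditions, not performance on real scanner
data.

## Transit-time estimation

Three estimators share the convention that the returned delay is positive
when the second curve lags the first, with a quality score in [0, 1].

**Cross-wavelet phase (primary).** Both curves are mean-subtracted,
peak-normalized and transformed with an analytic Morlet wavelet
($\omega_0 = 6$, 32 logarithmic scales spanning pseudo-frequencies
1–12 Hz, periodic extension — cardiac signals are cyclic). Within a time
window covering the reference upslope (10–90% of the rise, dilated one
sample) the cross-spectrum $W_a \overline{W_b}$ is formed. Three numerical
choices matter and were set by measurement against ground truth:

* *Phase-to-delay conversion.* The cross phase of a pure shift $\tau$
  equals $\tau\,\omega_{loc}$ with $\omega_{loc}$ the *local* phase
  advance rate of the signal at that cell, not the scale's nominal
  band-center frequency. Dividing by the nominal pseudo-frequency biases
  delays multiplicatively by several percent for a pulse waveform;
  dividing by the central-difference instantaneous frequency of the
  reference transform makes pure shifts exact on the dense grid.
* *Scale selection and weighting.* A cell's phase noise converts to delay
  noise as $1/\omega$, so low-frequency cells — which carry the largest
  amplitude — carry the *least* timing information per unit phase noise.
  Scales enter if their in-window amplitude reaches 10% of the maximum in
  both transforms, and cells are averaged with inverse-variance weights
  $\omega^2 |W_a \overline{W_b}|$. With the conventional
  amplitude-only weighting at a 50% gate, the per-pair delay SD at 20 dB
  was about 4 ms; with this scheme it is about 1.1 ms, close to the
  Cramér–Rao bound for these signals (~1.2 ms).
* *Wrap handling.* A fine scale at frequency $f$ can only represent
  delays up to $\pm 1/(2f)$; at physiological delays of tens of ms the
  finest scales wrap *inside* any plausible rejection band, so wrapped
  cells cannot simply be discarded. Scales are therefore processed from
  coarse to fine: the coarsest (unambiguous) scale seeds the estimate and
  each finer scale's phase is unwrapped by the nearest $2\pi k$ around
  the running weighted mean before joining it.

The quality score is the retained fraction of cross-spectral weight after
the admissibility filters.

**Intersecting-tangent foot-to-foot.** The classical estimator: each
curve's foot is the intersection of its diastolic baseline (mean of the
lowest-decile band) with the tangent at maximal systolic upslope; the
delay is the difference of foot times. Amplitude-invariant by
construction; used for cross-validation.

**Systolic cross-correlation (two-plane default).** Normalized
cross-correlation of the systolic complex, refined to sub-sample
precision. Both curves are upsampled ×8 by exact trigonometric
interpolation before correlation; parabolic interpolation of a
coarse-grid correlation alone leaves an asymmetry bias of ~0.4 ms for
skewed pulses. The correlation template spans the full systolic pulse
(the contiguous region where the rise exceeds 10% of the range): using
the rising limb alone doubles the error at 20 dB (2.5 ms vs 1.1 ms MAE
at the 34 ms acquisition) because it discards the timing information in
the peak and early downslope. The classical 10–90% upslope template
remains available (`window = "upslope"`). A correlation peak below 0.5
raises a low-quality condition.

Per-plane failures in `plane_delays()` are marked missing rather than
aborting the subject — segmentation and SNR failures are routine in this
class of acquisition — and an error is raised only when more than half
the planes fail.

## From delays to stiffness measures

**Multi-plane PWV.** Plane delays (reference = most distal plane) against
distance-to-reference are combined by ordinary least squares. The
orientation matters: the delays carry essentially all the noise, so they
must be the *response* — `delay ~ distance`, PWV = 1/slope (default).
Regressing distance on delay puts the noise in the regressor and
attenuates PWV like any errors-in-variables fit; at the noise level of
the default conditions this attenuation reached 30% at 18–20 m/s before
the wavelet estimator was tightened, and it remains the wrong orientation
on principle. The alternative is kept behind the `orientation` flag for
comparison. One outlier pass removes points beyond 2.5 residual SDs and
refits; a non-positive slope raises a non-physiological-fit error.

**Two-plane PWV** is length/transit-time between the planes nearest the
two cine-slice landmarks. **Distensibility** is
$\Delta A / (A_{min}\,PP)$ per site, averaged without weights over the
ascending and descending sites (the unweighted mean is the conventional
reading of "averaged"), reported in $10^{-3}\,\mathrm{mmHg}^{-1}$.
**cf PWV** is passed through as a device-reported scalar; simulating the
tonometric waveform would add nothing the statistics consume.

## The cohort simulator

The case–control layer needs subjects whose four measures have realistic
marginals *and* realistic cross-correlations. Marginals per group follow
the published two-group study this bench is calibrated to: normal for the
three PWVs (e.g. 4D PWV 17.3 ± 4.04 m/s in patients vs 8.69 ± 2.54 m/s
in controls), log-normal for distensibility, whose published summary is
median [IQR]; $\mu$ is set from the median exactly and $\sigma$ solves
$2\,e^\mu \sinh(z_{75}\sigma) = \mathrm{IQR}$. Within a group, the four
measures are coupled by a Gaussian copula.

The published cross-method correlations are *pooled over both groups*, so
they mix within-group association with between-group mean separation:
with the default marginals, mixture alone (independent measures within
each group) already produces a pooled Pearson correlation of ~0.39
between the 4D and cf measures. The within-group copula correlation is
therefore *calibrated*: for each targeted pair, a monotone bisection
finds the within-group value whose Monte-Carlo pooled Spearman
correlation (common random numbers, $n = 2\times10^4$, 35:18 mixing)
matches the pooled target (0.66, 0.51, −0.33 for the 4D measure against
cf, 2D, distensibility; pairs without published values stay at 0). The
assembled matrix is projected to the nearest positive semi-definite
correlation matrix if needed.

Two simulation modes are exposed. Mode A draws the measured panel
directly from the marginals — correct for statistical calibration, since
the published marginals describe measured values. Mode B drives the full
waveform pipeline with each subject's true PWV and re-estimates the
panel — the mode for recovery experiments. Auxiliary variables
(pressures, heart rate, age, LV mass index, infarct counts) are drawn
independently per group; they feed the distensibility generator and the
covariate correlation tables.

## Statistics

Group comparisons are normality-gated at $\alpha = 0.05$ (the gate level
is a convention; the underlying report states the test but no level):
Shapiro–Wilk in each group selects an unpaired t test with mean ± SD
summaries, or a Wilcoxon rank-sum test with median [IQR]; 2×2 tables use
Fisher's exact test. Paired comparisons (method vs method within
subject) use the paired t or signed-rank test through the same gate. No
multiplicity correction is applied, matching the reporting convention of
this study class. Cross-method correlation matrices default to
Spearman's $\rho$ with pairwise-complete deletion.

ROC analysis is empirical: thresholds at observed score values (the
published thresholds look like observed-value conventions, not
midpoints; a midpoint rule is a one-line change), the rule
`score >= threshold` calls a case, AUC by the rank (Mann–Whitney)
formula — identical to the trapezoidal area under the empirical curve,
which a property test asserts on random tied instances — and the
operating point maximizes Youden's J with ties broken toward the lower,
more sensitive threshold. Distensibility enters negated (stiffer walls
are *less* distensible) and its threshold is reported back on the
original scale.

## Problem sizes and numerical conventions

Simulation sizes used by the test suite and the acceptance script: 1000
replicate cohorts for AUC summaries, 200 for pooled-correlation
summaries, 100 noise seeds per level for the PWV recovery sweep
(6–20 m/s), $2\times10^4$ Monte-Carlo subjects per calibration
bisection step. These sizes put Monte-Carlo error comfortably below the
effects being measured (e.g. SE of a mean AUC over 1000 cohorts
≈ 0.001) while keeping any single experiment in the seconds-to-a-minute
range on one core.

Units are fixed throughout: time s, arc length mm (converted to m only
inside PWV computation), flow mL/s, areas mm², pressure mmHg,
distensibility $10^{-3}\,\mathrm{mmHg}^{-1}$. All generators are
deterministic under (inputs, seed); cohort subjects receive derived
child seeds so a subject's waveform realization does not depend on
cohort size.

## Known limitations

* The propagation model is a pure delay: no wave reflection, no
  dispersion, no PWV gradient along the aorta. Recovery results bound
  estimator error, not model mismatch.
* The view-sharing emulation is linear interpolation; a scanner's actual
  temporal kernel differs and is proprietary.
* The copula calibration matches pooled Spearman correlations; it does
  not constrain higher-order dependence, and pairs without published
  targets are left conditionally independent within groups.
* Log-normality of distensibility is an assumption consistent with a
  positive, right-skewed measure summarized as median [IQR]; other
  positive families (gamma) would fit the same two numbers.
* The binormal marginals make the expected cf PWV AUC ≈ 0.84; an
  empirical AUC of 0.87 as published is within sampling noise of a
  single 35/18 cohort but is not the large-sample value under these
  marginals, so replicate means should be compared against ≈ 0.84, not
  0.87.
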