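---
title: "Methods: quantifying axonal ER organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying axonal ER organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erquant)
```

`erquant` measures the organization and continuity of the axonal
endoplasmic reticulum from three kinds of raw data: intensity line profiles
drawn on confocal images, FRAP time-lapse recordings, and serial-section
electron micrographs. This vignette is the package's account of each
procedure — the model behind it, the tunable parameters and why their
defaults are what they are, the numerical choices, and what the bundled
synthetic-data generator does and does not emulate.

## Line-profile fluctuation statistics

A line drawn across an epidermal cell with an ER-lumen label crosses
discrete tubules when the network is reticular, so the sampled intensity
fluctuates; when the network is disorganized and the label diffuse, it does
not. The **local normalized variance** (NV) quantifies this: for every
trailing window of `window_px` pixels (default 10, step 1 px), the sample
variance of the intensities is divided by their mean, and the per-profile
summary is the arithmetic mean of the per-window values.

Choices worth stating explicitly:

* *Sample variance (denominator n − 1)* throughout. Windows are small
  (10 px), so the unbiased estimator matters; the measurement convention
  does not specify an estimator and this is the common image-analysis
  default.
* *Full trailing windows only*, no partial edge windows: a rolling 10-px
  window most plainly means every contiguous 10-px span, giving
  `n − window + 1` values.
* *Summary = mean of window NVs.* One fluctuation value is reported per
  cell; mean, median and sum are all defensible reductions, the mean was
  chosen, and the choice is recorded in the result's `summary_stat`
  attribute so downstream consumers can see it.
* Windows with mean intensity at or below `eps = 1e-9` are excluded from
  the summary (NV is undefined there) and counted, not silently dropped.

The variance/mean ratio of i.i.d. Poisson counts is 1 regardless of rate,
which gives the statistic an absolute calibration point; the test suite
verifies `summary NV = 1.00 ± 0.05` on Poisson(20) profiles of 10⁴ px and
exactly 0 on constant profiles.

The **coefficient of variation** (SD/mean, sample SD) is computed on raw
intensities, without background subtraction: whether the original CoV
measurements were background-subtracted is unstated, raw was chosen, and
the function documents it. The **ER/PM CoV ratio** divides the ER channel's
CoV by the plasma-membrane channel's from the same axon; it is invariant to
per-channel gain and rises above 1 when ER label is irregular against a
smooth membrane.

**Gap detection** on a 45 µm axonal profile subtracts the profile's
background level (clamping negatives to zero) and calls every maximal run of
pixels *strictly below* the threshold — default 20 on the 0–255 scale,
strict because the rule is "less than" — a gap. `gap_percent` is the
percentage of pixels in retained runs, identical to the summed interval
length over the profile length. The background estimator is the mean
intensity of a user-supplied off-axon region (mirroring the FRAP background
definition); the subtraction rule itself does not fix an estimator.
Profiles containing saturated pixels are flagged (`is_saturated`,
`saturated` attribute) rather than dropped automatically — exclusion is an
analyst's decision.

## FRAP normalization and recovery fitting

A 12 µm stretch of axon is photobleached and imaged every 5 s for 200 s.
Normalization is two-step: per frame,
`r(f) = (bleach_roi − background) / (axon_mean − background)` corrects for
acquisition-wide intensity changes; then
`N(f) = (r(f) − r_bleach) / (r_pre − r_bleach)` maps the mean pre-bleach
ratio to 1 and the first post-bleach frame to exactly 0. Design choices:
`r_pre` is the mean over **all** pre-bleach frames (reduces noise; the
recipe says "prebleaching intensity" without singular/plural), the bleach
anchor is the **single** first post-bleach frame ("bleach intensity as 0",
singular), and negative normalized values are retained unclamped so the fit
is unbiased.

Recovery is fitted by unweighted nonlinear least squares to
`I(t) = A (1 − e^(−kt))` with `t = 0` at the bleach frame, which the model
itself treats as an exact (0, 0) anchor — the bleach frame is included in
the fitted points. `A ∈ (0, 1.5]` (values above 1.1 are flagged as suspect
rather than clipped), `k > 0`, and the optimizer is multi-start with
`k₀ ∈ {0.005, 0.02, 0.1} s⁻¹`, keeping the best-residual solution; this
covers half-times from seconds to minutes and in practice makes the fit
insensitive to initialization. Flat traces (variance < 1e-8) and traces
where no start converges are *refused* as non-identifiable — a bleached
region isolated between two ER gaps produces exactly this, and reporting
numbers for it would be meaningless. `t½ = ln 2 / k` by definition, checked
to machine precision.

**Kymographs** sample each frame by bilinear interpolation at 1-px
arc-length steps along a hand-drawn polyline (positions down the rows,
frames across the columns), optionally averaging across an odd perpendicular
width. Velocity measurement is deliberately minimal — the slope between two
hand-identified (time, distance) points, signed so that increasing distance
is anterograde — because delineating a punctum track on a kymograph is a
judgment call the software should not make.

## Diffusion simulation of FRAP

`simulate_frap_diffusion` integrates 1-D diffusion of a normalized
concentration `u(x, t)` with an explicit conservative finite-difference
scheme: `u = 1` everywhere initially, `u = 0` on the bleach interval at
`t = 0`, domain ends held at 1 (the connected ER of the rest of the neuron
acts as a reservoir) or closed for conservation checks. Each listed gap
position becomes a zero-flux internal wall — the hypothesis that a gap in
ER label is a physical break in the network translates directly into a
no-flux boundary. With closed ends the scheme conserves `∫u dx` to 1e-6
(it is conservative by construction; the test verifies it), an isolated
fully-bleached segment stays exactly at zero, and a single adjacent wall
strictly lengthens the half-recovery time at identical diffusivity — the
three qualitative signatures of the photobleaching experiments.

Numerics: the stability condition `D·dt/dx² ≤ 0.5` is enforced with an
explanatory error, never silently adjusted — a caller who asks for an
unstable grid should know. Defaults `D = 2 µm²/s`, `dx = 0.15 µm`,
`dt = 0.004 s`: no diffusion coefficient is reported for the marker, and
2 µm²/s is a representative value for a fast-diffusing ER-associated
fluorescent protein; it lets the 45 µm reservoir-bounded domain approach
full recovery within the 600 s horizons used in the benchmark runs.

## Serial-section EM analysis

Sections are 60 nm thick; the standard analyzed segment is 75 sections =
4.5 µm of axon. The pipeline is:

1. **Segmentation** (`segment_section`): a pixel is a candidate when it
   exceeds the mean of its `window_px` neighborhood (default 31 px,
   computed with integral images and count-normalized edges) by an offset
   expressed in robust units — the MAD of the ROI intensities, so detection
   is invariant under affine intensity changes of a section. Connected
   components of ≥ 2 px become detections, *strong* if any pixel passes the
   strong offset (default 5 MAD), otherwise *faint* (default 2.5 MAD). The
   exact local-threshold operator of the original manual workflow is
   unspecified; mean-offset local thresholding was chosen and every
   parameter is exposed. In noiseless synthetic sections the MAD
   degenerates to zero, and the scale falls back to 1/100 of the intensity
   range (still gain-invariant). ER-dark (membrane-stained) material is
   inverted to the ER-bright convention via a polarity flag.
2. **Linking** (`link_tubule_tracks`): detections in consecutive sections
   belong to the same tubule when their masks overlap by ≥ 1 px after 1-px
   dilation — the "same position" rule with a one-pixel tolerance for
   section-to-section jitter, for which no tolerance is stated anywhere.
   Chains grow greedily by maximal overlap with a deterministic tie-break
   (lowest centroid row, then column). A tubule must persist ≥ 3
   consecutive sections. Faint detections are admitted only when they
   overlap a strong detection in an adjacent section — the faint-signal
   rescue for sections with weak staining — so an isolated faint run can
   never fabricate a tubule.
3. **Gap calling** (`call_gaps`): a gap is the complete loss of tracked ER
   from ≥ 3 consecutive sections. Absence runs touching the first or last
   section are reported but **censored** and excluded from all metrics:
   "complete loss" cannot be confirmed beyond the imaged volume. Gap length
   is exactly `n_sections × 60 nm`, with no half-section corrections.
4. **Metrics** (`axon_er_metrics`): tubules per cross-section (tracked,
   persistence-filtered tubules only; the original counts were manual, this
   automates the stated identification rule), pooled minimum Feret
   diameters, gaps per µm, percent of axon length in gaps, and a has-gap
   flag. An axon with no tracked ER at all is flagged `no_er` with `NA` gap
   metrics — undetectable ER is not a 100% gap.

The **minimum Feret diameter** is computed by rotating calipers on the
convex hull of the pixel-*corner* cloud, so a single pixel has width
exactly 1 px and never 0 — the standard particle-analysis convention. The
corner convention plus digitization biases widths upward by a sub-pixel
amount (a digital disc of radius 10 px measures ≈ 20.6 px across); the test
suite pins the implementation to a brute-force projected-width oracle at
0.5° steps to < 0.5% and verifies diameter recovery on synthetic tubules of
6, 10 and 15 px to within ±1 px.

## The statistical decision tree

`compare_groups` reproduces the test-selection rules: measurements that are
means of raw data are treated as normally distributed — two-tailed
Student's t-test for 2 groups, one-way ANOVA for 3+ — while data declared
non-normal get a two-tailed Mann-Whitney U test. The distribution class is
an **a-priori declaration** (`dist_class`), mirroring reasoning about means
versus raw counts, not an automated normality test. After a 3+ group ANOVA,
variance homogeneity is assessed by Levene's test (median-centered, α =
0.05; the homogeneity test originally used is unstated, Levene is the
robust default): equal variances select Tukey HSD, unequal select
**Dunnett's T3**, implemented here directly — pairwise Welch-type t
statistics with Satterthwaite degrees of freedom referred to the
studentized maximum modulus distribution with one variate per pair
(`P(max|T| ≤ q) = (2F_t(q) − 1)^m`), since no installed package provides
it. The Monte-Carlo check in the test suite verifies the SMM tail
probabilities against direct simulation.

**Experiment-wise pooling**: when one-way ANOVA of value against experiment
shows significant (p < 0.05) between-experiment differences within either
group, unit-level points are averaged per (group × experiment) and the two
groups compared by a two-tailed paired t-test, paired on experiment;
otherwise unit-level analysis proceeds, and in both cases the decision
trail says which happened. Zero-variance paired differences are flagged as
degenerate rather than reported as p = 0. Experiments present in only one
group are dropped with a warning. No multiplicity correction is applied
across distinct measurements, matching the original analysis, which
corrects only within post-hoc families.

Every branch decision — class, pooling, omnibus, homogeneity gate,
post-hoc — is appended to `decision_trail`, which fully determines the test
performed: re-running the same table reproduces the result bit for bit.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure each analysis stage
assumes*, with ground truth attached, under a fixed `sim_config` (seeded;
identical configs give byte-identical outputs, and the generators restore
the caller's RNG state):

* Epidermal profiles: reticular = Gaussian peaks (tubule crossings, default
  1/µm, amplitude 80, SD 0.15 µm) on a baseline; diffuse = the same
  integrated intensity redistributed by heavy Gaussian smoothing (default
  3 µm; infinite smoothing gives a flat profile). Confocal pixel size
  defaults to 0.05 µm/px — the original acquisition pixel sizes are not
  reported, so this is an explicit configuration choice, not an inference.
* Axonal profiles: plateau (background + amplitude) with background-level
  gaps and additive Gaussian noise (default SD 8 on the 0–255 scale,
  background 20).
* FRAP series: three consistent traces whose normalized recovery follows
  the single-exponential model exactly in the noiseless limit; the bleach
  is modeled as instantaneous and complete within the ROI, because the fit
  model already assumes a clean `t = 0`.
* Section stacks: tubules as bright discs (analysis accepts either
  polarity) with ≤ 1 px/section centerline jitter, per-section log-normal
  brightness factors (SD 0.2) emulating section-to-section staining and
  contrast variability, additive noise, and axon-level gaps rendered as
  complete foreground absence.

Not emulated: realistic EM texture (membranous organelles, mitochondria,
glial processes), point-spread-function blur, section alignment errors,
anti-aliased tubule boundaries, branching tubule topology within a
cross-section, and dead-ending tubules. Passing round-trip benchmarks
therefore shows the *measurement chain* is correct and calibrated on data
satisfying its assumptions — it does not show that segmentation would
survive the full complexity of real micrographs, where ROI drawing and
staining variability dominate.

## Benchmark problem sizes

The test suite and `scripts/acceptance.R` run: 10,000 random occupancy
strings against an independent run-length oracle; 500 simulated recovery
traces at 5% noise (plus exact noiseless recovery); 100 random masks
against the brute-force Feret oracle; 15 noise-free and 200 noisy
75-section stacks (64×64 px) for gap round trips; 10 stacks per diameter
for diameter recovery; 200 reticular/diffuse profile pairs; and 2,000 null
replicates per decision-tree branch for type-I error. These sizes give
Monte-Carlo standard errors comfortably below the tolerances they are
checked against.

## Known limitations

* Axon ROIs and measurement lines are user-supplied; automated axon
  segmentation and line placement are out of scope.
* Linking assumes pre-aligned sections; no registration is attempted.
* Whether per-axon tubule counts should include faint-rescued detections is
  ambiguous in the source procedure; counts here use all tracked
  detections, and raw per-section candidate counts remain available from
  `segment_section` for QC.
* The Mann-Whitney branch uses the exact distribution only where
  `stats::wilcox.test` does (small samples, no ties), falling back to the
  tie-corrected normal approximation otherwise.
* `fit_recovery` assumes the single-exponential model; reaction-dominant or
  anomalous-diffusion recoveries will fit poorly (inspect `rms`).
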