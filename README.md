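# erquant

Quantification of axonal endoplasmic reticulum (ER) organization in
*Drosophila* larvae.

Axons contain a network of smooth ER tubules that is normally continuous
along the axon. Loss of curvature-stabilizing hairpin proteins (reticulons
and REEPs — several of which are hereditary spastic paraplegia genes)
changes this network: label along axons becomes irregular, occasional
physical gaps appear, and in electron microscopy the tubules are fewer and
wider. `erquant` implements the measurements used to quantify these
phenotypes, plus a seeded synthetic-data generator with ground truth so
every stage can be exercised and benchmarked without raw microscopy:

* **Line-profile statistics** — rolling local normalized variance
  (variance/mean in 10-pixel windows, high for reticular and low for
  diffuse ER label), mean intensity, coefficient of variation
  (CoV = SD/mean), ER/plasma-membrane CoV ratio, and threshold-based gap
  detection (sub-threshold runs after background subtraction; default
  threshold 20 on the 0–255 scale).
* **FRAP kinetics** — the two-step normalization (background-subtracted
  bleach-ROI over whole-axon mean, then rescaled so pre-bleach = 1 and the
  bleach frame = 0), single-exponential recovery fitting
  `I(t) = A (1 − e^(−kt))` with mobile fraction `A`, rate constant `k` and
  `t½ = ln 2 / k`, kymograph construction along a polyline, and track-slope
  velocity arithmetic. A 1-D diffusion simulator reproduces the
  recovery-from-both-ends and no-recovery-across-a-gap phenomenology.
* **Serial-section EM** — local-threshold tubule segmentation per 60-nm
  section, linking across sections with a ≥3-section persistence rule and
  faint-signal rescue, minimum Feret diameters by rotating calipers
  (tubule outer diameter proxy), gap calling (complete loss of ER from ≥3
  consecutive sections, boundary runs censored), and per-axon metrics
  (tubules per cross-section, gaps per µm, percent length with gaps).
* **Group statistics** — the study's decision tree: Student's t-test or
  one-way ANOVA for measurements that are means of raw data, Mann-Whitney U
  otherwise; post-hoc Tukey HSD when Levene's test finds equal variances,
  Dunnett's T3 (studentized-maximum-modulus, Welch df) otherwise;
  experiment-wise pooling with paired t-tests when between-experiment
  heterogeneity is significant; two-way type-II ANOVA. Every decision is
  recorded in a replayable trail.

Everything is tibble-first: profiles, traces, gap reports, tracks and
comparison results are (or tidy into) data frames, so results chain with
dplyr and plot with the provided `autoplot()` methods.

## Worked example

Simulate a 45 µm axonal ER profile with one 9 µm gap, call gaps, then run a
FRAP fit and a serial-section EM analysis on synthetic data with known
truth:

```r
library(erquant)

cfg <- sim_config(seed = 11)   # 0.05 um/px confocal, 4 nm/px EM, noise SD 8
axon <- gen_axon_profile(45, list(c(18, 27)), amplitude = 120, config = cfg)
gaps <- detect_gaps(axon)      # threshold 20/255 after background subtraction
attr(gaps, "gap_percent")
#> [1] 19.89
as.data.frame(gaps)
#>   start_um end_um length_um start_px end_px
#> 1    18.00   26.1      8.10      361    522
#> 2    26.15   27.0      0.85      524    540
```

19.89% of the axon length is below threshold — the truth is 20% (9/45);
noise splits the called interval in two at this noise level.

```r
frap <- gen_frap_series(A = 0.8, k = 0.02,
                        config = sim_config(seed = 11, noise_sd = 5))
fit_recovery(normalize_frap(frap))
#> <frap_fit> A = 0.8419 | k = 0.01634 /s | t_half = 42.43 s | rms 0.043 | n = 41
```

The fitted mobile fraction and rate constant recover the simulated truth
(A = 0.8, k = 0.02 s⁻¹, t½ = 34.7 s) within the scatter expected at 5%
trace noise.

```r
sim <- gen_section_stack(list(n_tubules = 2, gaps = list(c(30, 36))), 75,
                         config = sim_config(seed = 11, noise_sd = 8))
res <- analyze_section_stack(sim$stack)
as.data.frame(res$gaps)
#>   z_start z_end n_sections length_nm censored
#> 1      30    36          7       420    FALSE
res$metrics[, c("mean_tubules_per_section", "mean_feret_nm",
                "gaps_per_um", "percent_length_with_gaps")]
#>   mean_tubules_per_section mean_feret_nm gaps_per_um percent_length_with_gaps
#> 1                 1.813333      39.88235   0.2222222                 9.333333
```

The 7-section truth gap is recovered at its exact coordinates
(420 nm = 7 × 60 nm), the 40 nm tubule diameter is recovered to within a
pixel, and 2 tubules × 68/75 occupied sections gives the 1.81 mean count.

Group comparison with a decision trail:

```r
df <- data.frame(value = c(rnorm(12, 10), rnorm(12, 12)),
                 group = rep(c("wt", "mutant"), each = 12))
compare_groups(df, dist_class = "normal")
#> <er_comparison> Student's t-test | groups: mutant, wt | p = ...
#> decision trail:
#>   - 2 groups; distribution class 'normal'
#>   - branch: two-tailed Student's t-test
```

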