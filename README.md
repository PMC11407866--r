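# chromadiet

Chromatic scene statistics and colour psychophysics of the visual diet.

Human visual environments vary most, chromatically, along a roughly
blue–yellow axis, and human colour discrimination is poorest along that
same axis. `chromadiet` is an R package for researchers studying this
correspondence between the statistics of the "visual diet" — the
distribution of colours a person is exposed to, sampled with calibrated
head-mounted RGB cameras — and colour perception measured in the field
with tablet-based psychophysics. It provides both analysis pathways as
tested, reusable components, together with synthetic-data generators so
the entire pipeline can be exercised and validated without access to
privacy-restricted imagery.

## What it computes

**Scene statistics.** Camera RGB → LMS → MacLeod–Boynton chromaticity
(l = L/(L+M), s = S/(L+M)); dark/saturated RAW-pixel filtering (channels
< 15 or > 15000 on the 14-bit scale); every-fifth-image subsampling;
per-image s.d. ellipses (eigendecomposition of the chromaticity
covariance); and the blue–yellow **log axis ratio**

> lar = ln( σ₋₄₅ / σ₊₄₅ ),

the log ratio of the cloud's standard deviations along the negative and
positive diagonals after normalizing the two cardinal-axis variances
(lar > 0 ⇔ blue–yellow biased). A second pathway averages pixel
saturations inside eight opponent 22.5° hue-wedge pairs, giving the
environment curve relevant to preference analysis.

**Psychophysics.** Simulated 4AFC colour-discrimination sessions — eight
hue axes, randomly interleaved multiplicative staircases (×0.5 correct,
×1.5 incorrect, two consecutive staircases of 18 reversals per axis);
maximum-likelihood logistic psychometric fits on log saturation (guess
fixed at 0.25, lapse free) with thresholds at 45% correct;
origin-centred discrimination-ellipse fits; the perceptual log axis
ratio from the normalized ellipse; and a CVD screen from the cardinal
threshold ratio. Axis-constrained chromatic Mondrian stimuli (random
rectangles, two complementary hues per stimulus) are generated and
validated. Preference rankings are simulated and analysed with mean
ranks, a 10 000-permutation null band, Spearman preference–environment
correlations, and Zou confidence intervals for differences between
dependent correlations.

## Worked example

Generate ten synthetic acquisitions with a planted chromaticity
covariance (correlation −0.46, i.e. a planted log axis ratio of
0.5·ln(1.46/0.54) ≈ 0.497), run the scene pipeline, and simulate a small
discrimination experiment:

```r
library(chromadiet)

gt <- scene_ground_truth()   # blue-yellow biased synthetic environment
scenes <- lapply(1:10, function(i)
  gen_scene_image(gt, dim = c(48, 48), seed = 100 + i)$image)
res <- run_scene_pipeline(scenes, study_config())   # analyses every 5th
res$per_image[, c("source", "n_kept", "n_dark", "log_axis_ratio")]
#>           source n_kept n_dark log_axis_ratio
#> 1 synthetic_0005   2074    115          0.494
#> 2 synthetic_0010   2074    115          0.454
```

Each analysed image recovers the planted blue–yellow bias (≈ 0.49 and
0.45 against a planted 0.497); 115 of 2304 pixels were injected dark
(5%) and are counted by the filter, never silently dropped.

```r
pop <- gen_observer_population(4, seed = 42)
exp_res <- run_experiment_pipeline(pop$observers, seed = 42)
exp_res$results[, c("observer", "n_trials", "thr_1", "log_axis_ratio")]
#>   observer n_trials  thr_1 log_axis_ratio
#> 1        1      588 0.1250          1.020
#> 2        2      604 0.0900          0.448
#> 3        3      568 0.0442          0.593
#> 4        4      554 0.0750          0.601
sapply(pop$truths, `[[`, "log_axis_ratio")
#> [1] 0.913 0.727 0.520 0.451
```

Each observer completes ~570 trials (16 staircases); fitted thresholds
(`thr_1` is the +l cardinal axis, saturation units) and perceptual log
axis ratios recover the planted blue–yellow biases up to single-session
measurement noise (s.e. ≈ 0.3 on a log axis ratio; see the vignette).

```r
band <- permutation_null_band(30, 5, n_perm = 2000, seed = 1)
round(rbind(lower = band$lower, upper = band$upper), 2)[, 1:4]
#>       [,1] [,2] [,3] [,4]
#> lower 4.14 4.13 4.13 4.14
#> upper 4.86 4.86 4.88 4.87
```

Under random responding (30 participants × 5 ranking trials), a
stimulus's mean rank stays within ≈ 4.5 ± 0.37 at the 95% level — the
null band drawn behind empirical preference curves.

See `vignettes/visual-diet-analysis.Rmd` for the full model description,
parameter defaults, and numerical choices.

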