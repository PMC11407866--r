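---
title: "Chromatic visual diets and colour psychophysics with chromadiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatic visual diets and colour psychophysics with chromadiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadiet)
```

## The scientific problem

Natural visual environments are not chromatically isotropic: across very
different habitats, pixel chromaticities vary most along a roughly
blue-yellow axis, and human colour discrimination is poorest along the same
axis. `chromadiet` implements, as a reusable and fully testable pipeline,
the two analysis pathways needed to study this correspondence between
"visual diet" and perception:

1. **Scene statistics.** Calibrated head-mounted RGB cameras sample the
   environments people actually look at. Per image, every pixel's
   chromaticity is expressed in the MacLeod-Boynton diagram
   (l = L/(L+M), s = S/(L+M)), a standard-deviation ellipse is fitted to
   the pixel cloud, and the *blue-yellow log axis ratio* — the log of the
   ratio of the cloud's extent along the negative versus the positive
   diagonal, after equating the variances of the two cardinal axes —
   quantifies the blue-yellow bias. A second pathway averages pixel
   saturations inside eight opponent hue wedges, yielding the environment
   curve against which colour preferences are compared.
2. **Psychophysics.** Colour discrimination is probed with a 4AFC task:
   a chromatic target among achromatic distractors, its saturation driven
   by multiplicative adaptive staircases along eight hue axes. Logistic
   psychometric fits give per-axis thresholds at the 45%-correct level; an
   origin-centred ellipse through the eight threshold points summarizes
   each observer, and its normalized log axis ratio quantifies the
   perceptual blue-yellow bias. Colour preferences are measured by ranking
   chromatic Mondrian patterns whose colours vary along single axes of the
   chromaticity diagram, and compared with the environment wedge curves via
   Spearman correlations, with a permutation null for rank curves and Zou
   confidence intervals for differences between dependent correlations.

Because the original head-camera images cannot be shared, the package
includes first-class synthetic-data generators that plant known chromatic
structure (scene covariances, observer ellipses, preference strengths), so
that every stage of the analysis can be exercised end-to-end and verified
by parameter recovery.

## Colour spaces and calibration

All conversions run through a device `calibration_matrix()` (camera RGB to
LMS cone excitations) and a `diagram_config()` (white point, per-axis
contrast-equating scale factors, a cone-fundamentals tag). Two diagram
instances coexist, mirroring the two tasks: a discrimination space centred
on equal-energy white and a Mondrian/preference space centred on
Illuminant C. Different cone-fundamental conventions are absorbed entirely
by the calibration matrix and config — there is one code path.

The numeric scaling constants that equate chromatic contrast across axes
belong to specific devices and fundamentals, so they are configuration
values, not code: the shipped defaults (`inst/extdata/study_config.json`)
use axis scales of 1 and a nominal white point at (l, s) = (0.6, 1.0),
chosen so that the default synthetic calibration renders the neighbourhood
of the white point with strictly positive RGB. Real analyses replace these
with measured values; every numerical result in this vignette and in the
tests is produced under the shipped synthetic configuration.

Angles are degrees externally (hue in [0, 360)), radians internally.
Achromatic points (saturation exactly 0) carry an `NA` hue rather than an
arbitrary angle.

## Scene statistics

RAW-style images are 14-bit (0..16383). Pixels are excluded when any
channel is *below* 15 (sensor noise corrupts the chromaticity estimate) or
*above* 15000 (sensor saturation); values exactly 15 or 15000 are kept,
and a pixel violating both rules is counted once, as dark, so that
kept + dark + saturated always equals the pixel count. Acquisition
sequences are thinned by `subsample_every_kth()` — indices k, 2k, ... —
the rule consistent with the published per-site subsample counts
(e.g. 1078 from 5391).

```{r counts}
counts <- acquisition_counts()
vapply(counts$n_acquired, function(n) length(subsample_every_kth(n, 5)),
       integer(1))
```

The s.d. ellipse of a cloud is the eigendecomposition of its 2x2
covariance (radii = square roots of the eigenvalues). The log axis ratio
is computed, after per-image normalization of the cardinal variances, as
the log ratio of the standard deviations of the cloud projected onto the
-45 and +45 degree unit directions. For a bivariate normal cloud with unit
cardinal variances and correlation c this equals 0.5 log((1-c)/(1+c)) — an
identity the test suite exploits as a closed-form oracle:

```{r closedform}
set.seed(1)
xy <- MASS::mvrnorm(2e4, c(0, 0), matrix(c(1, -0.6, -0.6, 1), 2))
cl <- normalize_cardinal_variances(chromaticity_cloud(xy[, 1], xy[, 2]))
c(recovered = log_axis_ratio(cl)$log_axis_ratio, closed_form = log(2))
```

Projected standard deviations are used instead of intersecting the fitted
ellipse outline with the diagonals: the two are equivalent for Gaussian
clouds and the former is directly oracle-checkable. Normalization is
per-image by default; whether to normalize per image or pooled per site is
genuinely ambiguous, so the pooled variant is available by normalizing a
concatenated cloud. Wedge statistics divide the scaled diagram into
16 half-open 22.5-degree wedges (axis k's wedge pair is centred on poles
22.5(k-1) and 22.5(k-1)+180 degrees); each chromatic pixel falls in
exactly one opponent pair, and empty pairs yield `NA` rather than 0 so
that location means are not biased downward.

## The simulated discrimination experiment

A simulated observer is a ground-truth discrimination ellipse plus a
psychometric model: P(correct) = g + (1 - g - lambda) *
logistic(beta (log s - log theta)), with guess rate g = 0.25 (4AFC), lapse
rate lambda, slope beta on log saturation, and theta the axis's true
threshold parameter (the ellipse radius along that axis direction).
Defaults (slope 3, lapse 0.02) are typical of attentive adult observers.
Distractor luminance jitter is a rendering property of the real task and
does not enter the decision model: the simulated observer responds on
chromatic saturation alone.

Staircases start at the maximum displayable saturation `s_max` (1 in
normalized units), halve saturation after a correct response, multiply it
by 1.5 after an incorrect one (clamped at `s_max`), and stop after 18
reversals, where a reversal is a change of step direction between
consecutive trials (the first trial has no direction). Two consecutive
staircases run per axis; the second continues from the first's final
saturation (`second_start = "restart"` is available). Eight axis pairs are
randomly interleaved: each trial draws its axis uniformly among the
unfinished ones. A runaway guard (10x a nominal 4-trials-per-reversal
length) converts nonterminating staircases — e.g. an always-correct
responder — into an error carrying the trial log. Everything is replayable
from one session seed.

### Threshold estimation

Thresholds are extracted by maximum-likelihood logistic fits on log
saturation with the guess rate fixed at 0.25 and the lapse rate free in
[0, 0.2]; the reported threshold is the saturation where the *fitted*
curve, lapse included, crosses 45% correct — a deliberately low criterion
because high-lapse observers may never reach conventional levels.

Staircase data concentrate near the staircase equilibrium and live on a
discrete saturation lattice. Per-axis fits with an unconstrained slope are
then prone to a step-function degeneracy: the likelihood can grow
monotonically in the slope, stranding fits at arbitrarily steep values and
inflating threshold error. `fit_session_thresholds()` therefore defaults
to a *joint session fit*: one shared slope and one shared lapse across the
observer's eight axes (an observer has a single attentional lapse rate;
slopes on log saturation vary little across hues), with a free threshold
per axis. The shared slope is box-constrained to [0.25, 15]: the upper
bound acts as regularization against the step-function mode (such fits are
accepted — at slope 15 the 45% point sits within a few percent of the
logistic midpoint), while a fit stuck at the lower bound indicates a flat,
unfittable psychometric function. Per-axis thresholds whose 45% criterion
falls outside the range of saturations actually presented are flagged
unfittable rather than extrapolated; an observer with fewer than five
fittable axes is excluded with a reason, mirroring the field practice of
excluding participants whose psychometric functions cannot be fit.
Independent per-axis fits remain available
(`share_slope = FALSE` / `fit_psychometric()`).

In simulation, even an oracle estimator with the slope and lapse fixed at
their generative values attains about 12% median relative error on the 45%
threshold under the two-staircases-per-axis trial budget; the joint fit
performs within a percentage point of that floor, against roughly 16% for
unconstrained per-axis fits.

### Ellipses and the perceptual log axis ratio

`fit_discrimination_ellipse()` fits the origin-centred conic x'Ax = 1 to
the eight points (threshold times axis direction) by linear least squares
in the form coefficients — exact whenever the points lie on an ellipse
(the stimuli are radial excursions from the white point, so a non-origin
centre is not fitted). For the *log axis ratio*, threshold points are
first rescaled so the two cardinal-axis threshold means equal 1 (the
normalized diagram), the ellipse is refitted, and the ratio of the fitted
radii along the -45 and +45 degree directions is logged. The refit
minimizes log-radial residuals with the form kept positive definite by a
Cholesky parameterization: threshold noise is multiplicative, and the
plain conic least squares would weight an underestimated threshold by the
fourth power of its inverse radius, occasionally producing wild or
indefinite fits. Both criteria agree exactly on noiseless elliptical
input. The log axis ratio is invariant to uniform scaling of all
thresholds, and — to first order — to errors in the cardinal
normalization, which perturb both diagonals symmetrically.

CVD screening computes the ratio of mean L/(L+M)-axis to mean
S/(L+M)-axis thresholds and flags outliers by Tukey fences (1.5 IQR) over
a group, the conventional exploratory rule; no diagnostic claim is
attached.

### What the observer population models

`gen_observer_population()` plants log axis ratios uniform on [-1.1, 1.1]
(diagonal axis ratios up to about 3, the upper end of published human
discrimination-ellipse elongations; both signs are included so recovery is
tested in both directions) with overall ellipse scales lognormal around
0.1. The width matters: a single session's measurement noise puts a floor
of roughly 0.25-0.3 on the standard error of a fitted log axis ratio, so
rank-order recovery (Spearman correlation between planted and fitted
ratios) is only diagnostic when the planted between-observer spread
exceeds that floor. For narrower, more homogeneous populations the rank
correlation honestly degrades — a caution that applies equally to
individual-differences analyses of real single-session data.

## Mondrian stimuli

`generate_mondrian()` paints random rectangles onto a canvas 1.5x the
stimulus per dimension and crops the centre, so no background or edge
artefacts survive; placement continues until the crop is fully covered
(cap 5000 elements, then an error reporting the coverage fraction).
Element widths and heights are drawn uniformly between 2% and 17% of the
final image size; each element's hue is one of the axis's two
complementary poles with equal probability, its saturation uniform on
[0, s_max] (the gamut cap, default 0.5) and its luminance uniform within
+/-50% of the 55 cd/m^2 mean. The element count is not fixed in advance —
full coverage is the stated guarantee. Stimuli are returned as scaled-
diagram chromaticity planes plus a luminance plane together with the
element list, and `validate_mondrian()` checks axis purity, size bounds,
luminance bounds, saturation cap and coverage; generator output must
validate clean, which the acceptance suite verifies over 400 seeded
stimuli.

```{r mondrian}
m <- generate_mondrian(3, size = 48, seed = 7)
validate_mondrian(m)
```

## Preferences, permutation null, and correlation comparisons

The ranking task is simulated as repeated best-choice: each stimulus has a
latent strength, fresh Gaussian noise is added at every choice, and the
best remaining stimulus takes the next rank (rank 1 = most preferred).
Zero noise reproduces the strength order; equal strengths give exactly
uniform random permutations. Mean ranks conserve a grand mean of 4.5 for
8 stimuli — an exact invariant used throughout the tests.

The permutation null replaces every trial of every participant with an
independent uniform random permutation (the strictest reading of "random
responding"; permuting at trial level preserves each participant's trial
count) and records per-stimulus mean ranks over 10000 permutations; the
95% band is the 2.5/97.5 percentile envelope. Preference-environment
correlations are Spearman correlations over the eight axes; mean *ranks*
are negated first so that larger always means more preferred, matching
how ratings enter. Differences between two correlations sharing the
preference vector are interval-estimated with Zou's method for
overlapping dependent correlations (Fisher-z limits per correlation,
combined using the asymptotic correlation between the two estimates; the
required environment-environment correlation is computed from the two
environment curves). Its empirical coverage is verified by simulation
against trivariate normal data.

## Numerical choices and degenerate inputs

* Filter boundary reading: "lower than 15" and "greater than 15000" are
  strict; 15 and 15000 are kept.
* Natural log everywhere an axis ratio is logged; sign and zero carry the
  inferential content and are base-invariant.
* Collinear pixel clouds yield a degenerate-flagged ellipse (minor radius
  0); zero cardinal variance makes normalization an error, not a silent
  division.
* Pixels with nonpositive L+M are flagged invalid and counted, never
  silently dropped.
* Empty wedges are `NA` with a warning; achromatic pixels belong to no
  wedge.
* All generators and simulations take explicit seeds; pipelines re-run
  byte-identically.
* Scene generation rejects out-of-gamut tail chromaticity draws and
  resamples them; a rejection rate above 1% reports the planted covariance
  itself as unrenderable. With the default 14-bit quantization, planted
  chromaticities are recovered to about 1e-4; exact (1e-6) round trips are
  available with `quantize = FALSE`.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use sizes chosen to make
each statistical check informative at comfortable desk scale: chromaticity
clouds of 1e5 points for closed-form comparisons (Monte-Carlo s.e. about
0.003 on a log axis ratio), 100 simulated observers with full sessions for
recovery statistics, 10000 permutations for the null band with 200
replicate experiments for coverage, 400 seeded Mondrians at 48 px, and
1000 replicates at n = 50 for Zou-interval coverage.

## Known limitations

* The synthetic scene model is a bivariate normal chromaticity cloud; the
  analysis consumes only second moments and wedge means, which normality
  makes analytic, but real scenes are heavy-tailed, spatially correlated
  and multi-modal. Passing recovery tests demonstrates correctness of the
  estimators, not realism of the scene model.
* The default diagram scalings are nominal; absolute wedge saturations and
  ellipse sizes are only comparable across devices after real calibration.
* The simulated observer responds on saturation alone; luminance-artifact
  strategies real participants might adopt are out of scope.
* Log-axis-ratio estimates from one session carry a ~0.3 standard error;
  group comparisons need tens of observers, and individual classification
  is unreliable — the package reports per-observer values but they should
  be aggregated.
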