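#' Ground truth for a synthetic scene image
#'
#' Describes the planted chromatic structure of a synthetic acquisition: a
#' bivariate normal cloud of MacLeod-Boynton chromaticities (the analysis
#' consumes only second moments and wedge means, both analytic under
#' normality) plus fractions of injected under- and over-exposed pixels to
#' exercise the RAW-value filters. The defaults emulate a blue-yellow biased
#' natural environment: negative l-s correlation -0.46 gives a planted log
#' axis ratio of about 0.5.
#'
#' @param mean length-2 (l, s) mean chromaticity.
#' @param cov 2x2 symmetric positive-semidefinite chromaticity covariance
#'   (MacLeod-Boynton units squared).
#' @param dark_frac,saturated_frac fractions of pixels injected below the
#'   dark threshold / above the sensor-saturation threshold.
#' @param site site label carried onto generated images.
#' @return List of class `scene_ground_truth`.
#' @export
scene_ground_truth <- function(mean = c(l = 0.6, s = 1.0),
                               cov = matrix(c(0.02^2, -0.46 * 0.02 * 0.2,
                                              -0.46 * 0.02 * 0.2, 0.2^2),
                                            2L, 2L),
                               dark_frac = 0.05, saturated_frac = 0.05,
                               site = "synthetic") {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == 2L, identical(dim(cov), c(2L, 2L)),
            abs(cov[1L, 2L] - cov[2L, 1L]) < 1e-12,
            dark_frac >= 0, dark_frac < 1,
            saturated_frac >= 0, saturated_frac < 1,
            dark_frac + saturated_frac < 1)
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values < -1e-12)) {
    stop("covariance must be positive semidefinite")
  }
  structure(list(mean = c(l = mean[1L], s = mean[2L]), cov = cov,
                 dark_frac = dark_frac, saturated_frac = saturated_frac,
                 site = site),
            class = "scene_ground_truth")
}

#' Generate a RAW-like synthetic scene image
#'
#' Draws pixel chromaticities from the planted bivariate normal, renders
#' them to camera RGB through the inverse calibration at random intensities
#' (chromaticity is invariant to the per-pixel intensity, which is rescaled
#' where needed to keep all channels inside the kept range), and injects the
#' requested fractions of dark (< `low` in every channel) and saturated
#' (> `high` in every channel) pixels at random positions. Chromaticities
#' whose rendered RGB has a nonpositive channel are outside the synthetic
#' camera gamut and raise an error reporting the extent.
#'
#' @param gt a [scene_ground_truth()].
#' @param dim length-2 integer (height, width) of the image.
#' @param cal a [calibration_matrix()].
#' @param low,high the RAW filter thresholds the injected pixels must
#'   violate (15 and 15000).
#' @param quantize round to 14-bit integers (TRUE, like a real sensor);
#'   FALSE keeps continuous values for exact round-trip checks.
#' @param seed optional integer RNG seed.
#' @return List with `image` (a [raw_image()]), `truth` (the ground truth
#'   plus realized `n_dark`, `n_saturated`, `n_chromatic`) and `chromaticities`
#'   (the planted (l, s) draws for the kept pixels, in pixel order).
#' @export
gen_scene_image <- function(gt, dim = c(64L, 64L), cal = default_calibration(),
                            low = 15, high = 15000, quantize = TRUE,
                            seed = NULL) {
  stopifnot(inherits(gt, "scene_ground_truth"), length(dim) == 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  h <- as.integer(dim[1L]); w <- as.integer(dim[2L])
  n <- h * w
  n_dark <- round(gt$dark_frac * n)
  n_sat <- round(gt$saturated_frac * n)
  n_chrom <- n - n_dark - n_sat
  if (n_chrom < 1L) stop("no chromatic pixels left after injection")
  # draw chromaticities, rejecting the (rare) tail draws outside the camera
  # gamut; a rejection rate above 1% means the planted covariance itself is
  # unrenderable and is reported as an error
  ch <- matrix(NA_real_, n_chrom, 2L)
  rgb <- matrix(NA_real_, n_chrom, 3L)
  need <- seq_len(n_chrom)
  n_rejected <- 0L
  worst <- Inf
  for (round_ in 1:50) {
    if (length(need) == 0L) break
    draw <- MASS::mvrnorm(length(need), mu = gt$mean, Sigma = gt$cov)
    if (length(need) == 1L) draw <- matrix(draw, 1L)
    cand <- render_chromaticities(draw[, 1L], draw[, 2L],
                                  stats::runif(length(need), 2000, 8000), cal)
    # a pixel is renderable when all channels are positive and its dynamic
    # range fits between the filter thresholds at some intensity
    ok <- rowSums(cand <= 0) == 0L
    ok[ok] <- apply(cand[ok, , drop = FALSE], 1L, max) /
      apply(cand[ok, , drop = FALSE], 1L, min) < (high - 1) / (low + 1)
    n_rejected <- n_rejected + sum(!ok)
    if (any(!ok)) worst <- min(worst, min(cand[!ok, ]))
    if (n_rejected > 0.01 * n_chrom + 10) {
      stop(sprintf(
        "unrenderable chromaticities: %d draws (>1%% of %d pixels) fall outside the camera gamut (worst channel %.3g)",
        n_rejected, n_chrom, worst))
    }
    ch[need[ok], ] <- draw[ok, , drop = FALSE]
    rgb[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  if (length(need) > 0L) {
    stop("unrenderable chromaticities: rejection sampling did not converge")
  }
  # intensity rescaling preserves chromaticity: L,M,S scale together
  mx <- apply(rgb, 1L, max)
  mn <- apply(rgb, 1L, min)
  lo_keep <- low + 1
  hi_keep <- high - 1
  scl <- rep(1, n_chrom)
  scl[mx > hi_keep] <- hi_keep / mx[mx > hi_keep]
  mn2 <- mn * scl
  scl[mn2 < lo_keep] <- scl[mn2 < lo_keep] * lo_keep / mn2[mn2 < lo_keep]
  rgb <- rgb * scl
  if (any(apply(rgb, 1L, max) > high) || any(apply(rgb, 1L, min) < low)) {
    stop("unrenderable chromaticities: channel dynamic range exceeds the kept RAW range")
  }
  px <- matrix(NA_real_, n, 3L)
  pos <- sample.int(n)
  i_dark <- pos[seq_len(n_dark)]
  i_sat <- pos[n_dark + seq_len(n_sat)]
  i_chrom <- pos[n_dark + n_sat + seq_len(n_chrom)]
  if (n_dark > 0L) {
    px[i_dark, ] <- matrix(stats::runif(3L * n_dark, 0, low - 1), ncol = 3L)
  }
  if (n_sat > 0L) {
    px[i_sat, ] <- matrix(stats::runif(3L * n_sat, high + 1, 16383), ncol = 3L)
  }
  px[i_chrom, ] <- rgb
  if (quantize) px <- round(px)
  arr <- array(px, dim = c(h, w, 3L))
  truth <- gt
  truth$n_dark <- n_dark
  truth$n_saturated <- n_sat
  truth$n_chromatic <- n_chrom
  list(image = raw_image(arr, site = gt$site),
       truth = truth,
       chromaticities = data.frame(l = ch[, 1L], s = ch[, 2L]))
}

#' Ground truth for a simulated observer
#'
#' A true discrimination ellipse specified by its radii along the negative
#' and positive diagonals of the normalized diagram (the blue-yellow and
#' magenta-green directions), plus the psychometric slope and lapse. The
#' planted log axis ratio is `log(diag_radii[1] / diag_radii[2])`.
#'
#' @param diag_radii length-2 positive vector: radii along the negative and
#'   positive diagonals.
#' @param slope,lapse psychometric parameters, see [observer()].
#' @return List of class `observer_ground_truth` with the 2x2 form `A`.
#' @export
observer_ground_truth <- function(diag_radii = c(0.12, 0.08), slope = 3,
                                  lapse = 0.02) {
  stopifnot(length(diag_radii) == 2L, all(diag_radii > 0), slope > 0,
            lapse >= 0, lapse <= 0.2)
  u_neg <- c(1, -1) / sqrt(2)
  u_pos <- c(1, 1) / sqrt(2)
  A <- outer(u_neg, u_neg) / diag_radii[1L]^2 +
    outer(u_pos, u_pos) / diag_radii[2L]^2
  structure(list(A = A, diag_radii = diag_radii,
                 log_axis_ratio = log(diag_radii[1L] / diag_radii[2L]),
                 slope = slope, lapse = lapse),
            class = "observer_ground_truth")
}

#' Build an observer from its ground-truth ellipse
#'
#' The true threshold along each hue axis is the radius of the ground-truth
#' ellipse along that axis direction, 1/sqrt(u'Au).
#'
#' @param gt an [observer_ground_truth()].
#' @param axes a [hue_axis_set()].
#' @return An [observer()].
#' @export
gen_observer <- function(gt, axes = hue_axis_set()) {
  stopifnot(inherits(gt, "observer_ground_truth"),
            inherits(axes, "hue_axis_set"))
  thr <- apply(axes, 1L, function(u) 1 / sqrt(drop(t(u) %*% gt$A %*% u)))
  observer(thr, slope = gt$slope, guess_rate = 0.25, lapse_rate = gt$lapse)
}

#' Generate a heterogeneous population of simulated observers
#'
#' Draws `n` observer ground truths spanning the range of blue-yellow
#' biases reported for human colour discrimination: log axis ratios uniform
#' on \[-`lar_range`, `lar_range`\] (the default 1.1 corresponds to
#' diagonal axis ratios up to about 3, the upper end of published
#' discrimination-ellipse elongations; both signs are planted so that rank
#' recovery is tested across the full range) and overall ellipse scales
#' lognormal about `scale_median`. The spread is deliberately wide: a
#' single session's threshold noise puts a floor of roughly 0.25-0.3 on the
#' standard error of a fitted log axis ratio, so rank-order recovery is
#' only diagnostic when the planted between-observer variance exceeds it.
#'
#' @param n number of observers.
#' @param lar_range half-range of planted log axis ratios.
#' @param scale_median,scale_sdlog lognormal parameters of the overall
#'   ellipse scale (geometric mean radius, saturation units).
#' @param slope,lapse psychometric parameters shared by the population.
#' @param seed optional integer RNG seed.
#' @return List with `truths` (list of [observer_ground_truth()]) and
#'   `observers` (list of [observer()]).
#' @export
gen_observer_population <- function(n = 100L, lar_range = 1.1,
                                    scale_median = 0.1, scale_sdlog = 0.3,
                                    slope = 3, lapse = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  truths <- lapply(seq_len(n), function(i) {
    lar <- stats::runif(1L, -lar_range, lar_range)
    g <- stats::rlnorm(1L, log(scale_median), scale_sdlog)
    observer_ground_truth(c(g * exp(lar / 2), g * exp(-lar / 2)),
                          slope = slope, lapse = lapse)
  })
  list(truths = truths, observers = lapply(truths, gen_observer))
}

#' Simulate a population of preference-ranking sessions
#'
#' Runs [simulate_ranking_session()] for every participant and trial. As
#' noise tends to 0 the mean ranks converge to the strength order; as noise
#' grows they converge to the uniform null (mean rank 4.5 everywhere).
#'
#' @param strengths latent strengths, one per stimulus.
#' @param noise choice noise s.d.
#' @param n_participants,n_trials population size.
#' @param seed optional integer RNG seed.
#' @return A [preference_matrix()].
#' @export
gen_preference_population <- function(strengths, noise = 1,
                                      n_participants = 24L, n_trials = 5L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_stim <- length(strengths)
  grid <- expand.grid(trial = seq_len(n_trials),
                      participant = seq_len(n_participants))
  ranks <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_ranking_session(strengths, noise)
  })
  preference_matrix(
    participant = rep(grid$participant, each = n_stim),
    trial = rep(grid$trial, each = n_stim),
    stimulus = rep(seq_len(n_stim), nrow(grid)),
    rank = unlist(ranks))
}
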