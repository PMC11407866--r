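#' RAW-style camera image
#'
#' A linear, white-balance-free camera image on the 14-bit sensor scale
#' (values 0..16383). Real acquisitions are integer-valued; synthetic images
#' may carry non-integer values to avoid quantization where tests need exact
#' round trips.
#'
#' @param pixels H x W x 3 numeric array of RAW R, G, B values in
#'   \[0, 16383\].
#' @param site optional site/location label.
#' @param timestamp optional acquisition timestamp.
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, site = NA_character_, timestamp = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("pixels must be an H x W x 3 array")
  }
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels < 0) || any(pixels > 16383)) {
    stop("pixel values must lie in [0, 16383] (14-bit scale)")
  }
  structure(list(pixels = pixels, site = site, timestamp = timestamp),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("raw_image %dx%d, site: %s\n", d[1L], d[2L],
              ifelse(is.na(x$site), "<none>", x$site)))
  invisible(x)
}

#' Every-kth subsampling of an image sequence
#'
#' Selects indices k, 2k, 3k, ... from a sequence of `n_items`, i.e. every
#' kth item, giving `floor(n_items / k)` selections. This is the rule that
#' reproduces the study's printed per-site subsample counts.
#'
#' @param n_items sequence length.
#' @param k subsampling period (default 5, every fifth image).
#' @return Integer vector of selected (1-based) indices.
#' @examples
#' length(subsample_every_kth(5391, 5))  # 1078
#' @export
subsample_every_kth <- function(n_items, k = 5L) {
  n_items <- as.integer(n_items)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (is.na(n_items) || n_items < 0L) stop("n_items must be nonnegative")
  if (n_items < k) return(integer(0))
  seq.int(k, n_items, by = k)
}

#' Valid-pixel mask for a RAW image
#'
#' A pixel is excluded as dark when any of its RAW channels is lower than
#' `low` (sensor noise dominates the chromaticity estimate) and as saturated
#' when any channel is greater than `high` (sensor gamut clipping). Values
#' exactly equal to the thresholds are kept. A pixel failing both rules is
#' counted once, as dark, so that kept + dark + saturated = total.
#'
#' @param img a [raw_image()].
#' @param low,high exclusion thresholds (defaults 15 and 15000).
#' @return A list with `mask` (H x W logical, TRUE = kept), `n_kept`,
#'   `n_dark`, `n_saturated`.
#' @export
valid_pixel_mask <- function(img, low = 15, high = 15000) {
  stopifnot(inherits(img, "raw_image"))
  if (low < 0 || high > 16383 || low > high) {
    stop("thresholds must satisfy 0 <= low <= high <= 16383")
  }
  px <- img$pixels
  dark <- px[, , 1L] < low | px[, , 2L] < low | px[, , 3L] < low
  sat <- (px[, , 1L] > high | px[, , 2L] > high | px[, , 3L] > high) & !dark
  mask <- !dark & !sat
  list(mask = mask, n_kept = sum(mask), n_dark = sum(dark),
       n_saturated = sum(sat))
}

#' Chromaticity cloud
#'
#' Per-image set of MacLeod-Boynton chromaticities with filter bookkeeping.
#'
#' @param l,s numeric vectors of chromaticity coordinates (valid points
#'   only).
#' @param n_dark,n_saturated,n_invalid counts of pixels excluded as dark,
#'   as saturated, or with nonpositive L+M.
#' @param source identifier of the source image.
#' @return An object of class `chromaticity_cloud`.
#' @export
chromaticity_cloud <- function(l, s, n_dark = 0L, n_saturated = 0L,
                               n_invalid = 0L, source = NA_character_) {
  stopifnot(length(l) == length(s), all(is.finite(l)), all(is.finite(s)),
            n_dark >= 0, n_saturated >= 0, n_invalid >= 0)
  structure(list(l = as.numeric(l), s = as.numeric(s),
                 n_dark = as.integer(n_dark),
                 n_saturated = as.integer(n_saturated),
                 n_invalid = as.integer(n_invalid),
                 source = source),
            class = "chromaticity_cloud")
}

#' @export
print.chromaticity_cloud <- function(x, ...) {
  cat(sprintf(
    "chromaticity cloud: %d points (excluded: %d dark, %d saturated, %d invalid)\n",
    length(x$l), x$n_dark, x$n_saturated, x$n_invalid))
  invisible(x)
}

#' Chromaticity cloud of a RAW image
#'
#' Applies the dark/saturated pixel filter, converts kept pixels through the
#' calibration to LMS and on to MacLeod-Boynton chromaticity, and returns the
#' cloud with full exclusion bookkeeping. Pixels whose L+M is nonpositive
#' after conversion are counted as invalid.
#'
#' @param img a [raw_image()].
#' @param cal a [calibration_matrix()].
#' @param low,high filter thresholds, see [valid_pixel_mask()].
#' @return A [chromaticity_cloud()].
#' @export
image_chromaticity_cloud <- function(img, cal, low = 15, high = 15000) {
  vm <- valid_pixel_mask(img, low = low, high = high)
  if (vm$n_kept == 0L) {
    stop("empty cloud: every pixel excluded by the dark/saturated filter")
  }
  px <- img$pixels
  keep <- as.vector(vm$mask)
  rgb <- cbind(as.vector(px[, , 1L])[keep],
               as.vector(px[, , 2L])[keep],
               as.vector(px[, , 3L])[keep])
  mb <- lms_to_mb(rgb_to_lms(rgb, cal))
  n_invalid <- sum(!mb$valid)
  if (n_invalid == length(mb$valid)) {
    stop("empty cloud: all kept pixels have nonpositive L+M")
  }
  chromaticity_cloud(mb$l[mb$valid], mb$s[mb$valid],
                     n_dark = vm$n_dark, n_saturated = vm$n_saturated,
                     n_invalid = n_invalid, source = img$site)
}

cloud_xy <- function(cloud) {
  if (inherits(cloud, "chromaticity_cloud")) {
    cbind(cloud$l, cloud$s)
  } else if (is.data.frame(cloud)) {
    as.matrix(cloud[, 1:2])
  } else {
    as.matrix(cloud)
  }
}

#' Fit a standard-deviation ellipse to a 2-D point cloud
#'
#' The s.d. ellipse summarizes a chromatic distribution: its centre is the
#' mean, its axes are the eigenvectors of the 2x2 covariance matrix and its
#' radii are the square roots of the eigenvalues (1-s.d. lengths). The major
#' axis is the direction of maximum chromatic variance.
#'
#' @param cloud a [chromaticity_cloud()], a two-column data.frame or a
#'   two-column matrix.
#' @return An object of class `sd_ellipse` with `centre`, `radii`
#'   (major, minor), `orientation_deg` in \[0, 180) and a `degenerate` flag
#'   (collinear cloud, minor radius 0).
#' @export
fit_sd_ellipse <- function(cloud) {
  xy <- cloud_xy(cloud)
  if (nrow(xy) < 3L) stop("need at least 3 points to fit an s.d. ellipse")
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  radii <- sqrt(pmax(e$values, 0))
  v <- e$vectors[, 1L]
  orientation <- (atan2(v[2L], v[1L]) * 180 / pi) %% 180
  degenerate <- radii[2L] < 1e-9 * max(radii[1L], .Machine$double.eps)
  structure(list(centre = c(x = unname(ctr[1L]), y = unname(ctr[2L])),
                 radii = c(major = radii[1L], minor = radii[2L]),
                 orientation_deg = orientation,
                 degenerate = degenerate),
            class = "sd_ellipse")
}

#' @export
print.sd_ellipse <- function(x, ...) {
  cat(sprintf(
    "s.d. ellipse: centre (%.4g, %.4g), radii (%.4g, %.4g), orientation %.2f deg%s\n",
    x$centre[1L], x$centre[2L], x$radii[1L], x$radii[2L], x$orientation_deg,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Normalize cardinal-axis variances of a cloud
#'
#' Rescales the l and s coordinates so that the sample variance along each
#' cardinal axis is exactly 1 ("normalized" MacLeod-Boynton diagram). The
#' blue-yellow log axis ratio is defined in this normalized space.
#'
#' @param cloud a [chromaticity_cloud()].
#' @return A [chromaticity_cloud()] with unit cardinal variances.
#' @export
normalize_cardinal_variances <- function(cloud) {
  stopifnot(inherits(cloud, "chromaticity_cloud"))
  sd_l <- stats::sd(cloud$l)
  sd_s <- stats::sd(cloud$s)
  if (!is.finite(sd_l) || !is.finite(sd_s) || sd_l == 0 || sd_s == 0) {
    stop("cannot normalize: zero variance along a cardinal axis")
  }
  chromaticity_cloud(cloud$l / sd_l, cloud$s / sd_s,
                     n_dark = cloud$n_dark, n_saturated = cloud$n_saturated,
                     n_invalid = cloud$n_invalid, source = cloud$source)
}

#' Axis-ratio result container
#'
#' @param neg_diag_radius,pos_diag_radius s.d. extents along the negative
#'   and positive diagonals.
#' @return Object of class `axis_ratio_result` with `log_axis_ratio` =
#'   ln(neg/pos); positive values indicate blue-yellow bias.
#' @export
axis_ratio_result <- function(neg_diag_radius, pos_diag_radius) {
  stopifnot(neg_diag_radius > 0, pos_diag_radius > 0)
  structure(list(log_axis_ratio = log(neg_diag_radius / pos_diag_radius),
                 neg_diag_radius = neg_diag_radius,
                 pos_diag_radius = pos_diag_radius),
            class = "axis_ratio_result")
}

#' @export
print.axis_ratio_result <- function(x, ...) {
  cat(sprintf("log axis ratio %.4f (neg diag %.4g / pos diag %.4g)\n",
              x$log_axis_ratio, x$neg_diag_radius, x$pos_diag_radius))
  invisible(x)
}

#' Blue-yellow log axis ratio of a (normalized) cloud
#'
#' Projects the centred cloud onto the negative-diagonal (unit vector
#' (1, -1)/sqrt(2)) and positive-diagonal ((1, 1)/sqrt(2)) directions and
#' returns the natural log of the ratio of the projected standard
#' deviations. In the normalized diagram a positive value means more
#' chromatic variance along the (roughly blue-yellow) negative diagonal than
#' along the orthogonal (magenta-green) positive diagonal. For a bivariate
#' normal cloud with unit cardinal variances and correlation c this equals
#' 0.5 * log((1 - c) / (1 + c)).
#'
#' @param cloud a cloud with unit cardinal variances, typically from
#'   [normalize_cardinal_variances()].
#' @return An [axis_ratio_result()].
#' @export
log_axis_ratio <- function(cloud) {
  xy <- cloud_xy(cloud)
  l <- xy[, 1L] - mean(xy[, 1L])
  s <- xy[, 2L] - mean(xy[, 2L])
  r_neg <- stats::sd((l - s) / sqrt(2))
  r_pos <- stats::sd((l + s) / sqrt(2))
  if (r_neg == 0 || r_pos == 0) {
    stop("zero projected standard deviation along a diagonal")
  }
  axis_ratio_result(r_neg, r_pos)
}

#' Mean saturation within opponent hue wedges
#'
#' Divides the scaled chromaticity diagram into 2 * `n_axes` wedges of
#' width `2 * wedge_halfwidth` degrees centred on the poles of each stimulus
#' axis (poles at 22.5 * (k - 1) degrees for the default 8 axes), pairs each
#' wedge with its opponent (pole + 180 deg), and averages pixel saturations
#' within each opponent wedge pair. Wedge membership is half-open on the
#' upper edge, so every chromatic pixel belongs to exactly one axis;
#' achromatic pixels (saturation 0) belong to none.
#'
#' @param xy scaled-diagram coordinates: data.frame/matrix with columns x, y.
#' @param n_axes number of opponent axis pairs (default 8).
#' @param wedge_halfwidth half-width of each wedge in degrees (default
#'   11.25, giving 22.5-degree wedges).
#' @return Named numeric vector of `n_axes` mean saturations; `NA` (with a
#'   warning) for axes whose wedge pair contains no pixels.
#' @export
wedge_mean_saturations <- function(xy, n_axes = 8L, wedge_halfwidth = 11.25) {
  hs <- hue_saturation(if (is.data.frame(xy)) xy else
    data.frame(x = cloud_xy(xy)[, 1L], y = cloud_xy(xy)[, 2L]))
  step <- 180 / n_axes
  if (abs(2 * wedge_halfwidth - step) > 1e-12) {
    stop("wedges must tile the diagram: wedge_halfwidth must equal 90/n_axes")
  }
  chromatic <- !is.na(hs$hue_deg)
  hue <- hs$hue_deg[chromatic]
  sat <- hs$saturation[chromatic]
  # axis k has poles at step*(k-1) and step*(k-1)+180; fold hue to [0,180)
  # and bin half-open wedges [pole - hw, pole + hw)
  folded <- hue %% 180
  axis_id <- (floor((folded + wedge_halfwidth) / step) %% n_axes) + 1L
  out <- rep(NA_real_, n_axes)
  got <- tapply(sat, factor(axis_id, levels = seq_len(n_axes)), mean)
  out[!is.na(got)] <- got[!is.na(got)]
  names(out) <- sprintf("axis_%d", seq_len(n_axes))
  if (anyNA(out)) {
    warning("empty wedge pair(s): ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}
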