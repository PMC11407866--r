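#' Camera calibration matrix
#'
#' Wraps a 3x3 matrix mapping linear camera RGB to LMS cone excitations, as
#' obtained from a spectroradiometric calibration of a specific device. The
#' inverse is precomputed so that synthetic chromaticities can be rendered
#' back to RAW-like RGB.
#'
#' @param m 3x3 numeric matrix; rows produce L, M and S from (R, G, B).
#' @return An object of class `calibration_matrix` with elements `m` and
#'   `m_inv`.
#' @examples
#' cal <- calibration_matrix(diag(3))
#' rgb_to_lms(c(10, 20, 30), cal)
#' @export
calibration_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L))) {
    stop("calibration matrix must be a numeric 3x3 matrix")
  }
  if (!all(is.finite(m))) stop("calibration matrix entries must be finite")
  if (!is.finite(kappa(m)) || abs(det(m)) < .Machine$double.eps * 100) {
    stop("calibration matrix must be invertible")
  }
  structure(list(m = m, m_inv = solve(m)), class = "calibration_matrix")
}

#' @export
print.calibration_matrix <- function(x, ...) {
  cat("camera RGB -> LMS calibration matrix:\n")
  print(x$m)
  invisible(x)
}

#' Default synthetic-camera calibration
#'
#' A plausible, well-conditioned RGB-to-LMS matrix used by the synthetic-data
#' generators and shipped study configuration. It stands in for a measured
#' device calibration, which is always an input in real analyses.
#'
#' @return A [calibration_matrix()].
#' @export
default_calibration <- function() {
  calibration_matrix(rbind(
    c(0.55, 0.40, 0.05),
    c(0.25, 0.70, 0.05),
    c(0.03, 0.07, 0.90)
  ))
}

as_xyz_matrix <- function(x, n_col, what) {
  if (is.null(dim(x))) {
    if (length(x) != n_col) stop(what, " must have length ", n_col)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != n_col) stop(what, " must have ", n_col, " columns")
  x
}

#' Convert camera RGB to LMS cone excitations
#'
#' @param rgb length-3 vector or n x 3 matrix of linear, nonnegative camera
#'   RGB values.
#' @param cal a [calibration_matrix()].
#' @return Numeric vector (for a single pixel) or n x 3 matrix with columns
#'   L, M, S.
#' @export
rgb_to_lms <- function(rgb, cal) {
  stopifnot(inherits(cal, "calibration_matrix"))
  single <- is.null(dim(rgb))
  rgb <- as_xyz_matrix(rgb, 3L, "rgb")
  if (!all(is.finite(rgb))) stop("rgb values must be finite")
  if (any(rgb < 0)) stop("rgb values must be nonnegative")
  out <- rgb %*% t(cal$m)
  colnames(out) <- c("L", "M", "S")
  if (single) out[1L, ] else out
}

#' Convert LMS to MacLeod-Boynton chromaticity
#'
#' Computes the cardinal chromaticity coordinates l = L/(L+M) and
#' s = S/(L+M). Pixels with L+M <= 0 have undefined chromaticity; they are
#' flagged invalid (`NA` coordinates, `valid = FALSE`) rather than dropped.
#'
#' @param lms length-3 vector or n x 3 matrix of cone excitations.
#' @return A data.frame with columns `l`, `s`, `valid`.
#' @export
lms_to_mb <- function(lms) {
  lms <- as_xyz_matrix(lms, 3L, "lms")
  if (!all(is.finite(lms))) stop("lms values must be finite")
  denom <- lms[, 1L] + lms[, 2L]
  valid <- denom > 0
  l <- ifelse(valid, lms[, 1L] / denom, NA_real_)
  s <- ifelse(valid, lms[, 3L] / denom, NA_real_)
  data.frame(l = l, s = s, valid = valid)
}

#' Chromaticity-diagram configuration
#'
#' Describes one instance of the scaled MacLeod-Boynton diagram: the white
#' point on which it is centred, the per-axis contrast-equating scale factors
#' and a tag recording which cone fundamentals the upstream calibration
#' assumes. Two instances are typically in play: a discrimination space
#' centred on equal-energy white and a Mondrian/preference space centred on
#' Illuminant C. The numeric scaling constants belong to the device/space
#' calibration, so they live here as configuration (defaults 1).
#'
#' @param white_point length-2 numeric, the (l, s) chromaticity of the white
#'   point.
#' @param axis_scale length-2 positive numeric, multipliers applied to
#'   (l - white l) and (s - white s).
#' @param fundamentals character tag naming the cone fundamentals convention.
#' @return An object of class `diagram_config`.
#' @export
diagram_config <- function(white_point = c(l = 0.6, s = 1.0),
                           axis_scale = c(1, 1),
                           fundamentals = "synthetic") {
  white_point <- as.numeric(white_point)
  axis_scale <- as.numeric(axis_scale)
  stopifnot(length(white_point) == 2L, all(is.finite(white_point)),
            length(axis_scale) == 2L, all(axis_scale > 0))
  structure(list(white_point = c(l = white_point[1L], s = white_point[2L]),
                 axis_scale = axis_scale,
                 fundamentals = as.character(fundamentals)[1L]),
            class = "diagram_config")
}

#' @export
print.diagram_config <- function(x, ...) {
  cat(sprintf(
    "scaled chromaticity diagram [%s]: white (l=%g, s=%g), scales (%g, %g)\n",
    x$fundamentals, x$white_point[1L], x$white_point[2L],
    x$axis_scale[1L], x$axis_scale[2L]))
  invisible(x)
}

#' Map MacLeod-Boynton chromaticities into the scaled diagram
#'
#' Recentres chromaticities on the configured white point and applies the
#' per-axis scale factors, giving coordinates in which polar angle is hue and
#' radius is saturation.
#'
#' @param mb data.frame with columns `l` and `s` (e.g. from [lms_to_mb()]),
#'   or a length-2 vector.
#' @param cfg a [diagram_config()].
#' @return A data.frame with columns `x`, `y`.
#' @export
mb_to_scaled <- function(mb, cfg) {
  stopifnot(inherits(cfg, "diagram_config"))
  if (is.data.frame(mb)) {
    l <- mb$l
    s <- mb$s
  } else {
    mb <- as_xyz_matrix(mb, 2L, "mb")
    l <- mb[, 1L]
    s <- mb[, 2L]
  }
  data.frame(x = cfg$axis_scale[1L] * (l - cfg$white_point[1L]),
             y = cfg$axis_scale[2L] * (s - cfg$white_point[2L]))
}

#' Hue angle and saturation of scaled-diagram coordinates
#'
#' @param xy data.frame with columns `x`, `y`, or a length-2 vector.
#' @return data.frame with `hue_deg` in \[0, 360) (`NA` for achromatic
#'   points, i.e. saturation exactly 0) and `saturation`.
#' @export
hue_saturation <- function(xy) {
  if (is.data.frame(xy)) {
    x <- xy$x
    y <- xy$y
  } else {
    xy <- as_xyz_matrix(xy, 2L, "xy")
    x <- xy[, 1L]
    y <- xy[, 2L]
  }
  sat <- sqrt(x^2 + y^2)
  hue <- (atan2(y, x) * 180 / pi) %% 360
  hue[sat == 0] <- NA_real_
  data.frame(hue_deg = hue, saturation = sat)
}

#' Render chromaticities back to camera RGB
#'
#' Inverse of the RGB -> LMS -> MacLeod-Boynton pipeline: given (l, s)
#' chromaticities and total luminance-like intensities T = L + M, computes
#' LMS = (l T, (1 - l) T, s T) and maps through the inverse calibration.
#' Used by the synthetic scene generator and by round-trip tests.
#'
#' @param l,s chromaticity coordinates (vectors of equal length).
#' @param intensity L+M intensities, scalar or vector.
#' @param cal a [calibration_matrix()].
#' @return n x 3 matrix of linear camera RGB (may contain negative values if
#'   the chromaticity is outside the camera gamut).
#' @export
render_chromaticities <- function(l, s, intensity, cal) {
  stopifnot(inherits(cal, "calibration_matrix"), length(l) == length(s))
  intensity <- rep_len(intensity, length(l))
  lms <- cbind(L = l * intensity, M = (1 - l) * intensity, S = s * intensity)
  out <- lms %*% t(cal$m_inv)
  colnames(out) <- c("R", "G", "B")
  out
}
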