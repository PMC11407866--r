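#' Mondrian generation parameters
#'
#' @param s_max saturation cap (display-gamut limited), elements sample
#'   saturation uniformly on \[0, s_max\].
#' @param mean_luminance mean element luminance in cd/m^2 (55).
#' @param lum_jitter luminance jitter fraction: element luminance is uniform
#'   on mean * \[1 - lum_jitter, 1 + lum_jitter\] (0.5, i.e. +/-50%).
#' @param min_frac,max_frac element width/height bounds as fractions of the
#'   final (cropped) image size (0.02 and 0.17).
#' @param canvas_factor canvas oversize factor per dimension (1.5); the
#'   stimulus is cropped from the centre of the canvas so no background or
#'   edge artefacts survive.
#' @param max_elements hard cap on placed elements before giving up on full
#'   coverage (5000).
#' @return List of class `mondrian_params`.
#' @export
mondrian_params <- function(s_max = 0.5, mean_luminance = 55,
                            lum_jitter = 0.5, min_frac = 0.02,
                            max_frac = 0.17, canvas_factor = 1.5,
                            max_elements = 5000L) {
  stopifnot(s_max >= 0, mean_luminance > 0, lum_jitter >= 0, lum_jitter < 1,
            min_frac > 0, max_frac > min_frac, max_frac < 1,
            canvas_factor > 1, max_elements >= 1)
  structure(list(s_max = s_max, mean_luminance = mean_luminance,
                 lum_jitter = lum_jitter, min_frac = min_frac,
                 max_frac = max_frac, canvas_factor = canvas_factor,
                 max_elements = as.integer(max_elements)),
            class = "mondrian_params")
}

#' Hue pole angles of the eight Mondrian axes
#'
#' Axis k runs through the white point with poles at 22.5 * (k - 1) and
#' 22.5 * (k - 1) + 180 degrees, so each stimulus contains two complementary
#' hues at varying saturation.
#'
#' @param axis_id integer 1..8.
#' @return Length-2 numeric vector of pole angles in degrees.
#' @export
mondrian_axis_poles <- function(axis_id) {
  axis_id <- as.integer(axis_id)
  if (is.na(axis_id) || axis_id < 1L || axis_id > 8L) {
    stop("axis_id must be in 1..8")
  }
  pole <- 22.5 * (axis_id - 1L)
  c(pole, pole + 180)
}

#' Generate an axis-constrained chromatic Mondrian
#'
#' Places random rectangles on an oversized canvas until the central crop is
#' fully covered; each element draws its hue uniformly from the axis's two
#' complementary poles, its saturation uniformly on \[0, s_max\] and its
#' luminance uniformly within +/-50% of the mean. The crop is returned as
#' scaled-diagram chromaticity planes (x, y) plus a luminance plane, with
#' the element list for validation and exact reproduction.
#'
#' @param axis_id Mondrian axis 1..8 (pole angles 0, 22.5, ..., 157.5 deg).
#' @param size side length in pixels of the final (square) stimulus.
#' @param params a [mondrian_params()].
#' @param seed integer RNG seed; the element list is bit-identical across
#'   runs with the same seed.
#' @return Object of class `mondrian`: `axis_id`, `poles`, `size`,
#'   `canvas_size`, `elements` (data.frame: x, y, width, height, hue_deg,
#'   saturation, luminance), `image` (list of size x size matrices `x`, `y`,
#'   `luminance`), `params`, `seed`.
#' @export
generate_mondrian <- function(axis_id, size = 128L,
                              params = mondrian_params(), seed = NULL) {
  poles <- mondrian_axis_poles(axis_id)
  size <- as.integer(size)
  stopifnot(size >= 8L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  canvas <- as.integer(ceiling(size * params$canvas_factor))
  off <- (canvas - size) %/% 2L
  crop_rows <- (off + 1L):(off + size)
  w_lo <- as.integer(ceiling(params$min_frac * size))
  w_hi <- as.integer(floor(params$max_frac * size))
  if (w_lo < 1L || w_hi < w_lo) {
    stop("image too small for the element-size bounds")
  }
  Xc <- matrix(NA_real_, canvas, canvas)
  Yc <- matrix(NA_real_, canvas, canvas)
  Lc <- matrix(NA_real_, canvas, canvas)
  painted_crop <- matrix(FALSE, size, size)
  el_x <- integer(0); el_y <- integer(0); el_w <- integer(0); el_h <- integer(0)
  el_hue <- numeric(0); el_sat <- numeric(0); el_lum <- numeric(0)
  n <- 0L
  while (!all(painted_crop)) {
    if (n >= params$max_elements) {
      stop(errorCondition(
        sprintf("crop coverage %.1f%% after %d elements (cap reached)",
                100 * mean(painted_crop), n),
        class = "chromadiet_mondrian_coverage"))
    }
    n <- n + 1L
    w <- sample.int(w_hi - w_lo + 1L, 1L) + w_lo - 1L
    h <- sample.int(w_hi - w_lo + 1L, 1L) + w_lo - 1L
    x0 <- sample.int(canvas - w + 1L, 1L)
    y0 <- sample.int(canvas - h + 1L, 1L)
    hue <- poles[sample.int(2L, 1L)]
    sat <- stats::runif(1L, 0, params$s_max)
    lum <- params$mean_luminance *
      stats::runif(1L, 1 - params$lum_jitter, 1 + params$lum_jitter)
    rows <- y0:(y0 + h - 1L)
    cols <- x0:(x0 + w - 1L)
    Xc[rows, cols] <- sat * cospi(hue / 180)
    Yc[rows, cols] <- sat * sinpi(hue / 180)
    Lc[rows, cols] <- lum
    r_in <- rows[rows >= crop_rows[1L] & rows <= crop_rows[size]]
    c_in <- cols[cols >= crop_rows[1L] & cols <= crop_rows[size]]
    if (length(r_in) && length(c_in)) {
      painted_crop[r_in - off, c_in - off] <- TRUE
    }
    el_x[n] <- x0; el_y[n] <- y0; el_w[n] <- w; el_h[n] <- h
    el_hue[n] <- hue; el_sat[n] <- sat; el_lum[n] <- lum
  }
  structure(list(
    axis_id = as.integer(axis_id), poles = poles, size = size,
    canvas_size = canvas,
    elements = data.frame(x = el_x, y = el_y, width = el_w, height = el_h,
                          hue_deg = el_hue, saturation = el_sat,
                          luminance = el_lum),
    image = list(x = Xc[crop_rows, crop_rows], y = Yc[crop_rows, crop_rows],
                 luminance = Lc[crop_rows, crop_rows]),
    params = params, seed = seed),
    class = "mondrian")
}

#' @export
print.mondrian <- function(x, ...) {
  cat(sprintf("mondrian: axis %d (poles %g/%g deg), %dpx crop, %d elements\n",
              x$axis_id, x$poles[1L], x$poles[2L], x$size,
              nrow(x$elements)))
  invisible(x)
}

#' Validate a generated Mondrian against its stimulus constraints
#'
#' Report-only checks: axis purity (fraction of chromatic pixels whose hue
#' angle lies on one of the axis's two poles within `hue_tol` degrees),
#' element-size bounds (width and height within \[min_frac, max_frac\] of
#' the final image size), luminance bounds (within the jitter range of the
#' mean), saturation cap, and full crop coverage. A generator output must
#' validate clean.
#'
#' @param m a [generate_mondrian()] result.
#' @param hue_tol angular tolerance in degrees for axis purity.
#' @return List of class `mondrian_validation`: `axis_purity`,
#'   `n_size_violations`, `n_luminance_violations`,
#'   `n_saturation_violations`, `coverage`, `clean`.
#' @export
validate_mondrian <- function(m, hue_tol = 1e-6) {
  stopifnot(inherits(m, "mondrian"))
  hs <- hue_saturation(data.frame(x = as.vector(m$image$x),
                                  y = as.vector(m$image$y)))
  chrom <- !is.na(hs$hue_deg)
  if (any(chrom)) {
    d <- vapply(m$poles %% 360, function(p) {
      dd <- abs(hs$hue_deg[chrom] - p) %% 360
      pmin(dd, 360 - dd)
    }, numeric(sum(chrom)))
    on_axis <- apply(matrix(d, ncol = 2L), 1L, min) <= hue_tol
    purity <- mean(on_axis)
  } else {
    purity <- 1  # fully achromatic stimulus is vacuously on-axis
  }
  p <- m$params
  size_bad <- sum(m$elements$width < p$min_frac * m$size |
                    m$elements$width > p$max_frac * m$size |
                    m$elements$height < p$min_frac * m$size |
                    m$elements$height > p$max_frac * m$size)
  lum_lo <- p$mean_luminance * (1 - p$lum_jitter)
  lum_hi <- p$mean_luminance * (1 + p$lum_jitter)
  lum_bad <- sum(m$elements$luminance < lum_lo | m$elements$luminance > lum_hi)
  sat_bad <- sum(m$elements$saturation < 0 | m$elements$saturation > p$s_max)
  coverage <- mean(!is.na(m$image$luminance))
  structure(list(axis_purity = purity,
                 n_size_violations = size_bad,
                 n_luminance_violations = lum_bad,
                 n_saturation_violations = sat_bad,
                 coverage = coverage,
                 clean = purity == 1 && size_bad == 0L && lum_bad == 0L &&
                   sat_bad == 0L && coverage == 1),
            class = "mondrian_validation")
}

#' @export
print.mondrian_validation <- function(x, ...) {
  cat(sprintf(
    "mondrian validation: purity %.4f, coverage %.4f, violations: %d size, %d luminance, %d saturation -> %s\n",
    x$axis_purity, x$coverage, x$n_size_violations, x$n_luminance_violations,
    x$n_saturation_violations, if (x$clean) "clean" else "NOT clean"))
  invisible(x)
}
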