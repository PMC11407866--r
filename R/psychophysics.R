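#' Set of hue axes for the discrimination task
#'
#' Eight unit direction vectors in the normalized MacLeod-Boynton diagram:
#' increments and decrements along the two cardinal axes, along the
#' blue-yellow axis and along its reflection about the vertical. By default
#' the blue-yellow axis is taken as the negative diagonal (315 deg), with the
#' option of supplying the empirically measured unique-blue-to-unique-yellow
#' direction instead via `angles_deg`.
#'
#' @param angles_deg numeric vector of axis pole angles in degrees.
#' @return An object of class `hue_axis_set`: an n x 2 matrix of unit
#'   vectors with an `angles_deg` attribute.
#' @export
hue_axis_set <- function(angles_deg = c(0, 45, 90, 135, 180, 225, 270, 315)) {
  stopifnot(is.numeric(angles_deg), length(angles_deg) >= 4L)
  a <- angles_deg %% 360
  if (anyDuplicated(a)) stop("axis angles must be distinct")
  # every axis must come with its opposite pole
  opp <- (a + 180) %% 360
  if (!all(sapply(opp, function(o) any(abs(((a - o + 180) %% 360) - 180) < 1e-9)))) {
    stop("axes must come in opposite-sign pairs")
  }
  m <- cbind(cos(a * pi / 180), sin(a * pi / 180))
  colnames(m) <- c("x", "y")
  rownames(m) <- sprintf("axis_%03.1f", a)
  structure(m, angles_deg = a, class = c("hue_axis_set", "matrix", "array"))
}

#' Simulated observer for the 4AFC discrimination task
#'
#' Generative model of a participant: a true discrimination threshold per
#' hue axis, a common psychometric slope on log saturation, the 4AFC guess
#' rate and a lapse rate.
#'
#' @param thresholds positive numeric vector, one true threshold
#'   (saturation units) per axis of the accompanying [hue_axis_set()].
#' @param slope positive logistic slope on natural-log saturation.
#' @param guess_rate guessing probability (0.25 for 4AFC).
#' @param lapse_rate lapse probability in \[0, 0.2\].
#' @return An object of class `observer`.
#' @export
observer <- function(thresholds, slope = 3, guess_rate = 0.25,
                     lapse_rate = 0.02) {
  stopifnot(all(thresholds > 0), slope > 0,
            guess_rate >= 0, guess_rate <= 1,
            lapse_rate >= 0, lapse_rate <= 0.2)
  structure(list(thresholds = as.numeric(thresholds), slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf(
    "observer: %d axes, thresholds %.3g-%.3g, slope %g, guess %g, lapse %g\n",
    length(x$thresholds), min(x$thresholds), max(x$thresholds), x$slope,
    x$guess_rate, x$lapse_rate))
  invisible(x)
}

#' Probability of a correct response
#'
#' The observer's psychometric function: P(correct) = guess +
#' (1 - guess - lapse) * logistic(slope * (log s - log threshold)).
#' Monotone nondecreasing in saturation; at saturation 0 the observer
#' guesses.
#'
#' @param obs an [observer()].
#' @param axis axis index into `obs$thresholds`.
#' @param saturation nonnegative saturation value(s).
#' @return Probability vector.
#' @export
observer_p_correct <- function(obs, axis, saturation) {
  stopifnot(inherits(obs, "observer"), axis >= 1,
            axis <= length(obs$thresholds))
  if (any(saturation < 0)) stop("saturation must be nonnegative")
  thr <- obs$thresholds[axis]
  p <- ifelse(saturation == 0, obs$guess_rate,
              obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) *
                stats::plogis(obs$slope * (log(pmax(saturation,
                                                    .Machine$double.xmin)) -
                                             log(thr))))
  p
}

#' Staircase parameters
#'
#' @param s_max maximum (starting) saturation; the staircase is clamped
#'   here.
#' @param down multiplicative step after a correct response (0.5).
#' @param up multiplicative step after an incorrect response (1.5).
#' @param n_reversals reversals at which a staircase ends (18).
#' @param max_trials runaway guard; default 10x a nominal expected staircase
#'   length of 4 trials per reversal.
#' @param second_start `"continue"`: the second staircase of a pair starts
#'   at the final saturation of the first; `"restart"`: it restarts at
#'   `s_max`.
#' @return A list of class `staircase_params`.
#' @export
staircase_params <- function(s_max = 1, down = 0.5, up = 1.5,
                             n_reversals = 18L,
                             max_trials = 10L * 4L * n_reversals,
                             second_start = c("continue", "restart")) {
  stopifnot(s_max > 0, down > 0, down < 1, up > 1, n_reversals >= 1,
            max_trials > n_reversals)
  structure(list(s_max = s_max, down = down, up = up,
                 n_reversals = as.integer(n_reversals),
                 max_trials = as.integer(max_trials),
                 second_start = match.arg(second_start)),
            class = "staircase_params")
}

#' Run one adaptive staircase
#'
#' Presents trials starting at `start` saturation; a correct response
#' multiplies saturation by `down`, an incorrect one by `up`, clamped at
#' `s_max`. A reversal is a trial whose step direction differs from the
#' previous trial's; the staircase ends after `n_reversals` reversals. If
#' the reversal criterion is not reached within `max_trials` trials an error
#' condition of class `chromadiet_staircase_overrun` is signalled carrying
#' the trial log.
#'
#' @param respond function(saturation) -> logical correct/incorrect.
#' @param start starting saturation.
#' @param params a [staircase_params()].
#' @return A list with `trials` (data.frame: trial, saturation, correct,
#'   reversal), `final_saturation` (the next saturation that would have been
#'   shown) and `n_reversals`.
#' @export
run_staircase <- function(respond, start = params$s_max,
                          params = staircase_params()) {
  stopifnot(is.function(respond), start > 0, start <= params$s_max)
  cap <- params$max_trials
  sat_log <- numeric(cap)
  cor_log <- logical(cap)
  rev_log <- logical(cap)
  sat <- start
  dir_prev <- NA_integer_
  nrev <- 0L
  i <- 0L
  while (nrev < params$n_reversals) {
    i <- i + 1L
    if (i > cap) {
      trials <- data.frame(trial = seq_len(cap), saturation = sat_log,
                           correct = cor_log, reversal = rev_log)
      stop(errorCondition(
        sprintf("staircase did not reach %d reversals within %d trials (%d reversals logged)",
                params$n_reversals, cap, nrev),
        class = "chromadiet_staircase_overrun",
        trials = trials, n_reversals = nrev))
    }
    corr <- isTRUE(respond(sat))
    dir <- if (corr) -1L else 1L
    rev <- !is.na(dir_prev) && dir != dir_prev
    if (rev) nrev <- nrev + 1L
    sat_log[i] <- sat
    cor_log[i] <- corr
    rev_log[i] <- rev
    sat <- min(params$s_max, sat * if (corr) params$down else params$up)
    dir_prev <- dir
  }
  list(trials = data.frame(trial = seq_len(i), saturation = sat_log[seq_len(i)],
                           correct = cor_log[seq_len(i)],
                           reversal = rev_log[seq_len(i)]),
       final_saturation = sat, n_reversals = nrev)
}

observer_responder <- function(obs, axis) {
  force(obs); force(axis)
  function(saturation) stats::runif(1L) < observer_p_correct(obs, axis, saturation)
}

#' Run a full interleaved discrimination session
#'
#' Simulates the 4AFC task: per hue axis, two consecutive staircases of
#' `n_reversals` reversals each; across axes, staircases are randomly
#' interleaved (on each trial the active axis is drawn uniformly among axes
#' whose staircase pair is unfinished). The first staircase of each axis
#' starts at `s_max`; the second continues from the first's final saturation
#' (or restarts, per `params$second_start`). Fully reproducible from the
#' seed.
#'
#' @param obs an [observer()] with one threshold per axis.
#' @param axes a [hue_axis_set()].
#' @param params a [staircase_params()].
#' @param seed integer RNG seed (sets the session's RNG state); `NULL` uses
#'   the current state.
#' @return data.frame trial log with columns `trial`, `axis`, `staircase`
#'   (1 or 2), `saturation`, `correct`, `reversal`.
#' @export
run_session <- function(obs, axes = hue_axis_set(), params = staircase_params(),
                        seed = NULL) {
  stopifnot(inherits(obs, "observer"), inherits(axes, "hue_axis_set"),
            length(obs$thresholds) == nrow(axes))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_axes <- nrow(axes)
  sat <- rep(params$s_max, n_axes)   # current saturation per axis
  phase <- rep(1L, n_axes)           # which staircase of the pair
  nrev <- rep(0L, n_axes)            # reversals in current staircase
  trials_in <- rep(0L, n_axes)       # trials in current staircase (guard)
  dir_prev <- rep(NA_integer_, n_axes)
  done <- rep(FALSE, n_axes)
  est <- params$max_trials * 2L * n_axes
  ax_log <- integer(est); ph_log <- integer(est)
  sat_log <- numeric(est); cor_log <- logical(est); rev_log <- logical(est)
  t <- 0L
  while (!all(done)) {
    act <- which(!done)
    a <- if (length(act) == 1L) act else act[sample.int(length(act), 1L)]
    t <- t + 1L
    trials_in[a] <- trials_in[a] + 1L
    if (trials_in[a] > params$max_trials) {
      stop(errorCondition(
        sprintf("axis %d staircase %d did not terminate within %d trials",
                a, phase[a], params$max_trials),
        class = "chromadiet_staircase_overrun",
        trials = data.frame(trial = seq_len(t - 1L), axis = ax_log[seq_len(t - 1L)],
                            staircase = ph_log[seq_len(t - 1L)],
                            saturation = sat_log[seq_len(t - 1L)],
                            correct = cor_log[seq_len(t - 1L)],
                            reversal = rev_log[seq_len(t - 1L)])))
    }
    corr <- stats::runif(1L) < observer_p_correct(obs, a, sat[a])
    dir <- if (corr) -1L else 1L
    rev <- !is.na(dir_prev[a]) && dir != dir_prev[a]
    if (rev) nrev[a] <- nrev[a] + 1L
    ax_log[t] <- a; ph_log[t] <- phase[a]
    sat_log[t] <- sat[a]; cor_log[t] <- corr; rev_log[t] <- rev
    sat[a] <- min(params$s_max, sat[a] * if (corr) params$down else params$up)
    dir_prev[a] <- dir
    if (nrev[a] >= params$n_reversals) {
      if (phase[a] == 1L) {
        phase[a] <- 2L
        nrev[a] <- 0L
        trials_in[a] <- 0L
        dir_prev[a] <- NA_integer_
        if (params$second_start == "restart") sat[a] <- params$s_max
      } else {
        done[a] <- TRUE
      }
    }
  }
  data.frame(trial = seq_len(t), axis = ax_log[seq_len(t)],
             staircase = ph_log[seq_len(t)], saturation = sat_log[seq_len(t)],
             correct = cor_log[seq_len(t)], reversal = rev_log[seq_len(t)])
}

#' Fit a logistic psychometric function and extract the 45% threshold
#'
#' Maximum-likelihood logistic fit on natural-log saturation with the guess
#' rate fixed (0.25 for 4AFC) and the lapse rate free in \[0, `lapse_max`\].
#' The threshold is the saturation at which the fitted curve, including the
#' lapse term, passes `p_threshold` (default 0.45, chosen low because some
#' participants have high lapse rates). Degenerate data (fewer than two
#' distinct levels, one response category only, or a likelihood maximized at
#' the flat-slope boundary) yield an unfittable flag rather than an error.
#'
#' @param saturation,correct trial vectors (saturation > 0, logical
#'   correct).
#' @param guess fixed guess rate.
#' @param lapse_max upper bound for the free lapse rate.
#' @param p_threshold performance criterion defining the threshold.
#' @return An object of class `psychometric_fit`: list with `threshold`
#'   (at `p_threshold`), `alpha` (logistic midpoint saturation), `slope`,
#'   `lapse`, `loglik`, `n_trials`, `unfittable`, `reason`.
#' @export
fit_psychometric <- function(saturation, correct, guess = 0.25,
                             lapse_max = 0.2, p_threshold = 0.45) {
  stopifnot(length(saturation) == length(correct))
  ok <- is.finite(saturation) & saturation > 0 & !is.na(correct)
  saturation <- saturation[ok]
  correct <- as.logical(correct[ok])
  unfit <- function(reason) {
    structure(list(threshold = NA_real_, alpha = NA_real_, slope = NA_real_,
                   lapse = NA_real_, loglik = NA_real_,
                   n_trials = length(saturation), unfittable = TRUE,
                   reason = reason),
              class = "psychometric_fit")
  }
  if (length(saturation) < 4L) return(unfit("too few trials"))
  ls <- log(saturation)
  lev <- sort(unique(ls))
  if (length(lev) < 2L) return(unfit("fewer than 2 distinct saturation levels"))
  if (all(correct) || !any(correct)) {
    return(unfit("responses all in one category"))
  }
  idx <- match(ls, lev)
  n <- tabulate(idx, length(lev))
  k <- tabulate(idx[correct], length(lev))
  lo_sl <- log(1e-2); hi_sl <- log(50)
  nll <- function(par) {
    lt <- par[1L]; sl <- exp(par[2L]); la <- par[3L]
    p <- guess + (1 - guess - la) * stats::plogis(sl * (lev - lt))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }
  starts <- lapply(stats::quantile(ls, c(0.25, 0.5, 0.75), names = FALSE),
                   function(q) c(q, log(3), 0.02))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B",
                   lower = c(min(lev) - 5, lo_sl, 0),
                   upper = c(max(lev) + 5, hi_sl, lapse_max)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(unfit("optimizer failure"))
  lt <- best$par[1L]; sl <- exp(best$par[2L]); la <- best$par[3L]
  if (best$par[2L] <= lo_sl + 1e-6) {
    return(unfit("degenerate likelihood (flat psychometric function)"))
  }
  Fcrit <- (p_threshold - guess) / (1 - guess - la)
  if (Fcrit <= 0 || Fcrit >= 1) return(unfit("criterion outside fitted range"))
  structure(list(threshold = exp(lt + stats::qlogis(Fcrit) / sl),
                 alpha = exp(lt), slope = sl, lapse = la,
                 loglik = -best$value, n_trials = sum(n), unfittable = FALSE,
                 reason = NA_character_),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$unfittable) {
    cat("psychometric fit: unfittable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "psychometric fit: threshold %.4g, slope %.3g, lapse %.3g (%d trials)\n",
      x$threshold, x$slope, x$lapse, x$n_trials))
  }
  invisible(x)
}

#' Fit thresholds for every axis of a session trial log
#'
#' With `share_slope = TRUE` (the default) the eight axes of one observer
#' are fit jointly by maximum likelihood with a common slope and a common
#' lapse rate but a free threshold per axis: an observer has a single
#' attentional lapse rate, and pooling the slope across hues stabilizes it
#' against the step-function degeneracy that per-axis fits on adaptive
#' (staircase-concentrated) data are prone to. With `share_slope = FALSE`
#' every axis gets an independent [fit_psychometric()] fit.
#'
#' @param trials trial log from [run_session()] (or a CSV read into the same
#'   columns).
#' @param n_axes number of axes.
#' @param share_slope share slope and lapse across axes (default TRUE).
#' @param ... passed to [fit_psychometric()] (and honoured by the joint
#'   fit: `guess`, `lapse_max`, `p_threshold`).
#' @return List with `thresholds` (numeric vector, `NA` where unfittable),
#'   `fits` (per-axis `psychometric_fit` list for independent fits, or a
#'   single joint-fit summary), `slope`, `lapse`.
#' @export
fit_session_thresholds <- function(trials, n_axes = 8L, share_slope = TRUE,
                                   ...) {
  if (!share_slope) {
    fits <- lapply(seq_len(n_axes), function(a) {
      sel <- trials$axis == a
      fit_psychometric(trials$saturation[sel], trials$correct[sel], ...)
    })
    thr <- vapply(fits, function(f) f$threshold, numeric(1L))
    return(list(thresholds = thr, fits = fits,
                slope = vapply(fits, function(f) f$slope, numeric(1L)),
                lapse = vapply(fits, function(f) f$lapse, numeric(1L))))
  }
  fit_session_joint(trials, n_axes = n_axes, ...)
}

fit_session_joint <- function(trials, n_axes = 8L, guess = 0.25,
                              lapse_max = 0.2, p_threshold = 0.45) {
  thr <- rep(NA_real_, n_axes)
  tabs <- vector("list", n_axes)
  usable <- logical(n_axes)
  for (a in seq_len(n_axes)) {
    sel <- trials$axis == a & is.finite(trials$saturation) &
      trials$saturation > 0
    sat <- trials$saturation[sel]
    corr <- as.logical(trials$correct[sel])
    if (length(sat) < 4L) next
    lev <- sort(unique(log(sat)))
    if (length(lev) < 2L || all(corr) || !any(corr)) next
    idx <- match(log(sat), lev)
    tabs[[a]] <- list(lev = lev, n = tabulate(idx, length(lev)),
                      k = tabulate(idx[corr], length(lev)))
    usable[a] <- TRUE
  }
  fail <- list(thresholds = thr, fits = NULL, slope = NA_real_,
               lapse = NA_real_)
  ax <- which(usable)
  if (length(ax) == 0L) return(fail)
  # slope is box-constrained to a plausible band for logistic slopes on log
  # saturation: the upper bound regularizes against the step-function
  # degeneracy of staircase data (whose likelihood can grow monotonically in
  # slope), the lower bound marks flat, unfittable data
  lo_sl <- log(0.25); hi_sl <- log(15)
  nll <- function(par) {
    sl <- exp(par[1L]); la <- par[2L]
    v <- 0
    for (j in seq_along(ax)) {
      tb <- tabs[[ax[j]]]
      p <- guess + (1 - guess - la) * stats::plogis(sl * (tb$lev - par[2L + j]))
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      v <- v - sum(tb$k * log(p) + (tb$n - tb$k) * log1p(-p))
    }
    v
  }
  lt0 <- vapply(ax, function(a) stats::median(tabs[[a]]$lev), numeric(1L))
  lo <- c(lo_sl, 0, lt0 - 8)
  hi <- c(hi_sl, lapse_max, lt0 + 8)
  best <- NULL
  for (s0 in c(0.5, 1, 2, 3, 5, 8)) {
    fit <- tryCatch(
      stats::optim(c(log(s0), 0.02, lt0), nll, method = "L-BFGS-B",
                   lower = lo, upper = hi),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$par[1L] <= lo_sl + 1e-6) next  # flat psychometric function
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(fail)
  sl <- exp(best$par[1L]); la <- best$par[2L]
  Fcrit <- (p_threshold - guess) / (1 - guess - la)
  if (Fcrit <= 0 || Fcrit >= 1) return(fail)
  thr[ax] <- exp(best$par[2L + seq_along(ax)] + stats::qlogis(Fcrit) / sl)
  # a criterion level outside the sampled saturation range is extrapolation
  # with no data support: flag that axis rather than report it
  for (j in seq_along(ax)) {
    rng <- range(tabs[[ax[j]]]$lev)
    if (!is.finite(thr[ax[j]]) || log(thr[ax[j]]) < rng[1L] ||
        log(thr[ax[j]]) > rng[2L]) {
      thr[ax[j]] <- NA_real_
    }
  }
  list(thresholds = thr,
       fits = list(method = "joint", loglik = -best$value,
                   n_axes_fit = length(ax)),
       slope = sl, lapse = la)
}

#' Fit an origin-centred discrimination ellipse to threshold points
#'
#' Converts each (axis direction, threshold) pair into a point
#' threshold * direction and fits the conic x'Ax = 1 by linear least squares
#' in the quadratic-form coefficients. Exact when the points lie on an
#' ellipse. The ellipse is origin-centred because thresholds are radial
#' excursions from the white point.
#'
#' @param thresholds numeric vector of thresholds (NA allowed, dropped).
#' @param axes a [hue_axis_set()] matching `thresholds`.
#' @return Object of class `discrimination_ellipse`: `A` (2x2 symmetric
#'   form), `radii` (major, minor), `orientation_deg`, `valid` (FALSE when
#'   the fitted form is not positive definite), `n_points`.
#' @export
fit_discrimination_ellipse <- function(thresholds, axes = hue_axis_set()) {
  stopifnot(inherits(axes, "hue_axis_set"),
            length(thresholds) == nrow(axes))
  keep <- is.finite(thresholds) & thresholds > 0
  if (sum(keep) < 5L) stop("need at least 5 valid threshold points")
  pts <- thresholds[keep] * axes[keep, , drop = FALSE]
  x <- pts[, 1L]; y <- pts[, 2L]
  D <- cbind(x^2, 2 * x * y, y^2)
  beta <- stats::lsfit(D, rep(1, length(x)), intercept = FALSE)$coefficients
  A <- matrix(c(beta[1L], beta[2L], beta[2L], beta[3L]), 2L, 2L)
  e <- eigen(A, symmetric = TRUE)
  valid <- all(e$values > 0)
  radii <- if (valid) rev(1 / sqrt(e$values)) else c(NA_real_, NA_real_)
  v <- e$vectors[, 2L]  # smallest eigenvalue of A <-> major radius
  orientation <- if (valid) (atan2(v[2L], v[1L]) * 180 / pi) %% 180 else NA_real_
  structure(list(A = A, radii = c(major = radii[1L], minor = radii[2L]),
                 orientation_deg = orientation, valid = valid,
                 n_points = sum(keep)),
            class = "discrimination_ellipse")
}

#' @export
print.discrimination_ellipse <- function(x, ...) {
  if (!x$valid) {
    cat("discrimination ellipse: invalid fit (form not positive definite)\n")
  } else {
    cat(sprintf(
      "discrimination ellipse: radii (%.4g, %.4g), orientation %.2f deg (%d points)\n",
      x$radii[1L], x$radii[2L], x$orientation_deg, x$n_points))
  }
  invisible(x)
}

#' Radius of a fitted ellipse along a direction
#'
#' @param ellipse a `discrimination_ellipse`.
#' @param direction length-2 vector (need not be unit length).
#' @return The radius 1/sqrt(u'Au) for the unit vector u along `direction`.
#' @export
ellipse_radius <- function(ellipse, direction) {
  u <- direction / sqrt(sum(direction^2))
  q <- drop(t(u) %*% ellipse$A %*% u)
  if (q <= 0) stop("direction has nonpositive quadratic form")
  1 / sqrt(q)
}

cardinal_axis_ids <- function(axes) {
  ang <- attr(axes, "angles_deg")
  list(l = which(abs(ang %% 180) < 1e-9),
       s = which(abs(ang %% 180 - 90) < 1e-9))
}

#' Blue-yellow log axis ratio of a discrimination threshold set
#'
#' Rescales the threshold points so that the cardinal-axis thresholds have
#' unit scale (the normalized diagram: x divided by the mean of the two
#' l-axis thresholds, y by the mean of the two s-axis thresholds), refits
#' the origin-centred ellipse, and returns the natural log of the ratio of
#' the fitted radii along the negative and positive diagonals. Invariant to
#' uniform scaling of all thresholds.
#'
#' @param thresholds numeric vector of thresholds (NA allowed).
#' @param axes a [hue_axis_set()] including both cardinal axis pairs.
#' @return An [axis_ratio_result()].
#' @export
discrimination_log_axis_ratio <- function(thresholds, axes = hue_axis_set()) {
  card <- cardinal_axis_ids(axes)
  if (length(card$l) < 1L || length(card$s) < 1L) {
    stop("axis set must include the cardinal axes")
  }
  scale_l <- mean(thresholds[card$l], na.rm = TRUE)
  scale_s <- mean(thresholds[card$s], na.rm = TRUE)
  if (!is.finite(scale_l) || !is.finite(scale_s) || scale_l <= 0 ||
      scale_s <= 0) {
    stop("cardinal-axis thresholds unavailable; cannot normalize")
  }
  keep <- is.finite(thresholds) & thresholds > 0
  if (sum(keep) < 5L) stop("need at least 5 valid threshold points")
  pts <- thresholds[keep] * axes[keep, , drop = FALSE]
  pts[, 1L] <- pts[, 1L] / scale_l
  pts[, 2L] <- pts[, 2L] / scale_s
  A <- fit_conic_points(pts, loss = "log_radius")
  if (any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("normalized ellipse fit is not positive definite")
  }
  ell <- structure(list(A = A), class = "discrimination_ellipse")
  axis_ratio_result(ellipse_radius(ell, c(1, -1)),
                    ellipse_radius(ell, c(1, 1)))
}

# Fit the origin-centred conic x'Ax = 1 to points. loss = "conic" is the
# linear least-squares fit in the quadratic-form coefficients; loss =
# "log_radius" refines it by minimizing log-radial residuals, which weights
# multiplicative (percentage) threshold errors evenly instead of by r^4.
# Both interpolate exactly when the points lie on an ellipse.
fit_conic_points <- function(pts, loss = c("conic", "log_radius")) {
  loss <- match.arg(loss)
  x <- pts[, 1L]; y <- pts[, 2L]
  D <- cbind(x^2, 2 * x * y, y^2)
  beta <- stats::lsfit(D, rep(1, length(x)), intercept = FALSE)$coefficients
  if (loss == "log_radius") {
    r2 <- x^2 + y^2
    u1 <- x / sqrt(r2); u2 <- y / sqrt(r2)
    # A = L L' with L lower triangular: positive definite by construction
    unpack <- function(par) {
      l11 <- exp(par[1L]); l21 <- par[2L]; l22 <- exp(par[3L])
      c(l11^2, l11 * l21, l21^2 + l22^2)
    }
    obj <- function(par) {
      b <- unpack(par)
      q <- b[1L] * u1^2 + 2 * b[2L] * u1 * u2 + b[3L] * u2^2
      sum((0.5 * log(q) + 0.5 * log(r2))^2)
    }
    A_lin <- matrix(c(beta[1L], beta[2L], beta[2L], beta[3L]), 2L, 2L)
    p0 <- if (all(eigen(A_lin, symmetric = TRUE,
                        only.values = TRUE)$values > 0)) {
      L <- t(chol(A_lin))
      c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]))
    } else {
      c(-0.5 * log(mean(r2)), 0, -0.5 * log(mean(r2)))
    }
    par <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))$par
    b <- unpack(par)
    beta <- c(b[1L], b[2L], b[3L])
  }
  matrix(c(beta[1L], beta[2L], beta[2L], beta[3L]), 2L, 2L)
}

#' Cardinal threshold ratio for CVD screening
#'
#' Ratio of the mean L/(L+M)-axis threshold to the mean S/(L+M)-axis
#' threshold. Colour-vision-deficient observers show outlying ratios; the
#' screen flags outliers by Tukey fences (1.5 x IQR) over a supplied group
#' of ratios.
#'
#' @param thresholds numeric threshold vector for one participant.
#' @param axes a [hue_axis_set()].
#' @return The threshold ratio (scalar).
#' @export
cvd_threshold_ratio <- function(thresholds, axes = hue_axis_set()) {
  card <- cardinal_axis_ids(axes)
  num <- mean(thresholds[card$l], na.rm = TRUE)
  den <- mean(thresholds[card$s], na.rm = TRUE)
  if (!is.finite(den) || den == 0) stop("zero or missing S-axis threshold mean")
  num / den
}

#' Tukey-fence outlier flags
#'
#' @param values numeric vector (e.g. a group's CVD threshold ratios).
#' @param k fence multiplier (1.5).
#' @return Logical vector, TRUE where the value lies outside
#'   \[Q1 - k IQR, Q3 + k IQR\].
#' @export
tukey_outliers <- function(values, k = 1.5) {
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2L] - q[1L]
  values < q[1L] - k * iqr | values > q[2L] + k * iqr
}
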