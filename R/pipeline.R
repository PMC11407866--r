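#' Study-wide configuration
#'
#' Bundles everything the two analysis pathways need: the device
#' calibration, the two chromaticity-diagram instances (discrimination
#' space and Mondrian/preference space — the two tasks use
#' different cone-fundamental conventions for the two tasks, absorbed here
#' by the calibration and diagram configs rather than by separate code
#' paths), the RAW filter thresholds, the subsampling period, staircase and
#' Mondrian parameters and the permutation count.
#'
#' @param calibration a [calibration_matrix()].
#' @param discrimination_space,mondrian_space [diagram_config()] instances.
#' @param filter_low,filter_high RAW filter thresholds.
#' @param subsample_k subsampling period (5 = every fifth image).
#' @param staircase a [staircase_params()].
#' @param mondrian a [mondrian_params()].
#' @param n_perm permutation count for null bands (10000).
#' @return List of class `study_config`.
#' @export
study_config <- function(calibration = default_calibration(),
                         discrimination_space = diagram_config(
                           fundamentals = "synthetic-EEW"),
                         mondrian_space = diagram_config(
                           fundamentals = "synthetic-illuminantC"),
                         filter_low = 15, filter_high = 15000,
                         subsample_k = 5L,
                         staircase = staircase_params(),
                         mondrian = mondrian_params(),
                         n_perm = 10000L) {
  stopifnot(inherits(calibration, "calibration_matrix"),
            inherits(discrimination_space, "diagram_config"),
            inherits(mondrian_space, "diagram_config"),
            subsample_k >= 1L)
  structure(list(calibration = calibration,
                 discrimination_space = discrimination_space,
                 mondrian_space = mondrian_space,
                 filter_low = filter_low, filter_high = filter_high,
                 subsample_k = as.integer(subsample_k),
                 staircase = staircase, mondrian = mondrian,
                 n_perm = as.integer(n_perm)),
            class = "study_config")
}

mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lower = NA_real_, upper = NA_real_, n = n))
  half <- stats::qt(1 - (1 - level) / 2, n - 1L) * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Run the scene-statistics pipeline
#'
#' Applies the full visual-diet image analysis: every-kth subsampling of
#' the acquisition sequence, dark/saturated pixel filtering, per-image
#' chromaticity clouds, s.d. ellipses, normalized-diagram blue-yellow log
#' axis ratios, and mean saturations in the eight opponent wedges of the
#' Mondrian space. Unreadable or fully filtered images are skipped and
#' logged.
#'
#' @param images either a directory containing 16-bit TIFF acquisitions
#'   (read in sorted filename order) or a list of [raw_image()] objects in
#'   acquisition order.
#' @param cfg a [study_config()].
#' @return List with `per_image` (one row per analysed image), `summary`
#'   (per-site means with 95% CIs of the log axis ratio and the eight wedge
#'   means) and `skipped` (source and reason).
#' @export
run_scene_pipeline <- function(images, cfg = study_config()) {
  if (is.character(images)) {
    paths <- sort(list.files(images, pattern = "\\.tiff?$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(paths) == 0L) stop("no TIFF images found in ", images)
    get <- function(i) read_raw_image(paths[i], site = basename(dirname(paths[i])))
    n_seq <- length(paths)
    src <- basename(paths)
  } else {
    stopifnot(is.list(images), all(vapply(images, inherits, logical(1L),
                                          "raw_image")))
    get <- function(i) images[[i]]
    n_seq <- length(images)
    src <- vapply(seq_len(n_seq), function(i) {
      s <- images[[i]]$site
      if (is.na(s)) sprintf("image_%04d", i) else sprintf("%s_%04d", s, i)
    }, character(1L))
  }
  sel <- subsample_every_kth(n_seq, cfg$subsample_k)
  rows <- list()
  skipped <- list()
  for (i in sel) {
    img <- tryCatch(get(i), error = function(e) e)
    res <- if (inherits(img, "error")) img else tryCatch({
      cloud <- image_chromaticity_cloud(img, cfg$calibration,
                                        low = cfg$filter_low,
                                        high = cfg$filter_high)
      ell <- fit_sd_ellipse(cloud)
      lar <- log_axis_ratio(normalize_cardinal_variances(cloud))
      xy <- mb_to_scaled(data.frame(l = cloud$l, s = cloud$s),
                         cfg$mondrian_space)
      wedges <- suppressWarnings(wedge_mean_saturations(xy))
      c(list(source = src[i],
             site = if (is.na(img$site)) "unknown" else img$site,
             n_kept = length(cloud$l), n_dark = cloud$n_dark,
             n_saturated = cloud$n_saturated, n_invalid = cloud$n_invalid,
             centre_l = unname(ell$centre[1L]),
             centre_s = unname(ell$centre[2L]),
             sd_major = unname(ell$radii[1L]),
             sd_minor = unname(ell$radii[2L]),
             orientation_deg = ell$orientation_deg,
             log_axis_ratio = lar$log_axis_ratio),
        as.list(wedges))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(source = src[i], reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  if (length(rows) == 0L) stop("no analysable images after filtering")
  per_image <- do.call(rbind, rows)
  stat_cols <- c("log_axis_ratio", sprintf("axis_%d", 1:8))
  summaries <- lapply(split(per_image, per_image$site), function(d) {
    stats <- lapply(stat_cols, function(cn) mean_ci(d[[cn]]))
    out <- data.frame(site = d$site[1L], statistic = stat_cols,
                      mean = vapply(stats, `[[`, numeric(1L), "mean"),
                      ci_lower = vapply(stats, `[[`, numeric(1L), "lower"),
                      ci_upper = vapply(stats, `[[`, numeric(1L), "upper"),
                      n_images = nrow(d))
    rownames(out) <- NULL
    out
  })
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(per_image = per_image, summary = summary,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(source = character(0), reason = character(0)))
}

#' Per-site environment saturation curves
#'
#' Extracts, from a [run_scene_pipeline()] result, the per-site mean wedge
#' saturation along each of the eight Mondrian axes (with 95% CIs): the
#' environment curve against which preference curves are correlated.
#'
#' @param scene_result a [run_scene_pipeline()] result.
#' @return List with `means` (sites x 8 matrix) and `ci` (long data.frame).
#' @export
environment_curves <- function(scene_result) {
  s <- scene_result$summary
  wedge <- s[grepl("^axis_", s$statistic), ]
  sites <- unique(wedge$site)
  m <- matrix(NA_real_, length(sites), 8L,
              dimnames = list(sites, sprintf("axis_%d", 1:8)))
  for (i in seq_along(sites)) {
    d <- wedge[wedge$site == sites[i], ]
    m[i, d$statistic] <- d$mean
  }
  list(means = m, ci = wedge)
}

#' Run the discrimination-experiment pipeline
#'
#' For each simulated observer: a full interleaved session (two consecutive
#' 18-reversal staircases per axis), per-axis maximum-likelihood
#' psychometric fits with the 45%-correct threshold criterion, the
#' discrimination ellipse, the normalized blue-yellow log axis ratio and
#' the CVD threshold ratio. Observers with too few fittable axes are
#' excluded with a reason, mirroring the field exclusion rule; CVD outlier
#' flags are assigned over the group by Tukey fences.
#'
#' @param observers list of [observer()] objects (e.g. from
#'   [gen_observer()]).
#' @param cfg a [study_config()].
#' @param axes a [hue_axis_set()].
#' @param seed integer seed; observer i runs with seed `seed + i - 1`.
#' @return List with `results` (one row per observer: thresholds, ellipse
#'   radii/orientation, log axis ratio, CVD ratio and flags) and `logs`
#'   (per-observer trial logs).
#' @export
run_experiment_pipeline <- function(observers, cfg = study_config(),
                                    axes = hue_axis_set(), seed = 1L) {
  stopifnot(is.list(observers),
            all(vapply(observers, inherits, logical(1L), "observer")))
  n_axes <- nrow(axes)
  logs <- vector("list", length(observers))
  rows <- vector("list", length(observers))
  for (i in seq_along(observers)) {
    trials <- run_session(observers[[i]], axes = axes, params = cfg$staircase,
                          seed = seed + i - 1L)
    logs[[i]] <- trials
    fit <- fit_session_thresholds(trials, n_axes = n_axes)
    thr <- fit$thresholds
    n_valid <- sum(is.finite(thr))
    row <- c(list(observer = i, n_trials = nrow(trials),
                  n_fittable_axes = n_valid),
             stats::setNames(as.list(thr), sprintf("thr_%d", seq_len(n_axes))))
    if (n_valid < 5L) {
      row <- c(row, list(excluded = TRUE,
                         exclusion_reason = "psychometric functions could not be fit",
                         sd_major = NA_real_, sd_minor = NA_real_,
                         orientation_deg = NA_real_,
                         log_axis_ratio = NA_real_, cvd_ratio = NA_real_))
    } else {
      ell <- fit_discrimination_ellipse(thr, axes)
      lar <- tryCatch(discrimination_log_axis_ratio(thr, axes),
                      error = function(e) NULL)
      cvd <- tryCatch(cvd_threshold_ratio(thr, axes),
                      error = function(e) NA_real_)
      row <- c(row, list(excluded = FALSE, exclusion_reason = NA_character_,
                         sd_major = unname(ell$radii[1L]),
                         sd_minor = unname(ell$radii[2L]),
                         orientation_deg = ell$orientation_deg,
                         log_axis_ratio = if (is.null(lar)) NA_real_ else
                           lar$log_axis_ratio,
                         cvd_ratio = cvd))
    }
    rows[[i]] <- as.data.frame(row)
  }
  results <- do.call(rbind, rows)
  ok <- is.finite(results$cvd_ratio)
  results$cvd_outlier <- NA
  results$cvd_outlier[ok] <- tukey_outliers(results$cvd_ratio[ok])
  list(results = results, logs = logs)
}

#' Write pipeline tables to CSV
#'
#' @param result a [run_scene_pipeline()] or [run_experiment_pipeline()]
#'   result.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_results_csv <- function(result, dir, prefix = "chromadiet") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (nm in names(result)) {
    x <- result[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
      utils::write.csv(x, f, row.names = FALSE)
      written <- c(written, f)
    }
  }
  invisible(written)
}
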