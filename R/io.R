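#' Write a RAW image as 16-bit TIFF
#'
#' Values are stored losslessly for integer 14-bit data (scaled by 1/65535
#' as the TIFF convention requires). Non-integer synthetic values are
#' quantized to 16-bit on write.
#'
#' @param img a [raw_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raw_image <- function(img, path) {
  stopifnot(inherits(img, "raw_image"))
  tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a RAW image from 16-bit TIFF
#'
#' @param path TIFF file path.
#' @param site optional site label to attach.
#' @return A [raw_image()].
#' @export
read_raw_image <- function(path, site = NA_character_) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) != 3L || dim(px)[3L] < 3L) {
    stop("expected an RGB TIFF: ", path)
  }
  raw_image(round(px[, , 1:3] * 65535), site = site)
}

#' Write a study configuration (calibration + diagram spaces) to JSON
#'
#' @param cfg a [study_config()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  obj <- list(
    calibration = cfg$calibration$m,
    discrimination_space = list(
      white_point = cfg$discrimination_space$white_point,
      axis_scale = cfg$discrimination_space$axis_scale,
      fundamentals = cfg$discrimination_space$fundamentals),
    mondrian_space = list(
      white_point = cfg$mondrian_space$white_point,
      axis_scale = cfg$mondrian_space$axis_scale,
      fundamentals = cfg$mondrian_space$fundamentals),
    filter_low = cfg$filter_low, filter_high = cfg$filter_high,
    subsample_k = cfg$subsample_k,
    staircase = unclass(cfg$staircase),
    mondrian = unclass(cfg$mondrian),
    n_perm = cfg$n_perm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study configuration from JSON
#'
#' @param path JSON file path (e.g. the shipped
#'   `system.file("extdata", "study_config.json", package = "chromadiet")`).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_config(
    calibration = calibration_matrix(obj$calibration),
    discrimination_space = diagram_config(
      white_point = unlist(obj$discrimination_space$white_point),
      axis_scale = unlist(obj$discrimination_space$axis_scale),
      fundamentals = obj$discrimination_space$fundamentals),
    mondrian_space = diagram_config(
      white_point = unlist(obj$mondrian_space$white_point),
      axis_scale = unlist(obj$mondrian_space$axis_scale),
      fundamentals = obj$mondrian_space$fundamentals),
    filter_low = obj$filter_low, filter_high = obj$filter_high,
    subsample_k = obj$subsample_k,
    staircase = do.call(staircase_params, as.list(obj$staircase)),
    mondrian = do.call(mondrian_params, as.list(obj$mondrian)),
    n_perm = obj$n_perm)
}
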