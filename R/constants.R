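#' Image-acquisition counts of the visual-diet study
#'
#' Per-site numbers of head-mounted-camera timelapse images acquired in the
#' three studied environments (a rainforest site, a high-altitude city and a
#' UK seaside city). These printed counts, together with the every-fifth
#' subsampling rule, determine the analysed subsample sizes.
#'
#' @return data.frame with columns `location` and `n_acquired`.
#' @examples
#' counts <- acquisition_counts()
#' sum(counts$n_acquired)  # 18331
#' vapply(counts$n_acquired,
#'        function(n) length(subsample_every_kth(n, 5)), integer(1))
#' @export
acquisition_counts <- function() {
  data.frame(location = c("Esmeraldas", "Quito", "Sussex"),
             n_acquired = c(4690L, 8250L, 5391L))
}
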