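# Shared fixtures for the test suite. Everything is generated in code; no
# binary fixtures are stored.

# deterministic responder cycling through a fixed correct/incorrect pattern
pattern_responder <- function(pattern) {
  i <- 0L
  function(saturation) {
    i <<- i + 1L
    pattern[(i - 1L) %% length(pattern) + 1L]
  }
}

# brute-force Spearman: Pearson correlation of mid-ranks (definition), with
# the classical 1 - 6*sum(d^2)/(n(n^2-1)) shortcut exact for tie-free input
brute_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# uniform small image with a few pixels overridden; values on the 14-bit scale
flat_image <- function(h = 4L, w = 4L, value = c(4000, 5000, 3000),
                       site = "fixture") {
  px <- array(rep(value, each = h * w), dim = c(h, w, 3L))
  raw_image(px, site = site)
}

# stochastic responder drawing from the observer's psychometric function
observer_responder_test <- function(obs, axis) {
  function(saturation) {
    stats::runif(1L) < observer_p_correct(obs, axis, saturation)
  }
}

# true 45%-correct saturation for a simulated observer
true_threshold_45 <- function(obs) {
  obs$thresholds * exp(stats::qlogis(
    (0.45 - obs$guess_rate) / (1 - obs$guess_rate - obs$lapse_rate)
  ) / obs$slope)
}
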