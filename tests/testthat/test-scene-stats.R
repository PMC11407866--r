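test_that("every-kth subsampling matches the floor(n/k) rule", {
  expect_length(subsample_every_kth(4, 5), 0L)
  expect_identical(subsample_every_kth(10, 5), c(5L, 10L))
  expect_identical(subsample_every_kth(7, 3), c(3L, 6L))
  expect_error(subsample_every_kth(10, 0), "positive")
  set.seed(3)
  for (i in 1:20) {
    n <- sample.int(5000, 1L)
    k <- sample.int(9, 1L)
    expect_length(subsample_every_kth(n, k), n %/% k)
  }
})

test_that("pixel filter keeps boundary values and conserves counts", {
  img <- flat_image(3, 3, c(100, 100, 100))
  img$pixels[1, 1, ] <- c(14, 100, 100)      # dark (one channel below 15)
  img$pixels[1, 2, ] <- c(15, 15, 15)        # boundary: kept
  img$pixels[1, 3, ] <- c(15000, 20, 20)     # boundary: kept
  img$pixels[2, 1, ] <- c(15001, 20, 20)     # saturated
  vm <- valid_pixel_mask(img)
  expect_false(vm$mask[1, 1])
  expect_true(vm$mask[1, 2])
  expect_true(vm$mask[1, 3])
  expect_false(vm$mask[2, 1])
  expect_equal(vm$n_dark, 1L)
  expect_equal(vm$n_saturated, 1L)
  expect_equal(vm$n_kept, 7L)

  # conservation: kept + dark + saturated = total, on random images,
  # including pixels violating both rules (counted once, as dark)
  set.seed(4)
  for (i in 1:10) {
    px <- array(runif(3 * 48, 0, 16383), dim = c(4, 12, 3))
    px[1, 1, ] <- c(5, 16000, 100)
    vm <- valid_pixel_mask(raw_image(px))
    expect_equal(vm$n_kept + vm$n_dark + vm$n_saturated, 48L)
  }
})

test_that("image_chromaticity_cloud converts kept pixels and counts exclusions", {
  cal <- default_calibration()
  img <- flat_image(4, 4)
  cl <- image_chromaticity_cloud(img, cal)
  expect_length(cl$l, 16L)
  expect_equal(var(cl$l), 0)
  expect_equal(var(cl$s), 0)

  img$pixels[2, 2, ] <- c(10, 10, 10)
  cl2 <- image_chromaticity_cloud(img, cal)
  expect_length(cl2$l, 15L)
  expect_equal(cl2$n_dark, 1L)

  dark <- flat_image(2, 2, c(1, 1, 1))
  expect_error(image_chromaticity_cloud(dark, cal), "empty cloud")

  # synthetic render round trip: planted chromaticities recovered exactly
  set.seed(5)
  l <- runif(24, 0.5, 0.66)
  s <- runif(24, 0.5, 1.5)
  rgb <- render_chromaticities(l, s, 5000, cal)
  img3 <- raw_image(array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = c(4, 6, 3)))
  cl3 <- image_chromaticity_cloud(img3, cal)
  expect_equal(cl3$l, l, tolerance = 1e-6)
  expect_equal(cl3$s, s, tolerance = 1e-6)
})

test_that("fit_sd_ellipse is the covariance eigendecomposition", {
  set.seed(6)
  # isotropic cloud: circle
  xy <- cbind(rnorm(2000), rnorm(2000))
  e <- fit_sd_ellipse(xy)
  expect_equal(unname(e$radii[1] / e$radii[2]), 1, tolerance = 0.1)

  # collinear cloud: degenerate, minor radius 0
  line <- cbind(1:10, 2 * (1:10) + 3)
  el <- fit_sd_ellipse(line)
  expect_true(el$degenerate)
  expect_equal(unname(el$radii[2]), 0, tolerance = 1e-9)
  expect_equal(el$orientation_deg, atan(2) * 180 / pi, tolerance = 1e-6)

  # known covariance: radii are sqrt eigenvalues, orientation 0
  big <- MASS::mvrnorm(1e5, c(0, 0), matrix(c(2, 0, 0, 0.5), 2))
  eb <- fit_sd_ellipse(big)
  expect_equal(unname(eb$radii), c(sqrt(2), sqrt(0.5)), tolerance = 0.02)
  expect_lt(min(eb$orientation_deg, 180 - eb$orientation_deg), 2)

  # oracle equivalence with prcomp on arbitrary clouds
  for (i in 1:5) {
    xy <- matrix(rnorm(600), ncol = 2) %*% matrix(rnorm(4), 2)
    e1 <- fit_sd_ellipse(xy)
    p <- prcomp(xy)
    expect_equal(unname(e1$radii), unname(p$sdev), tolerance = 1e-9)
    expect_equal(unname(e1$centre), unname(colMeans(xy)), tolerance = 1e-12)
    ang <- unname((atan2(p$rotation[2, 1], p$rotation[1, 1]) * 180 / pi) %% 180)
    expect_equal(e1$orientation_deg, ang, tolerance = 1e-6)
  }
})

test_that("normalize_cardinal_variances gives unit variances and is idempotent", {
  set.seed(7)
  cl <- chromaticity_cloud(rnorm(500, sd = 2), rnorm(500, sd = 1))
  ncl <- normalize_cardinal_variances(cl)
  expect_equal(var(ncl$l), 1, tolerance = 1e-9)
  expect_equal(var(ncl$s), 1, tolerance = 1e-9)
  expect_equal(ncl$l, cl$l / sd(cl$l), tolerance = 1e-12)
  ncl2 <- normalize_cardinal_variances(ncl)
  expect_equal(ncl2$l, ncl$l, tolerance = 1e-12)

  flat <- chromaticity_cloud(rep(1, 10), rnorm(10))
  expect_error(normalize_cardinal_variances(flat), "zero variance")
})

test_that("log_axis_ratio matches the bivariate-normal closed form", {
  # 0.5 * log((1-c)/(1+c)) for unit cardinal variances and correlation c
  set.seed(8)
  for (c_ in c(-0.6, -0.3, 0.4)) {
    xy <- MASS::mvrnorm(1e5, c(0, 0), matrix(c(1, c_, c_, 1), 2))
    cl <- normalize_cardinal_variances(chromaticity_cloud(xy[, 1], xy[, 2]))
    lar <- log_axis_ratio(cl)$log_axis_ratio
    expect_equal(lar, 0.5 * log((1 - c_) / (1 + c_)), tolerance = 0.02)
  }

  # mirroring l about its mean flips the sign exactly
  xy <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, -0.5, -0.5, 1), 2))
  cl <- chromaticity_cloud(xy[, 1], xy[, 2])
  mir <- chromaticity_cloud(2 * mean(xy[, 1]) - xy[, 1], xy[, 2])
  expect_equal(log_axis_ratio(mir)$log_axis_ratio,
               -log_axis_ratio(cl)$log_axis_ratio, tolerance = 1e-12)
})

test_that("wedge means pool opponent wedges with half-open boundaries", {
  # 4 pixels at hue 0 with saturations 1..4: axis 1 mean 2.5, others empty
  xy <- data.frame(x = 1:4, y = 0)
  expect_warning(w <- wedge_mean_saturations(xy), "empty wedge")
  expect_equal(unname(w[1]), 2.5)
  expect_true(all(is.na(w[2:8])))

  # opponent pooling: 0 deg and 180 deg share axis 1
  xy2 <- data.frame(x = c(1, -3), y = c(0, 0))
  w2 <- suppressWarnings(wedge_mean_saturations(xy2))
  expect_equal(unname(w2[1]), 2)

  # hue exactly 11.25 deg belongs to axis 2 (half-open upper edge);
  # brute-force check of the boundary rule against explicit angular windows
  sc <- function(a, r = 1) data.frame(x = r * cospi(a / 180), y = r * sinpi(a / 180))
  w3 <- suppressWarnings(wedge_mean_saturations(sc(11.25)))
  expect_true(is.na(w3[1]) && w3[2] == 1)
  w4 <- suppressWarnings(wedge_mean_saturations(sc(11.249)))
  expect_true(w4[1] == 1 && is.na(w4[2]))
  for (a in c(0, 33.7, 78.75, 101.24, 168.7, 222, 348.7)) {
    xy1 <- sc(a)
    hue <- hue_saturation(xy1)$hue_deg  # bin the hue the pixel actually has
    w <- suppressWarnings(wedge_mean_saturations(xy1))
    poles <- 22.5 * (0:7)
    hit <- which(vapply(poles, function(p) {
      d <- (hue - (p - 11.25)) %% 180
      d >= 0 && d < 22.5
    }, logical(1)))
    expect_equal(unname(which(!is.na(w))), hit, info = paste("hue", a))
  }

  # partition: every chromatic pixel lands in exactly one wedge pair
  set.seed(9)
  n <- 5000
  xyr <- data.frame(x = rnorm(n), y = rnorm(n))
  hs <- hue_saturation(xyr)
  counts <- integer(8)
  for (k in 1:8) {
    d <- (hs$hue_deg %% 180 - (22.5 * (k - 1) - 11.25)) %% 180
    counts[k] <- sum(d < 22.5, na.rm = TRUE)
  }
  expect_equal(sum(counts), n)
  w <- wedge_mean_saturations(xyr)
  expect_false(anyNA(w))
})
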