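test_that("observer psychometric function has 4AFC floor, ceiling and midpoint", {
  obs <- observer(thresholds = rep(0.1, 8), slope = 2, lapse_rate = 0)
  expect_equal(observer_p_correct(obs, 1, 0), 0.25)
  expect_equal(observer_p_correct(obs, 1, 1e-9), 0.25, tolerance = 1e-6)
  expect_equal(observer_p_correct(obs, 1, 1e6), 1, tolerance = 1e-6)
  # logistic midpoint identity at the true threshold
  obs2 <- observer(rep(0.1, 8), slope = 3, lapse_rate = 0.1)
  expect_equal(observer_p_correct(obs2, 1, 0.1), 0.25 + (1 - 0.25 - 0.1) / 2)
  # monotone nondecreasing
  p <- observer_p_correct(obs2, 1, seq(0.001, 1, length.out = 50))
  expect_true(all(diff(p) >= 0))
})

test_that("staircase follows the multiplicative rules (hand trace C,C,W,C)", {
  st <- run_staircase(pattern_responder(c(TRUE, TRUE, FALSE, TRUE)),
                      start = 1, params = staircase_params(n_reversals = 2))
  expect_equal(st$trials$saturation, c(1.0, 0.5, 0.25, 0.375))
  expect_equal(which(st$trials$reversal), c(3L, 4L))
  expect_equal(st$n_reversals, 2L)
})

test_that("staircase guards against nontermination and clamps at s_max", {
  # always-correct: pure geometric descent, no reversals, guard trips
  err <- tryCatch(
    run_staircase(function(s) TRUE, start = 1,
                  params = staircase_params(n_reversals = 18, max_trials = 40)),
    condition = function(c) c)
  expect_s3_class(err, "chromadiet_staircase_overrun")
  expect_equal(err$n_reversals, 0L)
  expect_equal(err$trials$saturation, 0.5^(0:39))

  # always-wrong: stays clamped at s_max
  err2 <- tryCatch(
    run_staircase(function(s) FALSE, start = 1,
                  params = staircase_params(n_reversals = 18, max_trials = 30)),
    condition = function(c) c)
  expect_s3_class(err2, "chromadiet_staircase_overrun")
  expect_true(all(err2$trials$saturation == 1))
})

test_that("staircase sequences obey the update rule at every trial (replay)", {
  set.seed(31)
  obs <- observer(rep(0.1, 8))
  for (rep_ in 1:5) {
    tr <- run_staircase(observer_responder_test(obs, 1L),
                        params = staircase_params())$trials
    s <- tr$saturation
    for (t in seq_len(nrow(tr) - 1L)) {
      expected <- min(1, s[t] * if (tr$correct[t]) 0.5 else 1.5)
      expect_equal(s[t + 1L], expected)
    }
    # reversal = change of step direction between consecutive trials
    dir <- ifelse(tr$correct, -1L, 1L)
    expect_equal(tr$reversal, c(FALSE, diff(dir) != 0))
    expect_equal(sum(tr$reversal), 18L)
  }
})

test_that("sessions are seed-reproducible and conserve per-axis bookkeeping", {
  obs <- gen_observer(observer_ground_truth(c(0.12, 0.08)))
  t1 <- run_session(obs, seed = 99)
  t2 <- run_session(obs, seed = 99)
  expect_identical(t1, t2)

  # every axis contributes exactly two staircases of 18 reversals each
  for (a in 1:8) {
    for (ph in 1:2) {
      expect_equal(sum(t1$reversal[t1$axis == a & t1$staircase == ph]), 18L)
    }
  }
  expect_equal(nrow(t1), sum(table(t1$axis)))

  # one-axis degenerate session == two consecutive staircases run directly
  # with the identical RNG stream
  obs_single <- observer(thresholds = 0.1, slope = 3)
  set.seed(123)
  s1 <- run_staircase(observer_responder_test(obs_single, 1L),
                      params = staircase_params())
  s2 <- run_staircase(observer_responder_test(obs_single, 1L),
                      start = s1$final_saturation,
                      params = staircase_params())
  axes_one <- structure(matrix(c(1, 0), 1L, 2L,
                               dimnames = list("axis_0.0", c("x", "y"))),
                        angles_deg = 0,
                        class = c("hue_axis_set", "matrix", "array"))
  sess <- run_session(obs_single, axes = axes_one, seed = 123)
  expect_equal(sess$saturation,
               c(s1$trials$saturation, s2$trials$saturation))
  expect_equal(sess$correct, c(s1$trials$correct, s2$trials$correct))
})

test_that("psychometric fit recovers a known observer and handles degeneracy", {
  set.seed(32)
  obs <- observer(thresholds = rep(0.1, 8), slope = 2, lapse_rate = 0)
  lev <- exp(seq(log(0.02), log(0.6), length.out = 9))
  sat <- rep(lev, each = 500)
  p <- observer_p_correct(obs, 1, sat)
  corr <- runif(length(sat)) < p
  f <- fit_psychometric(sat, corr)
  expect_false(f$unfittable)
  true45 <- true_threshold_45(obs)[1]
  expect_lt(abs(f$threshold - true45) / true45, 0.10)

  # log-axis equivariance: scaling saturations scales the threshold
  f10 <- fit_psychometric(sat * 10, corr)
  expect_equal(f10$threshold, 10 * f$threshold, tolerance = 1e-4)

  # degenerate data flagged, not crashed
  expect_true(fit_psychometric(sat, rep(TRUE, length(sat)))$unfittable)
  expect_true(fit_psychometric(sat, rep(FALSE, length(sat)))$unfittable)
  expect_true(fit_psychometric(rep(0.1, 50),
                               runif(50) < 0.6)$unfittable)
})

test_that("discrimination ellipse fit is exact on noiseless conic data", {
  axes <- hue_axis_set()
  # isotropy: equal thresholds give a circle of that radius
  iso <- fit_discrimination_ellipse(rep(0.3, 8), axes)
  expect_true(iso$valid)
  expect_equal(unname(iso$radii), c(0.3, 0.3), tolerance = 1e-9)

  # exact interpolation of a known rotated ellipse (radii 2, 1 at 45 deg)
  R <- matrix(c(cospi(0.25), sinpi(0.25), -sinpi(0.25), cospi(0.25)), 2)
  A_true <- R %*% diag(c(1 / 4, 1)) %*% t(R)
  thr <- apply(axes, 1, function(u) 1 / sqrt(drop(t(u) %*% A_true %*% u)))
  fit <- fit_discrimination_ellipse(thr, axes)
  expect_equal(unname(fit$radii), c(2, 1), tolerance = 1e-6)
  expect_equal(fit$orientation_deg, 45, tolerance = 1e-6)
  expect_equal(fit$A, A_true, tolerance = 1e-6)

  # brute-force oracle: dense grid over (log radii, angle) parameterization
  # confirms the least-squares solution on noiseless 8-point input
  obj <- function(par) {
    Rm <- matrix(c(cos(par[3]), sin(par[3]), -sin(par[3]), cos(par[3])), 2)
    A <- Rm %*% diag(exp(-2 * par[1:2])) %*% t(Rm)
    pts <- thr * axes
    sum((rowSums((pts %*% A) * pts) - 1)^2)
  }
  g <- optim(c(log(2.1), log(0.9), 0.7), obj,
             control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(sort(exp(g$par[1:2])), c(1, 2), tolerance = 1e-4)

  # robustness: a missing axis still yields the same ellipse (7 points)
  thr_na <- thr
  thr_na[3] <- NA
  fit7 <- fit_discrimination_ellipse(thr_na, axes)
  expect_equal(fit7$A, A_true, tolerance = 1e-6)
  expect_equal(fit7$n_points, 7L)
  expect_error(fit_discrimination_ellipse(c(1, 1, 1, 1, NA, NA, NA, NA), axes),
               "at least 5")
})

test_that("discrimination log axis ratio reads the normalized ellipse diagonals", {
  axes <- hue_axis_set()
  expect_equal(discrimination_log_axis_ratio(rep(0.2, 8), axes)$log_axis_ratio,
               0, tolerance = 1e-9)

  # ellipse with diagonal radii (2, 1): blue-yellow thresholds twice the
  # reflected-axis thresholds, cardinals equal -> exactly ln 2
  gt <- observer_ground_truth(c(2, 1), slope = 3, lapse = 0)
  thr <- gen_observer(gt)$thresholds
  expect_equal(thr[c(4, 8)], rep(2, 2), tolerance = 1e-12)
  expect_equal(thr[c(2, 6)], rep(1, 2), tolerance = 1e-12)
  lar <- discrimination_log_axis_ratio(thr, axes)
  expect_equal(lar$log_axis_ratio, log(2), tolerance = 1e-9)

  # swapping the two diagonals flips the sign
  thr_sw <- thr
  thr_sw[c(2, 6)] <- thr[c(4, 8)]
  thr_sw[c(4, 8)] <- thr[c(2, 6)]
  expect_equal(discrimination_log_axis_ratio(thr_sw, axes)$log_axis_ratio,
               -log(2), tolerance = 1e-9)

  # invariance to uniform scaling of all thresholds
  for (k in c(0.01, 0.5, 7)) {
    expect_equal(discrimination_log_axis_ratio(k * thr, axes)$log_axis_ratio,
                 log(2), tolerance = 1e-9)
  }
})

test_that("CVD threshold ratio and Tukey-fence screening", {
  axes <- hue_axis_set()
  expect_equal(cvd_threshold_ratio(rep(0.2, 8), axes), 1)
  thr <- c(2, 1, 1, 1, 2, 1, 1, 1)  # l-axes (1, 5) at 2; s-axes (3, 7) at 1
  expect_equal(cvd_threshold_ratio(thr, axes), 2)

  ratios <- c(rep(1.0, 29), 10.0)
  flags <- tukey_outliers(ratios)
  expect_identical(which(flags), 30L)
})
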