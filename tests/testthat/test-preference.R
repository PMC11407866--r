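test_that("ranking sessions follow strengths at zero noise and are reproducible", {
  r <- simulate_ranking_session(8:1, noise = 0)
  expect_identical(r, 1:8)
  strengths <- c(0.3, -1, 2, 0.5, 0, 1.2, -0.7, 0.9)
  r1 <- simulate_ranking_session(strengths, noise = 2, seed = 5)
  r2 <- simulate_ranking_session(strengths, noise = 2, seed = 5)
  expect_identical(sort(r1), 1:8)
  expect_identical(r1, r2)
})

test_that("equal strengths produce uniform random permutations", {
  # with equal strengths, every step picks uniformly among the remaining:
  # marginal rank of any stimulus is uniform on 1..8 (chi-square sanity)
  set.seed(6)
  n <- 1e4
  first_rank <- integer(n)
  for (i in seq_len(n)) {
    first_rank[i] <- simulate_ranking_session(rep(0, 8), noise = 1)[1]
  }
  expect_gt(chisq.test(tabulate(first_rank, 8))$p.value, 0.001)
})

test_that("mean ranks conserve the grand mean of 4.5", {
  pm <- preference_matrix(participant = rep(1, 8), trial = rep(1, 8),
                          stimulus = 1:8, rank = 1:8)
  expect_equal(unname(mean_ranks(pm)), as.numeric(1:8))

  pm2 <- preference_matrix(participant = rep(1, 16), trial = rep(1:2, each = 8),
                           stimulus = rep(1:8, 2), rank = c(1:8, 8:1))
  expect_equal(unname(mean_ranks(pm2)), rep(4.5, 8))

  set.seed(7)
  pm3 <- gen_preference_population(rnorm(8), noise = 1.5,
                                   n_participants = 6, n_trials = 3)
  expect_equal(mean(mean_ranks(pm3)), 4.5, tolerance = 1e-12)
  expect_error(preference_matrix(rep(1, 8), rep(1, 8), 1:8, rep(1L, 8)),
               "permutation")
})

test_that("preference population converges to strengths and to the null", {
  strengths <- c(5, 3, 8, 1, 7, 2, 6, 4)
  pm0 <- gen_preference_population(strengths, noise = 0,
                                   n_participants = 3, n_trials = 2, seed = 1)
  mr0 <- mean_ranks(pm0)
  expect_equal(unname(mr0), rank(-strengths))

  set.seed(8)
  pm <- gen_preference_population(strengths, noise = 0.8,
                                  n_participants = 60, n_trials = 5)
  expect_equal(spearman_rho(mean_ranks(pm), -strengths), 1, tolerance = 1e-9)

  pm_inf <- gen_preference_population(strengths, noise = 1e6,
                                      n_participants = 200, n_trials = 5,
                                      seed = 9)
  expect_lt(max(abs(mean_ranks(pm_inf) - 4.5)), 0.3)
})

test_that("permutation null band is centred on 4.5 and scales as 1/sqrt(N)", {
  b1 <- permutation_null_band(10, 5, n_perm = 1500, seed = 10)
  expect_equal(mean(b1$centre), 4.5, tolerance = 1e-9)  # exact conservation
  expect_lt(max(abs(b1$centre - 4.5)), 0.1)

  # per-trial rank variance is 21/4; band half-width ~ 1/sqrt(n_p * n_t)
  b4 <- permutation_null_band(40, 5, n_perm = 1500, seed = 10)
  hw1 <- mean(b1$upper - b1$lower) / 2
  hw4 <- mean(b4$upper - b4$lower) / 2
  expect_equal(hw1 / hw4, 2, tolerance = 0.15)
  expect_equal(hw1, 1.96 * sqrt(21 / 4 / 50), tolerance = 0.1)

  # degenerate single-permutation band equals that draw
  b0 <- permutation_null_band(5, 2, n_perm = 1, seed = 11)
  expect_equal(b0$lower, b0$upper)
  expect_equal(b0$lower, b0$perm_means[1, ])
})

test_that("spearman_rho equals the brute-force definition", {
  expect_equal(spearman_rho(1:8, 1:8), 1)
  expect_equal(spearman_rho(1:8, 8:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  # exhaustive tie-free permutations of length 4 against 1 - 6*sum(d^2)/...
  perms4 <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms4 <- perms4[apply(perms4, 1, function(p) length(unique(p)) == 4), ]
  for (i in seq_len(nrow(perms4))) {
    p <- perms4[i, ]
    d2 <- sum((rank(p) - rank(1:4))^2)
    expect_equal(spearman_rho(1:4, p), 1 - 6 * d2 / (4 * 15))
    expect_equal(spearman_rho(1:4, p), brute_spearman(1:4, p))
  }

  # random length-8 inputs with ties: mid-rank Pearson oracle
  set.seed(12)
  for (i in 1:200) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- rnorm(8)
    if (sd(x) == 0) next
    expect_equal(spearman_rho(x, y), brute_spearman(x, y), tolerance = 1e-12)
  }

  expect_warning(out <- spearman_rho(rep(1, 8), 1:8), "zero rank variance")
  expect_true(is.na(out))
})

test_that("Zou CI behaves at the symmetric null and the dependent limit", {
  ci <- zou_ci_difference(0.5, 0.5, 0.3, n = 30)
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)

  # as r23 -> 1 with r12 = r13, the interval tightens around 0
  w <- sapply(c(0.3, 0.8, 0.99), function(r23) {
    diff(zou_ci_difference(0.5, 0.5, r23, n = 30))
  })
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], 0.5 * w[1])

  expect_error(zou_ci_difference(1, 0.5, 0.3, 10), "strictly within")
  expect_error(zou_ci_difference(0.5, 0.2, 0.3, 3), "at least 4")
})

test_that("preference-environment correlations recover planted structure", {
  env <- rbind(siteA = c(0.1, 0.2, 0.4, 0.7, 0.9, 0.6, 0.3, 0.15),
               siteB = c(0.9, 0.7, 0.5, 0.3, 0.1, 0.2, 0.4, 0.6))
  # environment curve as its own (rating) preference: diagonal 1
  rho <- preference_environment_correlation(env, env, type = "rating")
  expect_equal(unname(diag(rho)), c(1, 1))

  # ranking population planted to prefer siteA's curve: positive recovered
  # correlation with siteA, via the rank sign convention
  set.seed(13)
  pm <- gen_preference_population(env["siteA", ] * 10, noise = 0.5,
                                  n_participants = 40, n_trials = 5)
  pref <- rbind(groupA = mean_ranks(pm))
  rho2 <- preference_environment_correlation(pref, env, type = "rank")
  expect_gt(rho2["groupA", "siteA"], 0.9)
  expect_lt(rho2["groupA", "siteB"], 0)

  # reversed-rank transform of the environment curve gives exactly -1 -> +1
  pref_rev <- rbind(g = rank(-env["siteA", ]))
  rho3 <- preference_environment_correlation(pref_rev, env, type = "rank")
  expect_equal(unname(rho3["g", "siteA"]), 1)
})
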