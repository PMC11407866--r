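#' Simulate one preference-ranking session
#'
#' Emulates the ranking task: all stimuli are shown, the favourite is chosen
#' and removed, and the rest are shown again until one remains. The
#' respondent model is a strength value per stimulus plus fresh Gaussian
#' noise at every choice; at each step the remaining stimulus with the
#' highest noisy strength receives the next rank (1 = chosen first / most
#' preferred).
#'
#' @param strengths numeric vector of latent preference strengths.
#' @param noise nonnegative noise standard deviation; 0 gives the
#'   deterministic strength order, large values approach uniform random
#'   permutations.
#' @param seed optional integer RNG seed.
#' @return Integer vector `r` with `r[i]` = rank given to stimulus i (a
#'   permutation of 1..length(strengths)).
#' @export
simulate_ranking_session <- function(strengths, noise = 1, seed = NULL) {
  stopifnot(is.numeric(strengths), length(strengths) >= 2L, noise >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(strengths)
  remaining <- seq_len(n)
  ranks <- integer(n)
  for (r in seq_len(n - 1L)) {
    util <- strengths[remaining] + stats::rnorm(length(remaining), 0, noise)
    pick <- remaining[which.max(util)]
    ranks[pick] <- r
    remaining <- remaining[remaining != pick]
  }
  ranks[remaining] <- n
  ranks
}

#' Assemble a preference matrix from per-trial rank vectors
#'
#' @param participant,trial,stimulus,rank equal-length vectors in long
#'   format; every (participant, trial) must hold a full permutation of
#'   1..n_stimuli over the stimuli.
#' @return data.frame of class `preference_matrix`.
#' @export
preference_matrix <- function(participant, trial, stimulus, rank) {
  d <- data.frame(participant = participant, trial = trial,
                  stimulus = as.integer(stimulus), rank = as.integer(rank))
  n_stim <- length(unique(d$stimulus))
  key <- interaction(d$participant, d$trial, drop = TRUE)
  ok <- tapply(d$rank, key, function(r) {
    length(r) == n_stim && identical(sort(r), seq_len(n_stim))
  })
  if (!all(ok)) {
    stop("every (participant, trial) must be a permutation of 1..",
         n_stim)
  }
  class(d) <- c("preference_matrix", "data.frame")
  d
}

#' Mean rank per stimulus
#'
#' Averages ranks over participants and trials. Because every trial is a
#' permutation of 1..n, the grand mean of the per-stimulus means is exactly
#' (n + 1) / 2 (4.5 for 8 stimuli).
#'
#' @param prefs a [preference_matrix()] (or data.frame with `stimulus` and
#'   `rank` columns).
#' @return Named numeric vector of per-stimulus mean ranks.
#' @export
mean_ranks <- function(prefs) {
  stopifnot(nrow(prefs) >= 1L)
  m <- tapply(prefs$rank, prefs$stimulus, mean)
  out <- as.numeric(m)
  names(out) <- sprintf("stim_%s", names(m))
  out
}

rank_rows <- function(n_rows, n_stimuli) {
  # ranks of i.i.d. uniforms row-wise: rank_ij = 1 + #{k: x_ik < x_ij}
  X <- matrix(stats::runif(n_rows * n_stimuli), n_rows, n_stimuli)
  R <- matrix(1, n_rows, n_stimuli)
  for (j in seq_len(n_stimuli)) {
    for (k in seq_len(n_stimuli)) {
      if (k != j) R[, j] <- R[, j] + (X[, k] < X[, j])
    }
  }
  R
}

#' Permutation null band for mean preference ranks
#'
#' Null distribution of per-stimulus mean ranks under fully random
#' responding: each permutation replaces every trial of every participant
#' with an independent uniform random permutation of 1..n_stimuli, and the
#' per-stimulus mean rank is recorded. The band is the (alpha/2,
#' 1 - alpha/2) percentile envelope over permutations, centred on
#' (n_stimuli + 1)/2.
#'
#' @param n_participants,n_trials experiment size whose null is wanted.
#' @param n_stimuli number of stimuli (8).
#' @param n_perm number of permutations (10000).
#' @param alpha band level (0.05 for a 95% band).
#' @param seed optional integer RNG seed.
#' @return List of class `permutation_band`: `lower`, `upper`, `centre`
#'   (per-stimulus), `n_perm`, `alpha`, and `perm_means` (the n_perm x
#'   n_stimuli matrix of null mean ranks).
#' @export
permutation_null_band <- function(n_participants, n_trials, n_stimuli = 8L,
                                  n_perm = 10000L, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(n_participants >= 1L, n_trials >= 1L, n_perm >= 1L,
            alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nT <- n_participants * n_trials
  means <- matrix(NA_real_, n_perm, n_stimuli)
  chunk <- max(1L, min(n_perm, as.integer(2e6 / (nT * n_stimuli)) + 1L))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    R <- rank_rows(m * nT, n_stimuli)
    grp <- rep(seq_len(m), each = nT)
    means[done + seq_len(m), ] <- rowsum(R, grp) / nT
    done <- done + m
  }
  qs <- apply(means, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(lower = qs[1L, ], upper = qs[2L, ],
                 centre = colMeans(means), n_perm = n_perm, alpha = alpha,
                 perm_means = means),
            class = "permutation_band")
}

#' @export
print.permutation_band <- function(x, ...) {
  cat(sprintf(
    "permutation null band (%d permutations, %.0f%% level): mean half-width %.3f, centre %.3f\n",
    x$n_perm, 100 * (1 - x$alpha), mean(x$upper - x$lower) / 2,
    mean(x$centre)))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with ties mid-ranked. Returns `NA` with a warning when
#' either input has zero rank variance (the coefficient is undefined).
#'
#' @param x,y equal-length numeric vectors.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Zou confidence interval for a difference of dependent correlations
#'
#' Confidence interval for rho12 - rho13 when the two correlations share
#' variable 1 (overlapping dependent correlations): Fisher-z limits for each
#' correlation are combined using the asymptotic correlation between the two
#' sample coefficients.
#'
#' @param r12,r13 the two correlations being compared (each in (-1, 1)).
#' @param r23 the correlation between the two non-shared variables.
#' @param n sample size (number of paired observations, >= 4).
#' @param alpha 1 - confidence level (0.05).
#' @return Length-2 numeric vector (lower, upper) for r12 - r13.
#' @export
zou_ci_difference <- function(r12, r13, r23, n, alpha = 0.05) {
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("correlations must lie strictly within (-1, 1)")
  }
  if (n < 4) stop("n must be at least 4")
  zcrit <- stats::qnorm(1 - alpha / 2)
  ci_one <- function(r) {
    z <- atanh(r)
    tanh(c(z - zcrit / sqrt(n - 3), z + zcrit / sqrt(n - 3)))
  }
  c1 <- ci_one(r12)
  c2 <- ci_one(r13)
  corr_r <- ((r23 - 0.5 * r12 * r13) * (1 - r12^2 - r13^2 - r23^2) +
               r23^3) / ((1 - r12^2) * (1 - r13^2))
  lo <- r12 - r13 - sqrt((r12 - c1[1L])^2 + (c2[2L] - r13)^2 -
                           2 * corr_r * (r12 - c1[1L]) * (c2[2L] - r13))
  hi <- r12 - r13 + sqrt((c1[2L] - r12)^2 + (r13 - c2[1L])^2 -
                           2 * corr_r * (c1[2L] - r12) * (r13 - c2[1L]))
  c(lower = lo, upper = hi)
}

#' Correlate preference curves with environment saturation curves
#'
#' Computes all pairwise Spearman correlations between per-location mean
#' preference curves (over the 8 Mondrian axes) and per-location mean
#' environment saturations along the same axes. Ranking-task preferences
#' (rank 1 = most preferred) are negated before correlating so that larger
#' always means more preferred; ratings are used as-is.
#'
#' @param pref_curves matrix (locations x axes) of mean ranks or mean
#'   ratings; rownames label the preference groups.
#' @param env_curves matrix (locations x axes) of mean wedge saturations;
#'   rownames label the environments.
#' @param type `"rank"` or `"rating"`.
#' @return Matrix of Spearman correlations, preference groups in rows,
#'   environments in columns.
#' @export
preference_environment_correlation <- function(pref_curves, env_curves,
                                               type = c("rank", "rating")) {
  type <- match.arg(type)
  pref_curves <- as.matrix(pref_curves)
  env_curves <- as.matrix(env_curves)
  if (ncol(pref_curves) != ncol(env_curves)) {
    stop("preference and environment curves must cover the same axes")
  }
  signed <- if (type == "rank") -pref_curves else pref_curves
  out <- matrix(NA_real_, nrow(pref_curves), nrow(env_curves),
                dimnames = list(rownames(pref_curves), rownames(env_curves)))
  for (i in seq_len(nrow(pref_curves))) {
    for (j in seq_len(nrow(env_curves))) {
      out[i, j] <- spearman_rho(signed[i, ], env_curves[j, ])
    }
  }
  out
}
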