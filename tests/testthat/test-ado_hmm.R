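# brute-force Viterbi oracle: enumerate every state path and return the
# most probable one under the Gaussian-emission 2-state model
viterbi_oracle <- function(obs, pi0, A, mu, sigma2) {
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  best <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log(pi0[p[1]]) + dnorm(obs[1], mu[p[1]], sqrt(sigma2[p[1]]),
                                 log = TRUE)
    for (t in 2:n) {
      lp <- lp + log(A[p[t - 1], p[t]]) +
        dnorm(obs[t], mu[p[t]], sqrt(sigma2[p[t]]), log = TRUE)
    }
    if (lp > best) {
      best <- lp
      best_path <- p
    }
  }
  best_path
}

make_hmm <- function(p_stay = c(0.95, 0.9), mu = c(0.05, 0.9),
                     sigma2 = c(0.05, 0.05)) {
  structure(list(
    initial = c(0.5, 0.5),
    transition = rbind(c(p_stay[1], 1 - p_stay[1]),
                       c(1 - p_stay[2], p_stay[2])),
    means = mu, variances = sigma2, loglik = NA_real_, converged = TRUE,
    emission = "gaussian"
  ), class = "ado_hmm")
}

test_that("BAF binarization applies the 0.2 band rule, boundary excluded", {
  expect_equal(binarize_baf(c(0.5, 0.45, 0.9)), c(0L, 0L, 1L))
  expect_equal(binarize_baf(0.3), 1L)   # |0.3 - 0.5| = 0.2, not < 0.2
  expect_equal(binarize_baf(0.7), 1L)
  expect_equal(binarize_baf(c(0.31, 0.69)), c(0L, 0L))
  expect_error(binarize_baf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Baum-Welch recovers the generating chain", {
  set.seed(7)
  n <- 10000L
  p_stay <- c(0.95, 0.9)
  p_emit1 <- c(0.05, 0.9)   # P(obs = 1 | state)
  states <- integer(n)
  states[1] <- 1L
  for (t in 2:n) {
    states[t] <- if (runif(1) < p_stay[states[t - 1]]) states[t - 1] else
      3L - states[t - 1]
  }
  obs <- as.integer(runif(n) < p_emit1[states])
  fit <- fit_ado_hmm(obs, seed = 3L, n_restarts = 4L)
  expect_true(fit$means[1] < fit$means[2])      # canonical ADO labelling
  expect_lt(abs(fit$transition[1, 1] - 0.95), 0.03)
  expect_lt(abs(fit$transition[2, 2] - 0.90), 0.03)
  expect_lt(abs(fit$means[1] - 0.05), 0.03)
  expect_lt(abs(fit$means[2] - 0.90), 0.03)
  # determinism under the seed
  fit2 <- fit_ado_hmm(obs, seed = 3L, n_restarts = 4L)
  expect_identical(fit$transition, fit2$transition)
  expect_identical(fit$means, fit2$means)
})

test_that("Viterbi decoding matches exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:3) {
    hmm <- make_hmm(p_stay = c(0.9, 0.8) + runif(2, -0.05, 0.05))
    obs <- as.numeric(runif(12) < 0.4)
    pos <- sort(sample(1:5000, 12))
    oracle <- viterbi_oracle(obs, hmm$initial, hmm$transition,
                             hmm$means, hmm$variances)
    ev <- decode_ado_events(hmm, pos, obs)
    # reconstruct the decoded path from events
    path <- rep(1L, 12)
    if (nrow(ev) > 0L) {
      for (i in seq_len(nrow(ev))) {
        path[pos >= ev$start[i] & pos <= ev$end[i]] <- 2L
      }
    }
    expect_equal(path, unname(oracle))
  }
})

test_that("dropout runs become single events; isolated flickers do not", {
  hmm <- make_hmm()
  obs <- c(rep(0, 50), rep(1, 20), rep(0, 50))
  pos <- seq_along(obs) * 100L
  ev <- decode_ado_events(hmm, pos, obs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 51 * 100)
  expect_equal(ev$end, 70 * 100)
  expect_equal(ev$n_snps, 20L)
  expect_equal(ev$length, ev$end - ev$start + 1)
  # all-zero sequence: no events
  expect_equal(nrow(decode_ado_events(hmm, pos, rep(0, 120))), 0L)
  # one isolated 1 under sticky transitions with broad emissions is
  # absorbed (switching twice costs more than one off-state emission)
  hmm_broad <- make_hmm(sigma2 = c(0.16, 0.16))
  obs2 <- c(rep(0, 60), 1, rep(0, 59))
  expect_equal(nrow(decode_ado_events(hmm_broad, pos, obs2)), 0L)
  # decoded events are non-overlapping and sorted
  obs3 <- c(rep(0, 30), rep(1, 15), rep(0, 30), rep(1, 15), rep(0, 30))
  ev3 <- decode_ado_events(hmm, seq_along(obs3) * 50L, obs3)
  expect_equal(nrow(ev3), 2L)
  expect_true(all(diff(ev3$start) > 0))
  expect_true(all(ev3$start[-1] > ev3$end[-nrow(ev3)]))
})

test_that("bin-size selection follows the 95th-percentile rule", {
  lengths_kb <- (1:100) * 1000
  sel <- select_bin_size(lengths_kb)
  expect_equal(sel$p95, 95000)
  expect_equal(sel$bin_size, 95000)
  # ladder: smallest entry at or above the percentile
  sel2 <- select_bin_size(lengths_kb, ladder = c(5e4, 1e5, 5e5))
  expect_equal(sel2$bin_size, 1e5)
  # constant lengths
  expect_equal(select_bin_size(rep(12345, 50))$bin_size, 13000)
  # too few events falls back to the default with a warning
  expect_warning(sel3 <- select_bin_size(c(1e3, 2e3)), "default")
  expect_equal(sel3$bin_size, 1e5)
})

test_that("PTA-like and MDA-like dropout lengths give bin sizes two orders apart", {
  set.seed(5)
  pta <- rlnorm(500, log(1e3), 0.5)
  mda <- rlnorm(500, log(1e5), 0.5)
  sel_pta <- select_bin_size(pta)
  sel_mda <- select_bin_size(mda)
  expect_gte(sel_mda$p95 / sel_pta$p95, 50)
  expect_gte(sel_mda$bin_size / sel_pta$bin_size, 50)
})
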