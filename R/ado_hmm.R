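# Two-state Gaussian HMM on binarized BAF for allelic-dropout analysis.
# States: non-ADO (balanced, emission mean near 0) and ADO (homozygous-
# looking, emission mean near 1). Fitting is Baum-Welch with random
# restarts; decoding is Viterbi, so ADO events are contiguous runs.

#' Binarize per-site BAF values for dropout analysis
#'
#' A site is marked `0` (no sign of homozygosity) iff `|baf - 0.5| < 0.2`,
#' and `1` otherwise.
#'
#' @param baf_values Numeric vector of BAF values in \[0, 1\].
#' @return Integer vector of 0/1 indicators.
#' @export
binarize_baf <- function(baf_values) {
  if (any(!is.finite(baf_values)) ||
      any(baf_values < 0) || any(baf_values > 1)) {
    stop("BAF values must be finite and in [0, 1]")
  }
  # small epsilon so e.g. |0.7 - 0.5| lands on the boundary despite
  # floating-point representation
  as.integer(abs(baf_values - 0.5) >= 0.2 - 1e-9)
}

# scaled forward-backward pass; returns sufficient statistics for one
# Baum-Welch iteration plus the log-likelihood. Written with scalar
# two-state arithmetic: the time recursion cannot be vectorized and the
# scalar form keeps long gHET sequences cheap.
.ado_e_step <- function(obs, pi0, A, mu, sigma2,
                        emission = "gaussian") {
  n <- length(obs)
  dens <- .emission_dens(obs, mu, sigma2, emission)
  b1 <- dens$b1
  b2 <- dens$b2
  a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
  al1 <- numeric(n); al2 <- numeric(n); cv <- numeric(n)
  x1 <- pi0[1] * b1[1]; x2 <- pi0[2] * b2[1]
  cv[1] <- x1 + x2
  al1[1] <- x1 / cv[1]; al2[1] <- x2 / cv[1]
  for (t in 2:n) {
    x1 <- (al1[t - 1] * a11 + al2[t - 1] * a21) * b1[t]
    x2 <- (al1[t - 1] * a12 + al2[t - 1] * a22) * b2[t]
    cv[t] <- x1 + x2
    al1[t] <- x1 / cv[t]; al2[t] <- x2 / cv[t]
  }
  be1 <- numeric(n); be2 <- numeric(n)
  be1[n] <- 1; be2[n] <- 1
  xi11 <- 0; xi12 <- 0; xi21 <- 0; xi22 <- 0
  for (t in (n - 1):1) {
    bb1 <- b1[t + 1] * be1[t + 1]; bb2 <- b2[t + 1] * be2[t + 1]
    ct <- cv[t + 1]
    xi11 <- xi11 + al1[t] * a11 * bb1 / ct
    xi12 <- xi12 + al1[t] * a12 * bb2 / ct
    xi21 <- xi21 + al2[t] * a21 * bb1 / ct
    xi22 <- xi22 + al2[t] * a22 * bb2 / ct
    be1[t] <- (a11 * bb1 + a12 * bb2) / ct
    be2[t] <- (a21 * bb1 + a22 * bb2) / ct
  }
  g1 <- al1 * be1; g2 <- al2 * be2
  s <- g1 + g2
  list(gamma = cbind(g1 / s, g2 / s),
       xi = rbind(c(xi11, xi12), c(xi21, xi22)),
       loglik = sum(log(cv)))
}

# per-state emission densities at the observations
.emission_dens <- function(obs, mu, sigma2, emission) {
  if (emission == "bernoulli") {
    list(b1 = pmax(ifelse(obs > 0.5, mu[1], 1 - mu[1]), 1e-300),
         b2 = pmax(ifelse(obs > 0.5, mu[2], 1 - mu[2]), 1e-300))
  } else {
    list(b1 = pmax(dnorm(obs, mu[1], sqrt(sigma2[1])), 1e-300),
         b2 = pmax(dnorm(obs, mu[2], sqrt(sigma2[2])), 1e-300))
  }
}

.ado_fit_once <- function(obs, pi0, A, mu, sigma2, max_iter, tol,
                          var_floor, emission) {
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    e <- .ado_e_step(obs, pi0, A, mu, sigma2, emission)
    pi0 <- e$gamma[1, ]
    A <- e$xi / rowSums(e$xi)
    w <- colSums(e$gamma)
    mu <- colSums(e$gamma * obs) / w
    if (emission == "bernoulli") {
      mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
      sigma2 <- mu * (1 - mu)
    } else {
      sigma2 <- pmax(colSums(e$gamma * (outer(obs, mu, "-")^2)) / w,
                     var_floor)
    }
    if (abs(e$loglik - ll_old) < tol) {
      converged <- TRUE
      ll_old <- e$loglik
      break
    }
    ll_old <- e$loglik
  }
  list(initial = pi0, transition = A, means = mu, variances = sigma2,
       loglik = ll_old, converged = converged, emission = emission)
}

#' Fit the two-state ADO hidden Markov model
#'
#' Learns initial-state probabilities, the 2x2 transition matrix and
#' per-state emission parameters from a binarized BAF sequence by
#' Baum-Welch, using several random restarts and keeping the best
#' log-likelihood. The state with the higher emission mean is canonically
#' labelled "ADO" (state 2), so the fit is invariant to relabelling of
#' hidden states.
#'
#' Two emission families are available. `"bernoulli"` (default) treats
#' each state as a coin with its own probability of emitting 1 — the
#' natural model for binary observations, under which the transition
#' matrix of a simulated chain is recovered consistently. `"gaussian"`
#' places a Gaussian kernel per state on the 0/1 values; on binary data
#' its maximum likelihood degenerates to spike emissions at 0 and 1
#' (bounded only by `var_floor`), which makes decoding equivalent to
#' run-length encoding of the raw sequence, so it is provided for
#' completeness rather than used by default.
#'
#' @param binary_seq 0/1 observation sequence from [binarize_baf()],
#'   length >= 100.
#' @param seed Integer seed for the restart initialisations.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Maximum Baum-Welch iterations per restart.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param var_floor Lower bound on Gaussian emission variances.
#' @param emission Emission family, `"bernoulli"` or `"gaussian"`.
#' @return Object of class `ado_hmm`: list with `initial`, `transition`,
#'   `means`, `variances`, `loglik`, `converged`, `emission`. For
#'   Bernoulli emissions `means` holds each state's probability of
#'   emitting 1 and `variances` the implied Bernoulli variance.
#' @export
fit_ado_hmm <- function(binary_seq, seed = 1L, n_restarts = 10L,
                        max_iter = 100L, tol = 1e-4, var_floor = 0.05,
                        emission = c("bernoulli", "gaussian")) {
  emission <- match.arg(emission)
  obs <- as.numeric(binary_seq)
  if (length(obs) < 100L) stop("need at least 100 observations")
  if (!all(obs %in% c(0, 1))) stop("binary_seq must contain only 0/1")
  best <- NULL
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    pi0 <- c(0.5, 0.5)
    p_stay <- runif(2, 0.7, 0.99)
    A <- rbind(c(p_stay[1], 1 - p_stay[1]), c(1 - p_stay[2], p_stay[2]))
    mu <- sort(runif(2, 0.01, 0.99))
    sigma2 <- if (emission == "bernoulli") mu * (1 - mu) else
      rep(max(var(obs), 10 * var_floor), 2)
    fit <- .ado_fit_once(obs, pi0, A, mu, sigma2, max_iter, tol,
                         var_floor, emission)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warning("Baum-Welch did not converge; returning best parameters found")
  }
  # canonical labelling: state 2 = ADO (higher emission mean)
  if (best$means[1] > best$means[2]) {
    perm <- c(2L, 1L)
    best$initial <- best$initial[perm]
    best$transition <- best$transition[perm, perm]
    best$means <- best$means[perm]
    best$variances <- best$variances[perm]
  }
  names(best$means) <- names(best$variances) <- c("non_ado", "ado")
  structure(best, class = "ado_hmm")
}

.viterbi2 <- function(obs, pi0, A, mu, sigma2,
                      emission = "gaussian") {
  n <- length(obs)
  dens <- .emission_dens(obs, mu, sigma2, emission)
  lb1 <- log(dens$b1)
  lb2 <- log(dens$b2)
  la11 <- log(max(A[1, 1], 1e-300)); la12 <- log(max(A[1, 2], 1e-300))
  la21 <- log(max(A[2, 1], 1e-300)); la22 <- log(max(A[2, 2], 1e-300))
  psi1 <- integer(n); psi2 <- integer(n)
  d1 <- log(max(pi0[1], 1e-300)) + lb1[1]
  d2 <- log(max(pi0[2], 1e-300)) + lb2[1]
  for (t in 2:n) {
    c11 <- d1 + la11; c21 <- d2 + la21
    c12 <- d1 + la12; c22 <- d2 + la22
    if (c11 >= c21) { psi1[t] <- 1L; d1n <- c11 } else {
      psi1[t] <- 2L; d1n <- c21
    }
    if (c12 >= c22) { psi2[t] <- 1L; d2n <- c12 } else {
      psi2[t] <- 2L; d2n <- c22
    }
    d1 <- d1n + lb1[t]
    d2 <- d2n + lb2[t]
  }
  path <- integer(n)
  path[n] <- if (d1 >= d2) 1L else 2L
  for (t in (n - 1):1) {
    path[t] <- if (path[t + 1] == 1L) psi1[t + 1] else psi2[t + 1]
  }
  path
}

#' Decode allelic-dropout events from a fitted HMM
#'
#' Runs Viterbi decoding and turns maximal runs of the "ADO" state into
#' events. Event coordinates span the first to last gHET of the run and
#' `length = end - start + 1` (positions are 1-based).
#'
#' @param params An `ado_hmm` fit.
#' @param positions Sorted 1-based gHET positions.
#' @param binary_obs 0/1 observations aligned with `positions`.
#' @param chrom Chromosome label for the output (default "chr1").
#' @return `data.table` with `chrom`, `start`, `end`, `length`, `n_snps`;
#'   empty for empty input or all-non-ADO paths.
#' @export
decode_ado_events <- function(params, positions, binary_obs,
                              chrom = "chr1") {
  stopifnot(inherits(params, "ado_hmm"))
  empty <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), length = numeric(),
                                  n_snps = integer())
  if (length(positions) == 0L) return(empty)
  stopifnot(length(positions) == length(binary_obs),
            !is.unsorted(positions))
  path <- .viterbi2(as.numeric(binary_obs), params$initial,
                    params$transition, params$means, params$variances,
                    emission = if (is.null(params$emission)) "gaussian"
                    else params$emission)
  in_ado <- path == 2L
  if (!any(in_ado)) return(empty)
  r <- rle(in_ado)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- which(r$values)
  data.table::data.table(
    chrom = chrom,
    start = positions[starts_idx[keep]],
    end = positions[ends_idx[keep]],
    length = positions[ends_idx[keep]] - positions[starts_idx[keep]] + 1,
    n_snps = r$lengths[keep]
  )
}

#' Empirical 95th-percentile dropout length
#'
#' Uses the explicit convention: the value at index `ceiling(0.95 * n)` of
#' the sorted sample, so exactly the top 5% of lengths exceed it (up to
#' ties).
#'
#' @param event_lengths Numeric vector of dropout lengths in bp.
#' @return The empirical 95th percentile.
#' @export
ado_length_p95 <- function(event_lengths) {
  stopifnot(length(event_lengths) >= 1L)
  sort(event_lengths)[ceiling(0.95 * length(event_lengths))]
}

#' Select the minimum permissible bin size from dropout lengths
#'
#' The smallest permissible bin size is the 95th percentile of the
#' dropout-size distribution; with a ladder of allowed bin sizes the
#' smallest ladder entry at or above that percentile is returned, and
#' with an empty ladder the raw percentile rounded up to the next 1 kb.
#'
#' @param event_lengths Dropout event lengths in bp (>= 20 recommended).
#' @param ladder Allowed bin sizes in bp; may be empty.
#' @param default Fallback bin size when fewer than 20 events are
#'   available (default 100 kb).
#' @return List with `bin_size`, `p95` (raw percentile cutoff) and
#'   `n_events`.
#' @export
select_bin_size <- function(event_lengths, ladder = numeric(0),
                            default = 1e5) {
  n <- length(event_lengths)
  if (n < 20L) {
    warning("fewer than 20 dropout events; using default bin size")
    return(list(bin_size = default, p95 = NA_real_, n_events = n))
  }
  p95 <- ado_length_p95(event_lengths)
  if (length(ladder) == 0L) {
    bs <- ceiling(p95 / 1e3) * 1e3
  } else {
    ladder <- sort(ladder)
    ok <- ladder[ladder >= p95]
    if (length(ok) == 0L) {
      warning("95th percentile exceeds every ladder entry; using largest")
      bs <- max(ladder)
    } else {
      bs <- ok[1]
    }
  }
  list(bin_size = bs, p95 = p95, n_events = n)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
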