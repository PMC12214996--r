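# Joint segmentation of read-depth profiles across cells by greedy
# adjacent-bin merging under the simplified multi-sample BIC.
#
# For one cell with segments j = 0..m carrying observed reads a_j and
# expected reads b_j:
#   BIC(lambda) = -2 * sum_j [ a_j log(a_j/(a_j+b_j))
#                             + b_j log(b_j/(a_j+b_j)) ]
#                 + (m+1) * lambda * log(N),   N = sum_j a_j
# and the multi-sample form over G cells sharing breakpoints:
#   BIC(lambda) = -2 * sum_k sum_j [ a_kj log(a_kj/(a_kj+b_kj))
#                                   + b_kj log(b_kj/(a_kj+b_kj)) ]
#                 + (m+1) * G * lambda * log(sum_k N_k)
# with the convention 0 * log 0 = 0.

# per-segment log-likelihood contribution, vectorized, 0*log0 == 0
.bic_llik <- function(a, b) {
  tot <- a + b
  ta <- ifelse(a > 0, a * log(a / tot), 0)
  tb <- ifelse(b > 0, b * log(b / tot), 0)
  ta + tb
}

#' Single-cell simplified BIC of a segmentation
#'
#' @param a Observed read counts per segment.
#' @param b Expected read counts per segment (positive).
#' @param lambda Positive tuning parameter.
#' @param N Total reads of the cell; defaults to `sum(a)`.
#' @return The BIC value.
#' @export
bic_single <- function(a, b, lambda = 1, N = sum(a)) {
  stopifnot(length(a) == length(b), lambda > 0, all(b > 0), all(a >= 0))
  if (N <= 0) stop("total read count N must be positive")
  -2 * sum(.bic_llik(a, b)) + length(a) * lambda * log(N)
}

#' Multi-sample simplified BIC of a shared segmentation
#'
#' @param A Observed counts, a `G x (m+1)` matrix (cells x segments).
#' @param B Expected counts, same shape, positive.
#' @param lambda Positive tuning parameter.
#' @return The BIC value.
#' @export
bic_joint <- function(A, B, lambda = 1) {
  A <- rbind(A); B <- rbind(B)
  if (!all(dim(A) == dim(B))) stop("cells have mismatched bin grids")
  stopifnot(lambda > 0, all(B > 0), all(A >= 0))
  N_k <- rowSums(A)
  if (any(N_k <= 0)) stop("every cell must have positive total reads")
  G <- nrow(A)
  -2 * sum(.bic_llik(A, B)) + ncol(A) * G * lambda * log(sum(N_k))
}

# Delta-BIC of merging adjacent segments with joint sufficient statistics
# sa_l, sb_l (G-vectors) and sa_r, sb_r; penalty_drop = G*lambda*log(sum N)
.merge_delta <- function(sa_l, sb_l, sa_r, sb_r, penalty_drop) {
  lik_merged <- sum(.bic_llik(sa_l + sa_r, sb_l + sb_r))
  lik_split <- sum(.bic_llik(sa_l, sb_l)) + sum(.bic_llik(sa_r, sb_r))
  -2 * (lik_merged - lik_split) - penalty_drop
}

#' Jointly segment binned profiles across cells
#'
#' Greedy agglomerative merging starting from singleton bins: at each
#' step the adjacent pair whose merge lowers the multi-sample BIC the
#' most is merged (leftmost pair on ties); merging stops when no merge
#' lowers the BIC. Chromosomes are segmented independently when `chrom`
#' is supplied.
#'
#' @param observed `G x n` matrix of observed per-bin counts (cells in
#'   rows; bins share one grid across cells).
#' @param expected `G x n` matrix of expected per-bin counts (positive).
#' @param lambda Positive tuning parameter (default 1).
#' @param chrom Optional length-`n` chromosome label per bin.
#' @return List of class `joint_segmentation`: `segments` (`data.table`
#'   with `chrom`, `start_bin`, `end_bin` — inclusive global bin
#'   indices — and `n_bins`), `obs`/`exp` (`G x S` per-segment sums),
#'   `bic` (final value), `bic_trace` (BIC after each merge, starting at
#'   the all-singleton value), `lambda`.
#' @export
joint_segment <- function(observed, expected, lambda = 1, chrom = NULL) {
  observed <- rbind(observed); expected <- rbind(expected)
  if (ncol(observed) == 0L) stop("empty profile")
  if (!all(dim(observed) == dim(expected))) {
    stop("cells have mismatched bin grids")
  }
  stopifnot(lambda > 0, all(expected > 0), all(observed >= 0))
  n <- ncol(observed)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  stopifnot(length(chrom) == n)
  G <- nrow(observed)
  penalty_unit <- G * lambda * log(sum(observed))

  seg_list <- list()
  trace <- numeric(0)
  total_bic <- bic_joint(observed, expected, lambda)
  trace <- total_bic
  offset <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    SA <- observed[, idx, drop = FALSE]
    SB <- expected[, idx, drop = FALSE]
    m <- length(idx)
    # linked-list of active segments over local bins
    nxt <- c(seq_len(m)[-1], NA_integer_)
    prv <- c(NA_integer_, seq_len(m)[-m])
    first <- seq_len(m)            # first bin of segment i
    last <- seq_len(m)             # last bin of segment i
    # delta[i] = cost of merging segment i with its right neighbour
    delta <- rep(Inf, m)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        delta[i] <- .merge_delta(SA[, i], SB[, i], SA[, i + 1L],
                                 SB[, i + 1L], penalty_unit)
      }
    }
    while (TRUE) {
      i <- which.min(delta)
      if (!is.finite(delta[i]) || delta[i] >= 0) break
      j <- nxt[i]
      total_bic <- total_bic + delta[i]
      trace <- c(trace, total_bic)
      SA[, i] <- SA[, i] + SA[, j]
      SB[, i] <- SB[, i] + SB[, j]
      last[i] <- last[j]
      nxt[i] <- nxt[j]
      if (!is.na(nxt[j])) prv[nxt[j]] <- i
      delta[j] <- Inf
      delta[i] <- if (is.na(nxt[i])) Inf else {
        .merge_delta(SA[, i], SB[, i], SA[, nxt[i]], SB[, nxt[i]],
                     penalty_unit)
      }
      if (!is.na(prv[i])) {
        delta[prv[i]] <- .merge_delta(SA[, prv[i]], SB[, prv[i]],
                                      SA[, i], SB[, i], penalty_unit)
      }
    }
    # reconstruct active segments by walking the linked list from bin 1
    ord <- integer(0)
    cur <- 1L
    while (!is.na(cur)) {
      ord <- c(ord, cur)
      cur <- nxt[cur]
    }
    seg_list[[ch]] <- list(
      dt = data.table::data.table(chrom = ch,
                                  start_bin = offset + first[ord],
                                  end_bin = offset + last[ord]),
      SA = SA[, ord, drop = FALSE],
      SB = SB[, ord, drop = FALSE]
    )
    offset <- offset + m
  }
  segments <- data.table::rbindlist(lapply(seg_list, `[[`, "dt"))
  obs_sum <- do.call(cbind, lapply(seg_list, `[[`, "SA"))
  exp_sum <- do.call(cbind, lapply(seg_list, `[[`, "SB"))
  segments[, n_bins := end_bin - start_bin + 1L]
  structure(
    list(segments = segments[], obs = obs_sum, exp = exp_sum,
         bic = total_bic, bic_trace = trace, lambda = lambda),
    class = "joint_segmentation"
  )
}

#' Exhaustive minimum-BIC segmentation (small instances)
#'
#' Enumerates every breakpoint subset and returns the minimum of the
#' multi-sample BIC; intended as an independent check of the greedy
#' search on instances of at most ~14 bins.
#'
#' @param observed,expected `G x n` matrices as in [joint_segment()].
#' @param lambda Positive tuning parameter.
#' @return List with `bic` (the optimum) and `breakpoints` (0-based
#'   indices after which a breakpoint is placed).
#' @export
exhaustive_segment <- function(observed, expected, lambda = 1) {
  observed <- rbind(observed); expected <- rbind(expected)
  n <- ncol(observed)
  if (n > 16L) stop("exhaustive search limited to 16 bins")
  best <- Inf
  best_bp <- integer(0)
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)  # break after bin bp
    bounds <- c(0L, bp, n)
    A <- vapply(seq_len(length(bounds) - 1L), function(s) {
      rowSums(observed[, (bounds[s] + 1L):bounds[s + 1L], drop = FALSE])
    }, numeric(nrow(observed)))
    B <- vapply(seq_len(length(bounds) - 1L), function(s) {
      rowSums(expected[, (bounds[s] + 1L):bounds[s + 1L], drop = FALSE])
    }, numeric(nrow(observed)))
    val <- bic_joint(matrix(A, nrow = nrow(observed)),
                     matrix(B, nrow = nrow(observed)), lambda)
    if (val < best) {
      best <- val
      best_bp <- bp
    }
  }
  list(bic = best, breakpoints = best_bp)
}
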