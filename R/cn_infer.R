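# Ploidy scale factor and integer allele-specific copy number inference.
#
# The cell-specific scale factor gamma maps RDR to total copy number
# (CN = gamma * RDR). Candidate gammas come from bins assumed allelically
# balanced (0.45 < pBAF < 0.55): with theta whole-genome duplications
# those bins carry total copy 2*theta, so
#   Gamma = { 2*theta / mean(RDR over balanced bins) : theta in Theta }.
# The per-segment allelic state (a, b), a >= b >= 0, is then chosen by a
# Gaussian likelihood of (RDR, folded BAF) around (total/gamma, b/total),
# and gamma by a BIC over the whole cell.

#' Identify allelically balanced bins by pBAF
#'
#' Balanced bins satisfy `lower < pbaf < upper` (exclusive; defaults
#' 0.45/0.55). If fewer than `min_n` qualify the band is widened once to
#' (0.4, 0.6) with a warning.
#'
#' @param pbaf Per-bin phased BAF values (`NA` allowed).
#' @param lower,upper Exclusive band bounds.
#' @param min_n Minimum acceptable number of balanced bins.
#' @return Integer indices of balanced bins.
#' @export
find_balanced_bins <- function(pbaf, lower = 0.45, upper = 0.55,
                               min_n = 30L) {
  idx <- which(is.finite(pbaf) & pbaf > lower & pbaf < upper)
  if (length(idx) < min_n) {
    warning("fewer than ", min_n,
            " balanced bins; widening band to (0.4, 0.6)")
    idx <- which(is.finite(pbaf) & pbaf > 0.4 & pbaf < 0.6)
  }
  idx
}

#' Largest RDR cluster among balanced bins
#'
#' Fits Gaussian mixtures with 1..t components to the RDR values of the
#' balanced bins, selects the number of components by BIC, and returns
#' the members of the most populated component. Guards against singular
#' fits with a variance-floored refit.
#'
#' @param rdr_values RDR values of the balanced bins (length >= 30).
#' @param t Maximum number of mixture components (maximum allowed WGDs).
#' @return Integer indices (into `rdr_values`) of the largest cluster.
#' @export
largest_balanced_cluster <- function(rdr_values, t = 2L) {
  ok <- which(is.finite(rdr_values))
  if (length(ok) < 30L) stop("need at least 30 balanced bins")
  x <- rdr_values[ok]
  fit <- tryCatch(
    Mclust(x, G = seq_len(t), modelNames = c("E", "V"),
                   verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- Mclust(x, G = seq_len(t), modelNames = "E",
                          prior = priorControl(), verbose = FALSE)
  }
  cl <- fit$classification
  biggest <- as.integer(names(which.max(table(cl))))
  ok[cl == biggest]
}

#' Candidate scale factors from balanced bins
#'
#' `Gamma = { 2 * theta / mean(rdr) : theta in theta_grid }`.
#'
#' @param rdr_balanced RDR values of the chosen balanced bins.
#' @param theta_grid Candidate WGD states, e.g. `1:2`.
#' @return Named numeric vector of gammas (names = theta).
#' @export
candidate_gammas <- function(rdr_balanced, theta_grid = 1:2) {
  m <- mean(rdr_balanced, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("mean balanced RDR must be positive")
  stats::setNames(2 * theta_grid / m, theta_grid)
}

#' Expected RDR and folded BAF of an allelic copy-number state
#'
#' For state `(a, b)` with `a >= b >= 0` under scale factor `gamma`:
#' expected RDR is `(a + b) / gamma` and expected folded BAF is
#' `b / (a + b)` (minor-allele convention; `NA` for total 0).
#'
#' @param cn_a,cn_b Allele-specific copy numbers, `cn_a >= cn_b`.
#' @param gamma Cell scale factor.
#' @return `data.table` with `cn_a`, `cn_b`, `total`, `exp_rdr`,
#'   `exp_baf`.
#' @export
state_expectations <- function(cn_a, cn_b, gamma) {
  stopifnot(all(cn_a >= cn_b), all(cn_b >= 0))
  total <- cn_a + cn_b
  data.table::data.table(
    cn_a = cn_a, cn_b = cn_b, total = total,
    exp_rdr = total / gamma,
    exp_baf = ifelse(total > 0, cn_b / total, NA_real_)
  )
}

# enumerate states (a, b): 0 <= b <= a, a + b <= max_total
.cn_states <- function(max_total) {
  grid <- expand.grid(cn_b = 0:max_total, cn_a = 0:max_total)
  grid <- grid[grid$cn_a >= grid$cn_b & grid$cn_a + grid$cn_b <= max_total, ]
  data.table::as.data.table(grid[, c("cn_a", "cn_b")])
}

#' Infer the scale factor and per-segment allelic copy numbers of a cell
#'
#' For each candidate gamma, each segment is assigned the state `(a, b)`
#' maximizing the Gaussian log-likelihood of its observed `(rdr, baf)`
#' around the state expectations (LOH segments are restricted to
#' `b = 0`; segments with missing BAF use the RDR term only). Gamma is
#' then selected by a BIC, `-2 * sum(loglik) + theta * log(n_segments)`,
#' with ties broken toward the smaller theta (parsimony).
#'
#' @param segments `data.table` with one row per segment: `rdr`, `baf`
#'   (folded, minor-allele convention, `NA` allowed), `loh` (logical),
#'   `n_bins`, and optionally `baf_depth` (total allele depth, used for
#'   the binomial BAF standard error).
#' @param gammas Named candidate gammas from [candidate_gammas()].
#' @param max_total Maximum total copy number (default 8).
#' @param sd_rdr_bin Per-bin RDR standard deviation (estimated from
#'   balanced bins); the per-segment sd is `sd_rdr_bin / sqrt(n_bins)`
#'   inflated by `ess_factor`, floored at `sd_rdr_floor`.
#' @param sd_baf_bin Per-bin folded-BAF standard deviation (allelic
#'   amplification imbalance plus sampling, estimated per cell from
#'   balanced bins); the per-segment BAF sd is the larger of
#'   `sd_baf_bin / sqrt(n_bins)` and the binomial standard error
#'   `sqrt(0.25 / baf_depth)`, floored at `sd_baf_floor`.
#' @param ess_factor Effective-sample-size inflation for autocorrelated
#'   amplification noise, applied to both the RDR and BAF standard
#'   errors (default 1).
#' @param state_prior Parsimony log-prior strength: each state's
#'   log-likelihood is penalised by
#'   `state_prior * (|a - theta| + |b - theta|)`, favouring the balanced
#'   baseline unless the data carry real evidence (default 2).
#' @param sd_rdr_floor,sd_baf_floor Standard-deviation floors.
#' @param theta_sel_min_bins Minimum segment size (bins) for a segment
#'   to contribute to the gamma/theta model selection. Small segments
#'   are dominated by focal amplification artifacts (partial dropout)
#'   whose extreme BAF would otherwise reward spuriously rich state
#'   spaces; genuine whole-genome duplication leaves its signature in
#'   large segments (default 10).
#' @param wgd_margin BIC margin by which a larger theta must beat the
#'   current one to be selected (default 200): an extra WGD is accepted
#'   only on decisive evidence — genuinely duplicated genomes carry
#'   megabases of segments at half-integer relative depth, worth
#'   thousands of BIC units, while focal artifacts reach tens.
#' @return List: `gamma`, `theta`, `bic` (per candidate), `calls`
#'   (`data.table` of per-segment states under the chosen gamma with
#'   `cn_a`, `cn_b`, `total_cn`, `exp_rdr`, `exp_baf`, `loglik`).
#' @export
infer_cell_cn <- function(segments, gammas, max_total = 8L,
                          sd_rdr_bin = 0.1, sd_baf_bin = 0.03,
                          ess_factor = 1, state_prior = 2,
                          sd_rdr_floor = 0.02, sd_baf_floor = 0.01,
                          theta_sel_min_bins = 10L, wgd_margin = 200) {
  seg <- data.table::as.data.table(segments)
  stopifnot(all(c("rdr", "baf", "loh", "n_bins") %in% names(seg)))
  if (!"baf_depth" %in% names(seg)) seg[, baf_depth := NA_real_]
  S <- nrow(seg)
  if (S == 0L) stop("no segments")
  states <- .cn_states(max_total)
  sigma_rdr <- pmax(sd_rdr_bin * sqrt(ess_factor / seg$n_bins),
                    sd_rdr_floor)
  sigma_baf <- pmax(sd_baf_bin * sqrt(ess_factor / seg$n_bins),
                    sqrt(0.25 / pmax(seg$baf_depth, 1)), sd_baf_floor)
  sigma_baf[!is.finite(sigma_baf)] <- 0.05

  results <- vector("list", length(gammas))
  bics <- numeric(length(gammas))
  for (gi in seq_along(gammas)) {
    gamma <- gammas[gi]
    exp_rdr <- (states$cn_a + states$cn_b) / gamma
    exp_baf <- ifelse(states$cn_a + states$cn_b > 0,
                      states$cn_b / (states$cn_a + states$cn_b), NA_real_)
    # S x n_states log-likelihood
    ll_rdr <- outer(seq_len(S), seq_len(nrow(states)), function(i, j) {
      dnorm(seg$rdr[i], exp_rdr[j], sigma_rdr[i], log = TRUE)
    })
    ll_baf <- outer(seq_len(S), seq_len(nrow(states)), function(i, j) {
      ifelse(is.finite(seg$baf[i]) & is.finite(exp_baf[j]),
             dnorm(seg$baf[i], exp_baf[j], sigma_baf[i], log = TRUE),
             ifelse(is.finite(seg$baf[i]) & !is.finite(exp_baf[j]),
                    -1e3, 0))
    })
    theta_gi <- as.numeric(names(gammas)[gi])
    prior_pen <- state_prior * (abs(states$cn_a - theta_gi) +
                                  abs(states$cn_b - theta_gi))
    ll <- ll_rdr + ll_baf -
      matrix(prior_pen, nrow = S, ncol = nrow(states), byrow = TRUE)
    # LOH segments: restrict to b = 0 states
    loh_rows <- which(seg$loh %in% TRUE)
    if (length(loh_rows) > 0L) {
      ll[loh_rows, states$cn_b > 0] <- -Inf
    }
    best_state <- max.col(ll, ties.method = "first")
    best_ll <- ll[cbind(seq_len(S), best_state)]
    if (all(!is.finite(best_ll))) {
      results[[gi]] <- NULL
      bics[gi] <- Inf
      next
    }
    sel <- which(seg$n_bins >= theta_sel_min_bins & is.finite(best_ll))
    if (length(sel) == 0L) sel <- which(is.finite(best_ll))
    bics[gi] <- -2 * sum(best_ll[sel]) + theta_gi * log(length(sel))
    calls <- data.table::data.table(
      seg,
      cn_a = states$cn_a[best_state],
      cn_b = states$cn_b[best_state],
      total_cn = states$cn_a[best_state] + states$cn_b[best_state],
      exp_rdr = exp_rdr[best_state],
      exp_baf = exp_baf[best_state],
      loglik = best_ll
    )
    results[[gi]] <- calls
  }
  if (all(!is.finite(bics))) stop("cell is uncallable: degenerate likelihood")
  # ascend theta only on decisive evidence (wgd_margin), ties -> smaller
  ord <- order(as.numeric(names(gammas)))
  pick <- ord[1]
  for (gi in ord[-1]) {
    if (is.finite(bics[gi]) && bics[gi] < bics[pick] - wgd_margin) {
      pick <- gi
    }
  }
  list(
    gamma = unname(gammas[pick]),
    theta = as.numeric(names(gammas)[pick]),
    bic = stats::setNames(bics, names(gammas)),
    calls = results[[pick]]
  )
}
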