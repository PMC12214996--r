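# Per-segment BAF refinement: LOH detection via a haplotype-specific
# GC shift plus a Kolmogorov-Smirnov test, followed by kernel-density
# peak calling with removal of dropout peaks near 0/1.
#
# Rationale for the shift: GC-driven depth fluctuations hit both
# haplotypes of a balanced segment roughly equally, so the observed pBAF
# sits tightly at 0.5 regardless of GC. Re-weighting only the B-haplotype
# count by the bin's GC-expected relative depth therefore perturbs pBAF
# in balanced segments (by an amount that tracks GC), while in LOH
# segments (B count near zero) the same operation changes almost
# nothing. Comparing |pBAF - 0.5| before and after the shift with a
# two-sample KS test separates the two situations: indistinguishable
# distributions point to LOH.

#' Haplotype-specific GC shift of phased BAF
#'
#' Divides the haplotype-B count of each bin by its GC-expected relative
#' depth and recomputes the phased BAF. With unit GC factors the shift is
#' the identity; with `count_b = 0` (LOH) it has no effect.
#'
#' @param count_a,count_b Haplotype-aggregated allele counts per bin.
#' @param gc_factor Per-bin relative expected depth from the cell's GC
#'   model (see [predict.gc_model()]); defaults to 1 (no shift).
#' @return Shifted pBAF values (`NA` where total count is zero).
#' @export
shift_baf <- function(count_a, count_b, gc_factor = rep(1, length(count_a))) {
  stopifnot(length(count_a) == length(count_b),
            length(gc_factor) == length(count_a))
  if (any(gc_factor <= 0, na.rm = TRUE)) stop("gc_factor must be positive")
  b_shift <- count_b / gc_factor
  tot <- count_a + b_shift
  ifelse(tot > 0, b_shift / tot, NA_real_)
}

#' Test a segment for loss of heterozygosity
#'
#' Applies [shift_baf()] and compares the distributions of
#' `|pbaf - 0.5|` before and after the shift with a two-sample
#' Kolmogorov-Smirnov test. LOH is called iff the distributions are
#' indistinguishable (`p >= alpha`) AND the segment is predominantly
#' homozygous (`median |pbaf - 0.5| > hom_threshold`); the second
#' condition prevents flat balanced segments (where the GC signal is too
#' weak for the KS test) from being labelled LOH. Segments with fewer
#' than `min_bins` informative bins are marked low-confidence and assumed
#' non-LOH.
#'
#' @param seg_bins `data.table` with `count_a`, `count_b`, `pbaf` and
#'   optionally `gc_factor` for the bins of one segment in one cell.
#' @param alpha Significance level (default 0.05).
#' @param min_bins Minimum informative bins for the test (default 10).
#' @param hom_threshold Homozygosity guard on `median |pbaf - 0.5|`.
#' @return List with `loh`, `ks_stat`, `ks_p`, `low_confidence`.
#' @export
detect_loh <- function(seg_bins, alpha = 0.05, min_bins = 10L,
                       hom_threshold = 0.4) {
  sb <- data.table::as.data.table(seg_bins)
  if (!"gc_factor" %in% names(sb)) sb[, gc_factor := 1]
  inf <- sb[is.finite(pbaf) & count_a + count_b > 0]
  if (nrow(inf) < min_bins) {
    return(list(loh = FALSE, ks_stat = NA_real_, ks_p = NA_real_,
                low_confidence = TRUE))
  }
  orig <- abs(inf$pbaf - 0.5)
  shifted <- abs(shift_baf(inf$count_a, inf$count_b, inf$gc_factor) - 0.5)
  ks <- suppressWarnings(ks.test(orig, shifted))
  loh <- ks$p.value >= alpha && median(orig) > hom_threshold
  list(loh = loh, ks_stat = unname(ks$statistic),
       ks_p = ks$p.value, low_confidence = FALSE)
}

# kernel density peaks of the (unfolded) per-bin BAF distribution on
# [0, 1]; data reflected at both boundaries to avoid edge bias,
# Silverman bandwidth, local maxima by sign change of the derivative.
# Peak calling is done unfolded: folding to [0, 0.5] before peak
# detection biases the mode of balanced segments below 0.5 (the fold is
# a max-type statistic), whereas the unfolded mode is unbiased; the
# minor-allele fold is applied to the final location only.
.baf_peaks <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(data.table::data.table(
    location = numeric(), density = numeric()))
  if (length(x) < 3L || sd(x) < 1e-8) {
    return(data.table::data.table(location = median(x), density = 1))
  }
  # bandwidth from the original sample: the reflected copies only
  # correct boundary bias and must not widen the kernel
  bw <- stats::bw.nrd0(x)
  refl <- c(x, -x, 2 - x)
  d <- density(refl, bw = bw, n = 1024, from = -0.05, to = 1.05)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  # floating-point ripples in regions of ~zero density are not peaks
  keep <- is_max & d$x >= 0 & d$x <= 1 & y > 1e-3 * max(y)
  if (!any(keep)) {
    in_band <- d$x >= 0 & d$x <= 1
    peak_at <- which(in_band)[which.max(y[in_band])]
    keep[peak_at] <- TRUE
  }
  data.table::data.table(location = pmin(pmax(d$x[keep], 0), 1),
                         density = y[keep])[order(-density)]
}

#' Refine the BAF of a segment by peak calling
#'
#' Peak-calls the per-bin pBAF distribution of the segment by Gaussian
#' kernel density on \[0, 1\]. For non-LOH segments, peaks within
#' `edge_band` of 0 or 1 are interpreted as dropout artifacts and
#' removed; the highest-density surviving peak, folded to the
#' minor-allele convention (`min(p, 1 - p)`, range \[0, 0.5\]), is the
#' segment BAF (median folded pBAF if no peak survives). For LOH
#' segments the BAF is 0.
#'
#' @param seg_bins `data.table` with per-bin `pbaf` (plus `count_a`,
#'   `count_b` for [detect_loh()] when used through [segment_baf()]).
#' @param loh Logical LOH flag from [detect_loh()].
#' @param edge_band Dropout-peak exclusion band (default 0.1).
#' @return List with `baf` (folded) and `peaks` (`data.table` of
#'   unfolded location, density).
#' @export
call_baf_peaks <- function(seg_bins, loh, edge_band = 0.1) {
  sb <- data.table::as.data.table(seg_bins)
  if (nrow(sb) == 0L) stop("empty segment")
  pb <- sb$pbaf[is.finite(sb$pbaf)]
  if (isTRUE(loh)) {
    return(list(baf = 0, peaks = .baf_peaks(pb)))
  }
  if (length(pb) == 0L) {
    return(list(baf = NA_real_, peaks = data.table::data.table(
      location = numeric(), density = numeric())))
  }
  peaks <- .baf_peaks(pb)
  surviving <- peaks[location >= edge_band & location <= 1 - edge_band]
  baf <- if (nrow(surviving) > 0L) {
    loc <- surviving$location[which.max(surviving$density)]
    min(loc, 1 - loc)
  } else {
    median(pmin(pb, 1 - pb))
  }
  list(baf = baf, peaks = peaks)
}

#' Split segments at decisive BAF changepoints
#'
#' Copy-neutral LOH leaves no read-depth signature, so depth-based
#' segment boundaries can miss its edges. This per-cell refinement
#' recursively splits a segment at the cut maximizing the two-mean
#' deviance of the per-bin folded BAF, whenever that deviance (scaled by
#' `sd_baf_bin^2`) exceeds `split_penalty`. An LOH boundary shifts the
#' folded BAF by ~0.5 (tens of sigma per bin) and is always found;
#' amplification noise (~1 sigma per bin) stays below the threshold.
#'
#' @param folded Per-bin folded BAF values of one segment (`NA` bins are
#'   imputed at the segment median).
#' @param sd_baf_bin Per-bin folded-BAF standard deviation.
#' @param split_penalty Scaled-deviance threshold to accept a split
#'   (default 30).
#' @param max_depth Maximum recursion depth.
#' @return Integer vector of local segment lengths (sums to
#'   `length(folded)`).
#' @export
baf_changepoint_split <- function(folded, sd_baf_bin = 0.03,
                                  split_penalty = 30, max_depth = 8L) {
  n <- length(folded)
  if (n < 2L || max_depth <= 0L) return(n)
  x <- folded
  if (anyNA(x)) x[is.na(x)] <- median(x, na.rm = TRUE)
  if (anyNA(x)) return(n)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1L)
  rss_left <- cs2[k] - cs[k]^2 / k
  rss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  rss0 <- cs2[n] - cs[n]^2 / n
  gain <- (rss0 - (rss_left + rss_right)) / sd_baf_bin^2
  best <- which.max(gain)
  if (!is.finite(gain[best]) || gain[best] < split_penalty) return(n)
  c(baf_changepoint_split(folded[1:best], sd_baf_bin, split_penalty,
                          max_depth - 1L),
    baf_changepoint_split(folded[(best + 1L):n], sd_baf_bin,
                          split_penalty, max_depth - 1L))
}

#' Full per-segment BAF refinement (LOH test + peak calling)
#'
#' @param seg_bins Per-bin `data.table` for one segment in one cell with
#'   `count_a`, `count_b`, `pbaf` and optionally `gc_factor`.
#' @param alpha LOH test significance level.
#' @param edge_band Dropout-peak exclusion band.
#' @param min_bins Minimum informative bins for the LOH test.
#' @return One-row `data.table`: `loh`, `ks_stat`, `ks_p`,
#'   `low_confidence`, `baf`, `n_informative`, `baf_depth` (total allele
#'   depth over informative bins).
#' @export
segment_baf <- function(seg_bins, alpha = 0.05, edge_band = 0.1,
                        min_bins = 10L) {
  sb <- data.table::as.data.table(seg_bins)
  lt <- detect_loh(sb, alpha = alpha, min_bins = min_bins)
  pk <- call_baf_peaks(sb, loh = lt$loh, edge_band = edge_band)
  inf <- sb[is.finite(pbaf)]
  data.table::data.table(
    loh = lt$loh, ks_stat = lt$ks_stat, ks_p = lt$ks_p,
    low_confidence = lt$low_confidence, baf = pk$baf,
    n_informative = nrow(inf),
    baf_depth = sum(inf$count_a + inf$count_b)
  )
}
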