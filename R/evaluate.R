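# Scoring of call sets against ground truth: reciprocal-overlap
# matching, size-matched FDR lookup, and clonality classification.

.as_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = paste(dt$cell_id, dt$chrom, dt$type, sep = "::"),
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
}

#' Match CNA calls against truth intervals
#'
#' A truth interval is a true positive when some call of the same type in
#' the same cell overlaps it reciprocally by at least
#' `min_reciprocal_overlap` (intersection length >= threshold x both
#' lengths). Calls matching no truth are false positives; truths matched
#' by no call are false negatives. Precision with zero calls is 1 by
#' convention (no false positives; set `zero_call_precision = NA` for
#' "undefined"). 95% confidence intervals come from a bootstrap over
#' cells.
#'
#' @param calls `data.table` with `chrom`, `start`, `end`, `cell_id`,
#'   `type`.
#' @param truth Same columns.
#' @param min_reciprocal_overlap Reciprocal overlap threshold (default
#'   0.5).
#' @param n_boot Bootstrap replicates over cells (default 200; 0 skips).
#' @param seed Bootstrap seed.
#' @param zero_call_precision Value reported when there are no calls.
#' @return List of class `match_result`: `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`, `precision_ci`, `sensitivity_ci`.
#' @export
match_calls <- function(calls, truth, min_reciprocal_overlap = 0.5,
                        n_boot = 200L, seed = 1L,
                        zero_call_precision = 1) {
  calls <- data.table::as.data.table(calls)
  truth <- data.table::as.data.table(truth)
  score <- function(cl, tr) {
    n_call <- nrow(cl); n_truth <- nrow(tr)
    if (n_truth == 0L && n_call == 0L) {
      return(c(tp = 0, fp = 0, fn = 0))
    }
    if (n_call == 0L) return(c(tp = 0, fp = 0, fn = n_truth))
    if (n_truth == 0L) return(c(tp = 0, fp = n_call, fn = 0))
    gc_ <- .as_granges(cl)
    gt_ <- .as_granges(tr)
    # disjoint seqlevels (cell/type combinations present on one side
    # only) are expected, not a data problem
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gc_, gt_))
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gc_)[S4Vectors::queryHits(hits)],
      IRanges::ranges(gt_)[S4Vectors::subjectHits(hits)]
    ))
    wc <- IRanges::width(IRanges::ranges(gc_))[S4Vectors::queryHits(hits)]
    wt <- IRanges::width(IRanges::ranges(gt_))[S4Vectors::subjectHits(hits)]
    good <- ov >= min_reciprocal_overlap * wc &
      ov >= min_reciprocal_overlap * wt
    tp_truth <- unique(S4Vectors::subjectHits(hits)[good])
    tp_call <- unique(S4Vectors::queryHits(hits)[good])
    c(tp = length(tp_truth), fp = n_call - length(tp_call),
      fn = n_truth - length(tp_truth))
  }
  counts <- score(calls, truth)
  prec <- if (counts["tp"] + counts["fp"] == 0) {
    zero_call_precision
  } else {
    counts["tp"] / (counts["tp"] + counts["fp"])
  }
  sens <- if (counts["tp"] + counts["fn"] == 0) {
    NA_real_
  } else {
    counts["tp"] / (counts["tp"] + counts["fn"])
  }
  ci <- list(precision = c(NA_real_, NA_real_),
             sensitivity = c(NA_real_, NA_real_))
  cell_ids <- unique(c(calls$cell_id, truth$cell_id))
  if (n_boot > 0L && length(cell_ids) > 1L) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(seed)
    bp <- bs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      pick <- sample(cell_ids, replace = TRUE)
      cl <- data.table::rbindlist(lapply(seq_along(pick), function(i) {
        x <- calls[cell_id == pick[i]]
        if (nrow(x) > 0L) x[, cell_id := paste0("b", i)]
        x
      }))
      tr <- data.table::rbindlist(lapply(seq_along(pick), function(i) {
        x <- truth[cell_id == pick[i]]
        if (nrow(x) > 0L) x[, cell_id := paste0("b", i)]
        x
      }))
      k <- score(cl, tr)
      bp[b] <- if (k["tp"] + k["fp"] == 0) zero_call_precision else
        k["tp"] / (k["tp"] + k["fp"])
      bs[b] <- if (k["tp"] + k["fn"] == 0) NA_real_ else
        k["tp"] / (k["tp"] + k["fn"])
    }
    ci$precision <- unname(quantile(bp, c(0.025, 0.975), na.rm = TRUE))
    ci$sensitivity <- unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(
    tp = unname(counts["tp"]), fp = unname(counts["fp"]),
    fn = unname(counts["fn"]),
    precision = unname(prec), sensitivity = unname(sens),
    precision_ci = ci$precision, sensitivity_ci = ci$sensitivity
  ), class = "match_result")
}

#' Estimate the FDR of a call set by size matching
#'
#' Each call is matched to the FDR-table row of its event type with the
#' largest size strictly smaller than the call's length; calls smaller
#' than every tabulated size take the smallest row (a conservative
#' choice, since FDR increases as CNA size decreases). The estimate is
#' the mean over calls.
#'
#' @param calls `data.table` with `start`, `end`, `type`.
#' @param fdr_table `data.table` with `type`, `size`, `fdr`.
#' @return The mean FDR (NA with a message for an empty call set).
#' @export
estimate_fdr <- function(calls, fdr_table) {
  calls <- data.table::as.data.table(calls)
  tab <- data.table::as.data.table(fdr_table)
  stopifnot(all(c("type", "size", "fdr") %in% names(tab)))
  if (nrow(calls) == 0L) {
    message("empty call set: FDR undefined")
    return(NA_real_)
  }
  per_call <- vapply(seq_len(nrow(calls)), function(i) {
    len <- calls$end[i] - calls$start[i]
    rows <- tab[type == calls$type[i]][order(size)]
    if (nrow(rows) == 0L) stop("FDR table has no rows for type ",
                               calls$type[i])
    smaller <- rows[size < len]
    if (nrow(smaller) > 0L) smaller$fdr[nrow(smaller)] else rows$fdr[1]
  }, numeric(1))
  mean(per_call)
}

#' Classify calls as clonal or private
#'
#' A call is clonal when at least two cells carry a call with identical
#' `(chrom, start, end, type)` on the shared bin grid; identical calls
#' form one clone group. Calls must be bin-aligned: starts and ends are
#' checked against `bin_size`.
#'
#' @param calls `data.table` with `chrom`, `start`, `end`, `cell_id`,
#'   `type`.
#' @param bin_size Bin size of the shared grid in bp.
#' @return Copy of `calls` with logical `clonal` and integer
#'   `clone_group` (NA for private calls) columns.
#' @export
classify_clonality <- function(calls, bin_size) {
  out <- data.table::copy(data.table::as.data.table(calls))
  if (nrow(out) == 0L) {
    out[, `:=`(clonal = logical(), clone_group = integer())]
    return(out[])
  }
  if (any(out$start %% bin_size != 0) || any(out$end %% bin_size != 0)) {
    stop("calls are not aligned to the shared bin grid")
  }
  out[, clone_key := paste(chrom, start, end, type, sep = ":")]
  counts <- out[, .(n_cells_with = data.table::uniqueN(cell_id)),
                by = clone_key]
  clonal_keys <- counts[n_cells_with >= 2L, clone_key]
  out[, clonal := clone_key %in% clonal_keys]
  key_ids <- stats::setNames(seq_along(clonal_keys), clonal_keys)
  out[, clone_group := ifelse(clonal,
                              key_ids[clone_key], NA_integer_)]
  out[, clone_key := NULL]
  out[]
}
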