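#' Load germline heterozygous SNPs and apply standard filters
#'
#' Reads a tab-separated SNP table and keeps the sites usable for
#' allele-specific analysis: heterozygous, pass-filtered, phased, and with
#' a bulk variant allele frequency strictly inside `vaf_bounds`.
#' Multi-allelic records (comma in `alt`) are dropped.
#'
#' The table must contain the columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `gt` (e.g. `"0|1"`; `"|"` marks a phased genotype), `filter`,
#' `depth_a`, `depth_b` (read counts supporting haplotype A / B) and
#' `bulk_vaf`.
#'
#' @param snp_table Path to a TSV file, or a data.frame with the columns
#'   above.
#' @param vaf_bounds Length-2 numeric, exclusive bounds on the bulk VAF.
#' @return A `data.table` of retained SNP records, sorted by
#'   `(chrom, pos)`, with attributes `n_dropped_unphased` and
#'   `n_dropped_total`.
#' @export
load_ghets <- function(snp_table, vaf_bounds = c(0.1, 0.9)) {
  stopifnot(length(vaf_bounds) == 2L, vaf_bounds[1] < vaf_bounds[2])
  snps <- if (is.character(snp_table)) {
    data.table::fread(snp_table, sep = "\t")
  } else {
    data.table::as.data.table(snp_table)
  }
  req <- c("chrom", "pos", "ref", "alt", "gt", "filter",
           "depth_a", "depth_b", "bulk_vaf")
  miss <- setdiff(req, names(snps))
  if (length(miss) > 0L) {
    stop("SNP table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(snps$pos) | snps$pos < 1 |
                 !is.finite(snps$bulk_vaf) |
                 snps$bulk_vaf < 0 | snps$bulk_vaf > 1 |
                 !is.finite(snps$depth_a) | snps$depth_a < 0 |
                 !is.finite(snps$depth_b) | snps$depth_b < 0)
  if (length(bad) > 0L) {
    stop("malformed SNP record at line ", bad[1] + 1L,
         " (1-based, counting the header)")
  }
  het <- snps$gt %in% c("0|1", "1|0", "0/1", "1/0")
  phased <- grepl("|", snps$gt, fixed = TRUE)
  n_unphased <- sum(het & !phased & snps$filter == "PASS")
  keep <- het & phased & snps$filter == "PASS" &
    !grepl(",", snps$alt, fixed = TRUE) &
    snps$bulk_vaf > vaf_bounds[1] & snps$bulk_vaf < vaf_bounds[2]
  out <- snps[keep]
  data.table::setorder(out, chrom, pos)
  if (n_unphased > 0L) {
    message(n_unphased, " unphased heterozygous record(s) dropped")
  }
  data.table::setattr(out, "n_dropped_unphased", n_unphased)
  data.table::setattr(out, "n_dropped_total", nrow(snps) - nrow(out))
  out[]
}

#' Construct fixed-span genome bins
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin size in bp; the last partial bin is dropped.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open),
#'   and `mappable_bp` (= span for fixed bins).
#' @export
make_bins <- function(chrom, chrom_length, bin_size) {
  stopifnot(bin_size > 0, chrom_length >= bin_size)
  n <- floor(chrom_length / bin_size)
  starts <- (seq_len(n) - 1L) * bin_size
  data.table::data.table(
    chrom = chrom, start = starts, end = starts + bin_size,
    mappable_bp = bin_size
  )
}

#' Construct variable-span bins with equal mappable content
#'
#' Walks a mappability track (0-based half-open intervals of uniquely
#' mappable sequence) and emits bins that each contain
#' `target_mappable_bp` mappable positions, so bins in poorly mappable
#' regions span more genomic sequence. Mirrors the "mappable bin"
#' convention used for real data; for simulated data [make_bins()] is the
#' fixed-span alternative.
#'
#' @param mappability `data.table`/data.frame with `chrom`, `start`, `end`.
#' @param target_mappable_bp Mappable positions per bin.
#' @return `data.table` with `chrom`, `start`, `end`, `mappable_bp`.
#' @export
make_mappable_bins <- function(mappability, target_mappable_bp) {
  mp <- data.table::as.data.table(mappability)
  stopifnot(all(c("chrom", "start", "end") %in% names(mp)),
            target_mappable_bp > 0)
  data.table::setorder(mp, chrom, start)
  out <- vector("list", 0L)
  for (ch in unique(mp$chrom)) {
    iv <- mp[chrom == ch]
    bin_start <- iv$start[1]
    acc <- 0
    for (i in seq_len(nrow(iv))) {
      s <- iv$start[i]; e <- iv$end[i]
      while (e - s + acc >= target_mappable_bp) {
        cut <- s + (target_mappable_bp - acc)
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = ch, start = bin_start, end = cut,
          mappable_bp = target_mappable_bp
        )
        s <- cut
        acc <- 0
        bin_start <- s
      }
      acc <- acc + (e - s)
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), mappable_bp = numeric()))
  }
  data.table::rbindlist(out)
}

#' Aggregate phased allele depths of gHETs into bins
#'
#' Sums haplotype-A and haplotype-B read depths over the gHETs falling in
#' each bin and computes the phased B-allele frequency
#' `pbaf = count_b / (count_a + count_b)`; bins with zero total allele
#' depth (or no gHETs) get `NA` pbaf. SNP positions are 1-based, bins
#' 0-based half-open, so SNP `pos` falls in bin `[start, end)` iff
#' `start < pos <= end`.
#'
#' @param snps `data.table` with `chrom`, `pos`, `depth_a`, `depth_b`.
#' @param bins `data.table` with `chrom`, `start`, `end` (non-overlapping,
#'   sorted).
#' @return `bins` with added `count_a`, `count_b`, `pbaf` columns; the
#'   number of SNPs outside every bin is attached as attribute
#'   `n_snps_outside`.
#' @export
aggregate_bin_counts <- function(snps, bins) {
  snps <- data.table::as.data.table(snps)
  out <- data.table::copy(data.table::as.data.table(bins))
  out[, `:=`(count_a = 0, count_b = 0)]
  n_outside <- 0L
  for (ch in unique(out$chrom)) {
    b <- out[chrom == ch]
    s <- snps[chrom == ch]
    if (nrow(s) == 0L) next
    # pos is 1-based: bin index via findInterval on starts, then check end
    idx <- findInterval(s$pos - 1L, b$start)
    inside <- idx >= 1L & (s$pos - 1L) < b$end[pmax(idx, 1L)]
    n_outside <- n_outside + sum(!inside)
    if (!any(inside)) next
    ca <- rowsum(s$depth_a[inside], idx[inside])
    cb <- rowsum(s$depth_b[inside], idx[inside])
    rows <- as.integer(rownames(ca))
    which_rows <- which(out$chrom == ch)[rows]
    out[which_rows, `:=`(count_a = as.numeric(ca[, 1]),
                         count_b = as.numeric(cb[, 1]))]
  }
  n_outside_all <- n_outside + sum(!snps$chrom %in% unique(out$chrom))
  out[, pbaf := ifelse(count_a + count_b > 0,
                       count_b / (count_a + count_b), NA_real_)]
  if (n_outside_all > 0L) {
    message(n_outside_all, " SNP(s) outside every bin were ignored")
  }
  data.table::setattr(out, "n_snps_outside", n_outside_all)
  out[]
}

#' Write allelic copy number calls as a BED-style TSV
#'
#' Columns: `chrom`, `start` (0-based), `end`, `cell_id`, `cn_a`, `cn_b`,
#' `total_cn`, `rdr`, `baf`, `loh_flag`. Calls must be sorted by
#' `(cell_id, chrom, start)`; the file round-trips losslessly through
#' [read_calls()].
#'
#' @param calls `data.table` of calls.
#' @param path Output file path.
#' @export
write_calls <- function(calls, path) {
  calls <- data.table::as.data.table(calls)
  cols <- c("chrom", "start", "end", "cell_id", "cn_a", "cn_b",
            "total_cn", "rdr", "baf", "loh_flag")
  miss <- setdiff(cols, names(calls))
  if (length(miss) > 0L) stop("calls missing column(s): ",
                              paste(miss, collapse = ", "))
  if (nrow(calls) > 1L) {
    o <- order(calls$cell_id, calls$chrom, calls$start)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (cell_id, chrom, start)")
    }
  }
  data.table::fwrite(calls[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read a call set written by [write_calls()]
#' @param path File path.
#' @return `data.table` of calls.
#' @export
read_calls <- function(path) {
  out <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = c("chrom", "cell_id"),
                                             logical = "loh_flag"))
  out[]
}

#' Read a 4-column bedGraph/TSV track (chrom, start, end, value)
#' @param path File path.
#' @param value_name Name for the fourth column.
#' @return `data.table`.
#' @export
read_track <- function(path, value_name = "value") {
  tr <- data.table::fread(path, sep = "\t", header = "auto")
  if (ncol(tr) < 4L) stop("track file must have >= 4 columns")
  tr <- tr[, 1:4]
  data.table::setnames(tr, c("chrom", "start", "end", value_name))
  tr[]
}
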