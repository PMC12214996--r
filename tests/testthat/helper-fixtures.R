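# shared fixture builders; everything is generated in code

# small SNP table covering the gHET filter paths
make_snp_table <- function() {
  data.table::data.table(
    chrom = "chr1",
    pos = c(100L, 250L, 400L, 550L, 700L, 850L, 1000L),
    ref = c("A", "C", "G", "T", "A", "C", "G"),
    alt = c("T", "G", "A", "C", "G", "T,A", "C"),
    gt = c("0|1", "1|0", "0/1", "1|1", "0|1", "0|1", "0|1"),
    filter = c("PASS", "PASS", "PASS", "PASS", "LowQual", "PASS", "PASS"),
    depth_a = c(10, 12, 9, 11, 10, 10, 8),
    depth_b = c(11, 9, 10, 12, 9, 11, 12),
    bulk_vaf = c(0.5, 0.45, 0.52, 0.48, 0.5, 0.5, 0.05)
  )
}

# a small, fast simulation configuration (20 Mb genome) for unit tests;
# the default full-scale configuration is exercised in the acceptance
# suite
small_sdx_config <- function(..., seed = 42L) {
  sdx_config(genome_length = 2e7, seed = seed, ...)
}

# balanced segment bins: per-bin haplotype counts around depth/2 with a
# small multiplicative allelic-bias field
make_balanced_segment <- function(n_bins = 25L, depth = 1500,
                                  bias_sd = 0.05, gc_factor = NULL) {
  fa <- exp(rnorm(n_bins, 0, bias_sd))
  fb <- exp(rnorm(n_bins, 0, bias_sd))
  count_a <- rpois(n_bins, depth / 2 * fa)
  count_b <- rpois(n_bins, depth / 2 * fb)
  data.table::data.table(
    count_a = count_a, count_b = count_b,
    pbaf = count_b / (count_a + count_b),
    gc_factor = if (is.null(gc_factor)) exp(rnorm(n_bins, 0, 0.05)) else
      gc_factor
  )
}

# LOH segment bins: haplotype B silenced
make_loh_segment <- function(n_bins = 25L, depth = 1500) {
  count_a <- rpois(n_bins, depth)
  count_b <- rpois(n_bins, depth * 0.005)
  data.table::data.table(
    count_a = count_a, count_b = count_b,
    pbaf = count_b / (count_a + count_b),
    gc_factor = exp(rnorm(n_bins, 0, 0.05))
  )
}
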