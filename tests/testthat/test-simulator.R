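test_that("the CNA size grid is geometric from 200 kb to 5 Mb", {
  grid <- make_size_grid()
  expect_length(grid, 13L)
  expect_equal(grid[1], 2e5)
  expect_equal(grid[13], 5e6)
  # geometric: constant consecutive ratio
  ratios <- grid[-1] / grid[-13]
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-9)
  # midpoint is the geometric mean = 1 Mb
  expect_equal(grid[7], sqrt(2e5 * 5e6), tolerance = 1e-9)
  expect_equal(grid[7], 1e6, tolerance = 1e-9)
  expect_error(make_size_grid(5e6, 2e5), "invalid")
})

test_that("haplotype depth tracks behave under noise-free settings", {
  cfg <- small_sdx_config(amp_cv = 0, ado_rate_per_mb = 0, gc_coef = 0,
                          poisson_noise = FALSE)
  tr <- simulate_haplotype_depth(cfg, "A", seed = 1L)
  # every bin = reads-per-bp x bin span exactly
  expect_true(all(tr$bins$observed == 15 / 150 * 1e5))
  # reproducibility
  tr2 <- simulate_haplotype_depth(cfg, "A", seed = 1L)
  expect_identical(tr$bins, tr2$bins)
})

test_that("dropout events arrive at the configured rate", {
  cfg <- small_sdx_config(ado_rate_per_mb = 5)
  counts <- vapply(1:10, function(i) {
    nrow(simulate_haplotype_depth(cfg, "A", seed = i)$ado_events)
  }, numeric(1))
  expected <- 5 * 20   # rate per Mb x genome Mb
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 10))
})

test_that("spiked CNAs change depth by the expected ratios", {
  cfg <- small_sdx_config(seed = 3L)
  plain <- simulate_cell(cfg, data.table::data.table(), "c", seed = 11L)
  base <- sum(plain$bins[start >= 8e6 & end <= 1e7, observed])
  mk <- function(type) {
    truth <- data.table::data.table(chrom = "chr1", start = 8e6,
                                    end = 10e6, cell_id = "c",
                                    type = type, haplotype = "B")
    cell <- simulate_cell(cfg, truth, "c", seed = 11L)
    sum(cell$bins[start >= 8e6 & end <= 1e7, observed]) / base
  }
  # same seed, so the ratio isolates the spike: half depth for a loss,
  # 1.5x / 2x for one- and two-copy gains, untouched for cnLOH
  expect_true(mk("loss_1_0") > 0.45 && mk("loss_1_0") < 0.55)
  r_gain <- mk("gain_2_1")
  expect_true(r_gain > 1.4 && r_gain < 1.6)
  r_gain2 <- mk("gain_3_1")
  expect_true(r_gain2 > 1.85 && r_gain2 < 2.15)
  expect_equal(mk("cnloh_2_0"), 1)
})

test_that("cnLOH conserves total depth bitwise but silences haplotype B", {
  cfg <- small_sdx_config(seed = 4L)
  truth <- data.table::data.table(chrom = "chr1", start = 5e6, end = 8e6,
                                  cell_id = "c", type = "cnloh_2_0",
                                  haplotype = "B")
  none <- data.table::data.table()
  cell_cnloh <- simulate_cell(cfg, truth, "c", seed = 9L)
  cell_plain <- simulate_cell(cfg, none, "c", seed = 9L)
  expect_identical(cell_cnloh$bins$observed, cell_plain$bins$observed)
  inside <- cell_cnloh$snps[pos > 5e6 & pos <= 8e6 & !flipped]
  expect_true(all(inside$depth_b == 0))
  # and the total allele depth per site is conserved too
  plain_inside <- cell_plain$snps[pos > 5e6 & pos <= 8e6 & !flipped]
  expect_equal(sum(inside$depth_a + inside$depth_b),
               sum(plain_inside$depth_a + plain_inside$depth_b))
})

test_that("gHET placement density, unbiasedness and flips are as configured", {
  cfg <- sdx_config(seed = 6L)   # full 150 Mb genome: 75,000 sites
  cell <- simulate_cell(cfg, data.table::data.table(), "c", seed = 2L)
  snps <- cell$snps
  # exactly 5 gHETs per 10 kb window
  win <- floor((snps$pos - 1) / 1e4)
  expect_true(all(table(win) == 5L))
  expect_equal(nrow(snps), 75000L)
  # marginal BAF over a diploid genome is centred at 0.5
  baf <- snps$depth_b / (snps$depth_a + snps$depth_b)
  expect_lt(abs(mean(baf, na.rm = TRUE) - 0.5), 0.005)
  # flip fraction sits inside a 3-sigma binomial band of 0.01
  n <- nrow(snps)
  expect_lt(abs(mean(snps$flipped) - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("per-site allele depth is unbiased for the local haplotype depth", {
  cfg <- small_sdx_config(amp_cv = 0, ado_rate_per_mb = 0, gc_coef = 0,
                          phase_switch_prob = 0, poisson_noise = FALSE)
  ta <- simulate_haplotype_depth(cfg, "A", seed = 1L)
  tb <- simulate_haplotype_depth(cfg, "B", seed = 2L)
  snps <- place_ghets(cfg, ta, tb, data.table::data.table(), seed = 3L)
  expect_true(all(snps$depth_a == cfg$depth_per_haplotype))
  expect_true(all(snps$depth_b == cfg$depth_per_haplotype))
})

test_that("the experiment driver emits the plan plus controls deterministically", {
  cfg <- small_sdx_config(
    cna_plan = data.frame(type = "loss_1_0", size = 1e6, n = 3L),
    seed = 8L)
  d1 <- file.path(tempdir(), "sdx_a")
  d2 <- file.path(tempdir(), "sdx_b")
  b1 <- run_sdx_experiment(cfg, out_dir = d1, write_tables = TRUE)
  b2 <- run_sdx_experiment(cfg, out_dir = d2)
  expect_equal(nrow(b1$truth), 3L)
  expect_length(b1$cells, 4L)           # 3 mutated + 1 control
  # truth BED and manifest written; per-cell tables only on request
  expect_identical(readLines(file.path(d1, "truth.bed")),
                   readLines(file.path(d2, "truth.bed")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  tables <- list.files(d1, pattern = "bins.tsv$")
  expect_length(tables, 4L)
  expect_length(list.files(d2, pattern = "bins.tsv$"), 0L)
  # bin and SNP tables round-trip through the generic readers
  bins_back <- data.table::fread(file.path(d1, tables[1]))
  expect_equal(nrow(bins_back), 200L)
  # zero plan: control only, empty truth
  b0 <- run_sdx_experiment(small_sdx_config(cna_plan = data.frame()))
  expect_equal(nrow(b0$truth), 0L)
  expect_length(b0$cells, 1L)
})
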