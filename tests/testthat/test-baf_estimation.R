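test_that("the haplotype-specific shift has the intended fixed points", {
  # unit GC factors: identity
  expect_equal(shift_baf(c(10, 20), c(10, 20)), c(0.5, 0.5))
  # LOH (no B reads): unaffected by any reweighting
  expect_equal(shift_baf(c(30, 40), c(0, 0), c(0.8, 1.3)), c(0, 0))
  # balanced bins move off 0.5 by an amount tracking the GC factor
  s <- shift_baf(c(100, 100), c(100, 100), c(0.8, 1.25))
  expect_equal(s, c((100 / 0.8) / (100 + 100 / 0.8), 0.8 / 1.8 / 1))
  expect_true(s[1] > 0.5 && s[2] < 0.5)
  expect_error(shift_baf(1, 1, 0), "positive")
})

test_that("LOH detection separates homozygous from balanced segments", {
  set.seed(21)
  loh <- detect_loh(make_loh_segment(25))
  expect_true(loh$loh)
  expect_gte(loh$ks_p, 0.05)
  bal <- detect_loh(make_balanced_segment(25))
  expect_false(bal$loh)
  # under-sized segments are low-confidence and assumed non-LOH
  tiny <- detect_loh(make_loh_segment(5))
  expect_false(tiny$loh)
  expect_true(tiny$low_confidence)
})

test_that("false LOH rate on balanced segments stays within alpha + 0.02", {
  set.seed(22)
  flags <- vapply(1:500, function(i) {
    detect_loh(make_balanced_segment(20))$loh
  }, logical(1))
  expect_lte(mean(flags), 0.05 + 0.02)
})

test_that("peak calling strips dropout peaks and folds the survivor", {
  set.seed(23)
  # density peaks near 0.02 (dropout artifact) and 0.33: artifact removed
  sb <- data.table::data.table(
    pbaf = c(rnorm(8, 0.02, 0.005), rnorm(20, 0.33, 0.01)))
  res <- call_baf_peaks(sb, loh = FALSE)
  expect_lt(abs(res$baf - 1 / 3), 0.02)
  # the mirror peak near 1 is equally an artifact
  sb2 <- data.table::data.table(
    pbaf = c(rnorm(8, 0.98, 0.005), rnorm(20, 0.5, 0.01)))
  expect_equal(call_baf_peaks(sb2, loh = FALSE)$baf, 0.5, tolerance = 0.02)
  # LOH forces BAF 0
  expect_equal(call_baf_peaks(sb, loh = TRUE)$baf, 0)
  # single balanced peak
  sb3 <- data.table::data.table(pbaf = rnorm(30, 0.5, 0.01))
  expect_equal(call_baf_peaks(sb3, loh = FALSE)$baf, 0.5, tolerance = 0.02)
  expect_error(call_baf_peaks(sb3[0], loh = FALSE), "empty")
})

test_that("segment BAF is accurate on balanced and single-gain segments", {
  set.seed(24)
  # balanced {1,1} segments: |baf - 0.5| < 0.05 in >= 95%
  baf_bal <- vapply(1:200, function(i) {
    segment_baf(make_balanced_segment(15))$baf
  }, numeric(1))
  expect_gte(mean(abs(baf_bal - 0.5) < 0.05), 0.95)
  expect_true(all(baf_bal >= 0 & baf_bal <= 0.5))
  # {2,1} segments: BAF within 0.05 of 1/3 in >= 90%
  baf_gain <- vapply(1:200, function(i) {
    n <- 15L
    fa <- exp(rnorm(n, 0, 0.05)); fb <- exp(rnorm(n, 0, 0.05))
    a <- rpois(n, 750 * fa); b <- rpois(n, 1500 * fb)
    sb <- data.table::data.table(count_a = a, count_b = b,
                                 pbaf = b / (a + b),
                                 gc_factor = exp(rnorm(n, 0, 0.05)))
    segment_baf(sb)$baf
  }, numeric(1))
  expect_gte(mean(abs(baf_gain - 1 / 3) < 0.05), 0.90)
})

test_that("LOH implies zero BAF and low_confidence paths are consistent", {
  set.seed(25)
  res <- segment_baf(make_loh_segment(25))
  expect_true(res$loh)
  expect_equal(res$baf, 0)
  res5 <- segment_baf(make_loh_segment(5))
  expect_true(res5$low_confidence)
  expect_false(res5$loh)
})

test_that("BAF changepoints split at LOH edges and nowhere flat", {
  set.seed(26)
  flat <- abs(rnorm(40, 0.48, 0.03))
  expect_equal(baf_changepoint_split(flat, 0.03), 40L)
  step <- c(rnorm(18, 0.48, 0.03), rnorm(12, 0.01, 0.005),
            rnorm(10, 0.48, 0.03))
  lens <- baf_changepoint_split(step, 0.03)
  expect_equal(sum(lens), 40L)
  expect_equal(lens, c(18L, 12L, 10L))
  # NA bins are tolerated
  step_na <- step
  step_na[c(3, 25)] <- NA
  expect_equal(sum(baf_changepoint_split(step_na, 0.03)), 40L)
})
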