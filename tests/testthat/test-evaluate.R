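mk_iv <- function(start, end, cell = "c1", type = "loss_1_0") {
  data.table::data.table(chrom = "chr1", start = start, end = end,
                         cell_id = cell, type = type)
}

test_that("reciprocal-overlap matching classifies calls and truths", {
  truth <- mk_iv(1e6, 2e6)
  # identical call: TP
  m <- match_calls(mk_iv(1e6, 2e6), truth, n_boot = 0)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  # 40% reciprocal overlap at threshold 0.5: both FP and FN
  m2 <- match_calls(mk_iv(1.6e6, 2.6e6), truth, n_boot = 0)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  # same interval in the wrong cell or with the wrong type never matches
  m3 <- match_calls(mk_iv(1e6, 2e6, cell = "c2"), truth, n_boot = 0)
  expect_equal(m3$tp, 0)
  m4 <- match_calls(mk_iv(1e6, 2e6, type = "gain_2_1"), truth, n_boot = 0)
  expect_equal(m4$tp, 0)
  # zero calls: sensitivity 0, precision 1 by convention (or NA on request)
  m5 <- match_calls(mk_iv(1, 2)[0], truth, n_boot = 0)
  expect_equal(m5$sensitivity, 0)
  expect_equal(m5$precision, 1)
  m6 <- match_calls(mk_iv(1, 2)[0], truth, n_boot = 0,
                    zero_call_precision = NA_real_)
  expect_true(is.na(m6$precision))
})

test_that("matching is invariant to call order and threshold is honoured", {
  truth <- rbind(mk_iv(1e6, 2e6), mk_iv(5e6, 6e6, cell = "c2"))
  calls <- rbind(mk_iv(5.2e6, 6.1e6, cell = "c2"), mk_iv(1e6, 2e6))
  m <- match_calls(calls, truth, n_boot = 0)
  m_rev <- match_calls(calls[2:1], truth, n_boot = 0)
  expect_equal(m$tp, m_rev$tp)
  expect_equal(m$tp, 2)  # 0.8/0.89 reciprocal overlap passes 0.5
  strict <- match_calls(calls, truth, min_reciprocal_overlap = 0.9,
                        n_boot = 0)
  expect_equal(strict$tp, 1)
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  truth <- data.table::rbindlist(lapply(1:8, function(i) {
    mk_iv(i * 1e6, i * 1e6 + 5e5, cell = paste0("c", i))
  }))
  calls <- truth[1:6]   # 6 of 8 recovered
  m <- match_calls(calls, truth, n_boot = 100, seed = 1)
  expect_equal(m$sensitivity, 0.75)
  expect_true(m$sensitivity_ci[1] <= 0.75 && m$sensitivity_ci[2] >= 0.75)
})

test_that("FDR lookup uses the largest tabulated size strictly below", {
  tab <- data.table::data.table(
    type = c("loss_1_0", "loss_1_0", "gain_2_1"),
    size = c(1e6, 2e6, 1e6), fdr = c(0.10, 0.05, 0.30))
  expect_equal(estimate_fdr(mk_iv(0, 1.2e6), tab), 0.10)
  # mean over calls
  two <- rbind(mk_iv(0, 1.2e6), mk_iv(0, 1.2e6, type = "gain_2_1"))
  expect_equal(estimate_fdr(two, tab), mean(c(0.10, 0.30)))
  # smaller than every tabulated size: conservative smallest row
  expect_equal(estimate_fdr(mk_iv(0, 5e5), tab), 0.10)
  expect_message(out <- estimate_fdr(mk_iv(0, 1)[0], tab), "undefined")
  expect_true(is.na(out))
})

test_that("FDR estimate is monotone when the table decreases with size", {
  tab <- data.table::data.table(type = "loss_1_0",
                                size = c(5e5, 1e6, 2e6, 4e6),
                                fdr = c(0.4, 0.2, 0.1, 0.05))
  sizes <- c(6e5, 1.5e6, 3e6)
  small <- estimate_fdr(data.table::rbindlist(
    lapply(sizes, function(s) mk_iv(0, s))), tab)
  grown <- estimate_fdr(data.table::rbindlist(
    lapply(sizes * 2, function(s) mk_iv(0, s))), tab)
  expect_lte(grown, small)
})

test_that("clonality requires identical bin coordinates in >= 2 cells", {
  calls <- rbind(
    mk_iv(1e6, 2e6, cell = "c1"), mk_iv(1e6, 2e6, cell = "c2"),
    mk_iv(3e6, 4e6, cell = "c1"), mk_iv(3.1e6, 4.1e6, cell = "c2"),
    mk_iv(1e6, 2e6, cell = "c3", type = "gain_2_1"))
  out <- classify_clonality(calls, bin_size = 1e5)
  expect_equal(out$clonal, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$clone_group[1], out$clone_group[2])
  expect_true(is.na(out$clone_group[3]))
  # clone groups are equivalence classes: same key -> same group
  expect_equal(data.table::uniqueN(out$clone_group[out$clonal]), 1L)
  # single-cell data: everything private
  solo <- classify_clonality(calls[cell_id == "c1"], bin_size = 1e5)
  expect_true(all(!solo$clonal))
  # off-grid coordinates are rejected
  expect_error(classify_clonality(mk_iv(1e6 + 3, 2e6), bin_size = 1e5),
               "grid")
})
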