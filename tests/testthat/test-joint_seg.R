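test_that("single-cell BIC matches hand computation and conventions", {
  # one segment, a = b = 100, lambda = 1:
  # -2 * (100 log(1/2) + 100 log(1/2)) + 1 * log(N), N = sum(a) = 100
  expect_equal(bic_single(100, 100, lambda = 1),
               400 * log(2) + log(100))
  # N is the observed-read total and can be supplied explicitly
  expect_equal(bic_single(100, 100, lambda = 1, N = 200),
               400 * log(2) + log(200))
  # 0 * log 0 convention keeps the value finite
  expect_true(is.finite(bic_single(c(0, 50), c(10, 50), lambda = 1,
                                   N = 50)))
  # splitting a homogeneous segment only adds penalty
  whole <- bic_single(200, 200, lambda = 1)
  split <- bic_single(c(100, 100), c(100, 100), lambda = 1)
  expect_gt(split, whole)
  expect_equal(split - whole, log(200))
  expect_error(bic_single(0, 10, lambda = 1), "positive")
})

test_that("the multi-sample BIC reduces to and extends the single-cell form", {
  a <- c(120, 60); b <- c(100, 80)
  # G = 1: numeric identity with the single-cell BIC
  expect_equal(bic_joint(rbind(a), rbind(b), lambda = 1.5),
               bic_single(a, b, lambda = 1.5))
  # duplicating a cell doubles the likelihood term; the penalty becomes
  # (m+1) * 2 * lambda * log(2N)
  lik <- bic_single(a, b, lambda = 1) - 2 * 1 * log(sum(a))
  expect_equal(bic_joint(rbind(a, a), rbind(b, b), lambda = 1),
               2 * lik + 2 * 2 * 1 * log(2 * sum(a)))
  # linearity in lambda: doubling lambda doubles only the penalty
  b1 <- bic_joint(rbind(a, a), rbind(b, b), lambda = 1)
  b2 <- bic_joint(rbind(a, a), rbind(b, b), lambda = 2)
  expect_equal(b2 - b1, 2 * 2 * log(2 * sum(a)))
  expect_error(bic_joint(rbind(a), rbind(c(100, 80, 60))), "mismatched")
})

test_that("greedy merging finds a shared noiseless breakpoint exactly", {
  obs <- rbind(c(rep(100, 6), rep(200, 6)),
               c(rep(150, 6), rep(300, 6)))
  expc <- matrix(100, 2, 12)
  res <- joint_segment(obs, expc, lambda = 1)
  expect_equal(nrow(res$segments), 2L)
  expect_equal(res$segments$end_bin[1], 6L)
  # matches exhaustive minimisation over all 2^11 breakpoint subsets
  ex <- exhaustive_segment(obs, expc, lambda = 1)
  expect_equal(ex$breakpoints, 6L)
  expect_equal(res$bic, ex$bic)
})

test_that("degenerate regimes collapse to a single segment", {
  obs <- matrix(100, 2, 10)
  expc <- matrix(100, 2, 10)
  res <- joint_segment(obs, expc, lambda = 1)
  expect_equal(nrow(res$segments), 1L)
  # huge lambda flattens even strong signal
  obs2 <- rbind(c(rep(50, 5), rep(400, 5)))
  res2 <- joint_segment(obs2, matrix(100, 1, 10), lambda = 1e6)
  expect_equal(nrow(res2$segments), 1L)
  expect_error(joint_segment(matrix(0, 1, 0), matrix(0, 1, 0)), "empty")
})

test_that("BIC is non-increasing across merges and stable to cell order", {
  set.seed(31)
  obs <- matrix(rpois(2 * 14, rep(c(100, 160), each = 14)), nrow = 2,
                byrow = TRUE)
  expc <- matrix(120, 2, 14)
  res <- joint_segment(obs, expc, lambda = 1)
  expect_true(all(diff(res$bic_trace) < 1e-9))
  expect_equal(res$bic, res$bic_trace[length(res$bic_trace)])
  res_flip <- joint_segment(obs[2:1, ], expc, lambda = 1)
  expect_equal(res_flip$segments, res$segments)
})

test_that("greedy result is near the exhaustive optimum on small instances", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 12L
    rate <- rep(sample(c(80, 150), 2), c(5, 7))
    obs <- rbind(rpois(n, rate), rpois(n, rate * 1.3))
    expc <- matrix(100, 2, n)
    greedy <- joint_segment(obs, expc, lambda = 1)
    ex <- exhaustive_segment(obs, expc, lambda = 1)
    expect_lte(greedy$bic, ex$bic * 1.01)
    expect_gte(greedy$bic, ex$bic - 1e-9)
  }
})

test_that("chromosomes are segmented independently", {
  obs <- rbind(c(rep(100, 5), rep(100, 5)))
  expc <- matrix(100, 1, 10)
  chrom <- rep(c("chr1", "chr2"), each = 5)
  res <- joint_segment(obs, expc, lambda = 1e-6, chrom = chrom)
  # even with a tiny penalty, no segment may span the chromosome break
  expect_true(all(res$segments[chrom == "chr1", end_bin] <= 5L))
  expect_true(all(res$segments[chrom == "chr2", start_bin] >= 6L))
})
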