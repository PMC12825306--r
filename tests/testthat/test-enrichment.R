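test_that("median-of-ratios size factors match hand-computed values", {
  sf <- compute_size_factors(matrix(c(10, 10, 20, 20), ncol = 2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  same <- matrix(c(5, 9, 13, 5, 9, 13), ncol = 2)
  expect_equal(unname(compute_size_factors(same)), c(1, 1))

  # row with a zero is excluded from the median
  withzero <- matrix(c(0, 10, 20, 8, 10, 20), ncol = 2)
  expect_equal(unname(compute_size_factors(withzero)), c(1, 1))

  allzero <- matrix(c(0, 5, 0, 0, 0, 9), ncol = 2)  # every row has a zero
  expect_error(compute_size_factors(allzero), "positive counts")
})

test_that("scaling a sample's column scales its relative size factor", {
  # size factors are defined up to a common scale (the geometric mean of
  # the counts shifts too), so the invariant concerns factor ratios
  set.seed(9)
  m <- matrix(rpois(300, 40) + 1L, ncol = 3)
  sf <- compute_size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  sf2 <- compute_size_factors(m2)
  expect_equal((sf2[2] / sf2[1]) / (sf[2] / sf[1]), 5,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sf2[3] / sf2[1], sf[3] / sf[1], tolerance = 1e-12)
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1L, ncol = 6)
  expect_equal(unname(compute_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("the NB test is null on constant data and flags all-zero rows", {
  K <- matrix(50L, nrow = 3, ncol = 6)
  K[2, ] <- 0L
  res <- nb_two_group_test(K, rep(c("IP", "control"), each = 3),
                           size_factors = rep(1, 6))
  expect_equal(res$log2FoldChange[1], 0, tolerance = 1e-6)
  expect_gt(res$pvalue[1], 0.5)
  expect_true(res$all_zero[2])
  expect_true(is.na(res$pvalue[2]))
  expect_false(res$all_zero[3])
})

test_that("the NB test detects a strong planted fold change", {
  set.seed(14)
  m <- 400
  K <- matrix(rnbinom(m * 6, mu = 50, size = 10), ncol = 6)
  planted <- 1:20
  K[planted, 1:3] <- rnbinom(length(planted) * 3, mu = 400, size = 10)
  res <- nb_two_group_test(K, rep(c("IP", "control"), each = 3),
                           size_factors = rep(1, 6))
  expect_true(all(res$padj[planted] < 0.05))
  expect_true(all(res$log2FoldChange[planted] > 1))
  # nulls mostly non-significant
  expect_lt(mean(res$padj[-planted] < 0.05, na.rm = TRUE), 0.02)
})

test_that("degenerate designs are refused", {
  K <- matrix(1L, 2, 4)
  expect_error(nb_two_group_test(K, rep("IP", 4)), "two groups")
  expect_error(nb_two_group_test(K, c("IP", "IP", "IP", "control")),
               "replicates")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.05), 0.05)

  set.seed(31)
  for (n in 2:8) {
    p <- round(runif(n), 3)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NA passthrough and monotonicity
  p <- c(0.01, NA, 0.5, 0.002)
  a <- bh_adjust(p)
  expect_true(is.na(a[2]))
  expect_true(all(a >= p, na.rm = TRUE))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significant-window filter applies all three rules inclusively", {
  res <- data.frame(
    padj = c(0.04, 0.06, 0.01, 0.01, 0.01),
    mean_ip = c(49, 500, 50, 500, 500),
    log2FoldChange = c(2, 2, 2, -1, 2),
    mean_control = 1, chrom = "c", start = 1, end = 100)
  out <- call_significant_windows(res)
  # row 1 fails the >= 50 rule, row 2 significance, row 4 direction
  expect_equal(rownames(out), c("3", "5"))
})

test_that("windows merge below a strict 200-nt gap", {
  win <- function(s0, e0) data.frame(chrom = "chr1", start = s0 + 1,
                                     end = e0, padj = 0.01, mean_ip = 100)
  two <- rbind(win(0, 100), win(250, 350))      # gap 150 -> one site
  s <- merge_windows_into_sites(two)
  expect_length(s, 1L)
  expect_equal(BiocGenerics::start(s) - 1L, 0L)
  expect_equal(BiocGenerics::end(s), 350L)

  apart <- rbind(win(0, 100), win(300, 400))    # gap 200 -> two sites
  expect_length(merge_windows_into_sites(apart), 2L)

  near <- rbind(win(0, 100), win(299, 400))     # gap 199 -> one site
  expect_length(merge_windows_into_sites(near), 1L)

  over <- rbind(win(0, 100), win(50, 150))      # overlap -> one site
  s3 <- merge_windows_into_sites(over)
  expect_length(s3, 1L)
  expect_equal(BiocGenerics::end(s3), 150L)
  expect_equal(s3$n_windows, 2L)

  # different chromosomes never merge
  crossed <- rbind(win(0, 100),
                   data.frame(chrom = "chr2", start = 51, end = 150,
                              padj = 0.02, mean_ip = 60))
  expect_length(merge_windows_into_sites(crossed), 2L)
})

test_that("merged sites partition their windows with >= 200-nt gaps", {
  set.seed(8)
  s0 <- sort(sample(seq(0, 50000, by = 50), 120))
  wins <- data.frame(chrom = "chr1", start = s0 + 1, end = s0 + 100,
                     padj = runif(120, 0, 0.05), mean_ip = 100)
  sites <- merge_windows_into_sites(wins)
  expect_equal(sum(sites$n_windows), nrow(wins))
  if (length(sites) > 1) {
    gaps <- BiocGenerics::start(sites)[-1] -
      BiocGenerics::end(sites)[-length(sites)] - 1L
    expect_true(all(gaps >= 200))
  }
  expect_equal(min(sites$min_padj), min(wins$padj))
})
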