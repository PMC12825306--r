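test_that("length filter keeps exactly 15-35 nt reads", {
  r <- srna_gr("chr1", c(0, 0, 0, 0), c(14, 15, 35, 36), "+",
               paste0("s", 1:4), 1, 1)
  kept <- filter_srna_reads(r)
  expect_equal(sort(BiocGenerics::width(kept)), c(15L, 35L))
  expect_length(filter_srna_reads(r[integer(0)]), 0L)
})

test_that("multimapper weighting conserves library mass", {
  expect_equal(weighted_abundance(8, 4, 1e6), 2)
  expect_equal(weighted_abundance(10, 2, 1e6), 5)
  expect_equal(weighted_abundance(7, 1, 1e6), 7)
  expect_error(weighted_abundance(1, 0, 1e6), "k")
  expect_error(weighted_abundance(1, 1, 0), "total_mapped")

  # summing per-position weights over a library returns 1e6 RPM
  set.seed(6)
  counts <- sample(1:50, 200, replace = TRUE)
  ks <- sample(1:5, 200, replace = TRUE)
  lib <- sum(counts)
  total <- sum(weighted_abundance(counts, ks, lib) * ks)
  expect_equal(total, 1e6, tolerance = 1e-6)
})

test_that("region profiles tally contained reads only", {
  region <- gr1("chr1", 1000, 1100)
  reads <- c(
    srna_gr("chr1", 1010, 21, "+", "seqA", 60, 1),
    srna_gr("chr1", 1050, 21, "+", "seqB", 40, 2),
    srna_gr("chr1", 1090, 24, "+", "edge", 99, 1))  # spans the boundary
  pr <- profile_region(reads, region)
  expect_equal(pr$R, 100)
  expect_equal(pr$R_plus, 100)
  expect_equal(pr$R_minus, 0)
  expect_equal(pr$density, 100)
  expect_equal(pr$dominant_fraction, 0.6)
  expect_true(pr$has_unique_mapper)
  expect_equal(pr$n_len_21, 100)

  empty <- profile_region(reads[integer(0)], region)
  expect_equal(empty$R, 0)
  expect_equal(empty$density, 0)
  expect_error(profile_region(reads, gr1("chr1", 5, 5)), "region")
})

test_that("the four-rule classifier reproduces its defining examples", {
  expect_equal(classify_region(fake_profile(3, 3, 0, 1))$category, "CAT0")
  expect_equal(classify_region(fake_profile(10, 12, 8, 0.3))$category,
               "CAT3")                                   # B = 1.5
  expect_equal(classify_region(fake_profile(50, 45, 5, 0.2))$category,
               "CAT2")                                   # B = 9
  cl1 <- classify_region(fake_profile(100, 99, 1, 0.6, TRUE))
  expect_equal(cl1$category, "CAT1")
  expect_false(cl1$ambiguous)
})

test_that("classifier boundaries are exact", {
  # density threshold at exactly 5
  expect_equal(classify_region(fake_profile(4.99, 499, 0, 1))$category,
               "CAT0")
  expect_equal(classify_region(fake_profile(5, 500, 0, 1, TRUE))$category,
               "CAT1")   # B = Inf with zero minority
  # bias 3.99 vs 4.0 vs 10.0
  expect_equal(classify_region(fake_profile(20, 399, 100, 0.2))$category,
               "CAT3")   # B = 3.99
  expect_equal(classify_region(fake_profile(20, 400, 100, 0.2))$category,
               "CAT2")   # B = 4 exactly
  expect_equal(classify_region(fake_profile(20, 1000, 100, 0.5,
                                            TRUE))$category,
               "CAT1")   # B = 10 exactly, d > 0.4, unique mapper
  # dominance 0.40 (not >) vs 0.401
  expect_equal(classify_region(fake_profile(20, 1000, 100, 0.40,
                                            TRUE))$category, "CAT2")
  expect_equal(classify_region(fake_profile(20, 1000, 100, 0.401,
                                            TRUE))$category, "CAT1")
})

test_that("classifier gap cells fall to CAT2 with the ambiguity flag", {
  g1 <- classify_region(fake_profile(20, 500, 100, 0.6))    # B in [4,10)
  expect_equal(g1$category, "CAT2")
  expect_true(g1$ambiguous)
  g2 <- classify_region(fake_profile(20, 1000, 50, 0.6, FALSE)) # no k=1
  expect_equal(g2$category, "CAT2")
  expect_true(g2$ambiguous)
  plain <- classify_region(fake_profile(20, 500, 100, 0.2))
  expect_false(plain$ambiguous)
})

test_that("every CAT1 profile satisfies the CAT2 numeric preconditions
           except the dominance bound", {
  set.seed(17)
  for (i in 1:1000) {
    pr <- fake_profile(runif(1, 0, 60), rpois(1, 60), rpois(1, 8),
                       runif(1), sample(c(TRUE, FALSE), 1))
    cl <- classify_region(pr)
    if (cl$category == "CAT1") {
      B <- max(pr$R_plus, pr$R_minus) / max(min(pr$R_plus, pr$R_minus), 1)
      expect_gte(pr$density, 5)
      expect_gte(B, 4)
    }
    # determinism: same profile, same answer
    expect_identical(classify_region(pr), cl)
  }
})

test_that("length-class proportions cover 20/21, 22 and 24 nt reads", {
  r <- srna_gr("chr1", rep(0, 3), c(21, 22, 24), "+", paste0("s", 1:3),
               c(8, 1, 1), 1)
  lp <- length_class_proportions(r)
  expect_equal(unname(lp$proportions), c(0.8, 0.1, 0.1))
  expect_equal(sum(lp$proportions), 1, tolerance = 1e-9)

  only24 <- srna_gr("chr1", 0, 24, "+", "x", 5, 1)
  expect_equal(unname(length_class_proportions(only24)$proportions),
               c(0, 0, 1))

  set.seed(23)
  lens <- sample(15:35, 60, replace = TRUE)
  cnts <- sample(1:9, 60, replace = TRUE)
  rr <- srna_gr("chr1", seq(0, by = 50, length.out = 60), lens, "+",
                paste0("q", 1:60), cnts, 1)
  lp2 <- length_class_proportions(rr)
  tot <- sum(cnts[lens %in% c(20, 21, 22, 24)])
  expect_equal(unname(lp2$proportions["22"]), sum(cnts[lens == 22]) / tot)
  expect_equal(lp2$n_other, sum(cnts[!lens %in% c(20, 21, 22, 24)]))
})

test_that("metaprofiles preserve constancy and mirror minus-strand loci", {
  cl <- c(chr1 = 4000)
  flat <- coverage_track(gr1("chr1", 0, 4000), cl)  # depth 1 everywhere
  f <- gr1("chr1", 1000, 1400, strand = "+")
  mp <- metaprofile(flat, f, flank = 100, body_bins = 20)
  expect_true(all(abs(mp$profile$value - 1) < 1e-12))
  expect_equal(mp$n_loci, 1L)

  # coverage only inside the body -> zero flanks
  inside <- coverage_track(gr1("chr1", 1000, 1400), cl)
  mp2 <- metaprofile(inside, f, flank = 100, body_bins = 20)
  expect_true(all(mp2$profile$value[mp2$profile$position != "body"] == 0))
  expect_true(all(mp2$profile$value[mp2$profile$position == "body"] == 1))

  # minus-strand feature with asymmetric coverage mirrors the plus profile
  asym <- coverage_track(gr1("chr1", 900, 1200), cl)
  fp <- gr1("chr1", 1000, 1400, strand = "+")
  fm <- gr1("chr1", 1000, 1400, strand = "-")
  vp <- metaprofile(asym, fp, flank = 100, body_bins = 20)$profile$value
  vm <- metaprofile(asym, fm, flank = 100, body_bins = 20)$profile$value
  expect_equal(vm, rev(vp))
})

test_that("peak positions are labelled within or flanking with ties inside", {
  cl <- c(chr1 = 3000)
  pre <- gr1("chr1", 1000, 1200)
  inside <- coverage_track(rep(gr1("chr1", 1050, 1100), 3), cl)
  expect_equal(classify_peak_position(inside, pre, flank = 500), "within")

  up <- coverage_track(rep(gr1("chr1", 700, 750), 3), cl)
  expect_equal(classify_peak_position(up, pre, flank = 500), "flanking")

  tie <- coverage_track(c(gr1("chr1", 700, 750), gr1("chr1", 1050, 1100)),
                        cl)
  expect_equal(classify_peak_position(tie, pre, flank = 500), "within")

  nothing <- coverage_track(GenomicRanges::GRanges(), cl)
  expect_true(is.na(classify_peak_position(nothing, pre, flank = 500)))
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 0.4857,
               tolerance = 1e-4)

  set.seed(19)
  for (i in 1:40) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})
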