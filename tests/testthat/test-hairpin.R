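test_that("a perfect inverted repeat yields exactly its stem", {
  set.seed(41)
  arm <- random_dna_string(30)
  hp <- make_hairpin_seq(arm, "AAAAAAAA")   # poly-A loop cannot pair
  cand <- scan_hairpins(hp)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$stem, 30L)
  expect_equal(cand$mismatches, 0L)
  expect_equal(cand$loop, 8L)
  expect_equal(cand$left_start, 1L)
  expect_equal(cand$right_end, 68L)
  expect_true(has_premirna_like_hairpin(hp))
})

test_that("stems below 25 columns or above 10 mismatches are rejected", {
  # AC-periodic arms: off-register pairings provably fail, so the only
  # stems are the constructed register and its even shifts
  arm24 <- strrep("AC", 12)
  expect_equal(nrow(scan_hairpins(make_hairpin_seq(arm24, "AAAAAAAA"))), 0L)
  expect_false(has_premirna_like_hairpin(make_hairpin_seq(arm24, "AAAAAAAA")))

  # 11 substitutions placed in the central columns: every >= 25-column
  # sub-window keeps all 11 mismatches, in every register
  arm30 <- strrep("AC", 15)
  broken <- make_hairpin_seq(arm30, "AAAAAAAA", sub_cols = 6:16)
  expect_false(has_premirna_like_hairpin(broken))
  ten <- make_hairpin_seq(arm30, "AAAAAAAA", sub_cols = 6:15)
  expect_true(has_premirna_like_hairpin(ten))   # 10 mismatches allowed

  expect_false(has_premirna_like_hairpin(strrep("A", 200)))
})

test_that("short sequences scan to an empty candidate set", {
  expect_message(out <- scan_hairpins(random_dna_string(40)), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("scanner matches brute-force enumeration on random sequences", {
  set.seed(47)
  par <- hairpin_params(min_stem = 8, max_mismatch = 3, min_loop = 3)
  n_pos <- 0L
  for (i in 1:60) {
    s <- random_dna_string(sample(30:90, 1))
    mine <- scan_hairpins(s, par)
    oracle <- oracle_scan_hairpins(s, min_stem = 8, max_mismatch = 3,
                                   min_loop = 3)
    expect_equal(mine, oracle, ignore_attr = TRUE)
    n_pos <- n_pos + (nrow(mine) > 0L)
  }
  expect_gt(n_pos, 5L)   # the suite exercises both accept and reject
})

test_that("reverse-complement symmetry holds under Watson-Crick pairing", {
  set.seed(53)
  par <- hairpin_params(min_stem = 8, max_mismatch = 2, wobble = FALSE)
  for (i in 1:20) {
    s <- random_dna_string(sample(40:80, 1))
    n <- nchar(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- scan_hairpins(s, par)
    b <- scan_hairpins(rc, par)
    mirrored <- data.frame(left_start = n + 1L - b$right_end,
                           left_end = n + 1L - b$right_start,
                           right_start = n + 1L - b$left_end,
                           right_end = n + 1L - b$left_start,
                           stem = b$stem, mismatches = b$mismatches,
                           loop = b$loop)
    mirrored <- mirrored[order(mirrored$left_start, mirrored$right_start,
                               mirrored$stem), , drop = FALSE]
    expect_equal(a, mirrored, ignore_attr = TRUE)
  }
})

test_that("relaxing the thresholds never loses a positive sequence", {
  set.seed(59)
  strict <- hairpin_params(min_stem = 12, max_mismatch = 2)
  fewer_mm <- hairpin_params(min_stem = 12, max_mismatch = 4)
  shorter <- hairpin_params(min_stem = 10, max_mismatch = 2)
  for (i in 1:30) {
    s <- random_dna_string(60)
    if (has_premirna_like_hairpin(s, strict)) {
      expect_true(has_premirna_like_hairpin(s, fewer_mm))
      expect_true(has_premirna_like_hairpin(s, shorter))
    }
  }
})

test_that("planted hairpins are recovered and shuffling lowers the rate", {
  # scan parameters matched to the planted structure (stem 30, <= 5
  # mismatches); at these settings a random sequence of this length
  # essentially never qualifies, so the discrimination is sharp
  par <- hairpin_params(min_stem = 30, max_mismatch = 5)
  set.seed(61)
  n <- 40
  planted <- vapply(seq_len(n), function(i) {
    arm <- random_dna_string(30)
    pre <- random_dna_string(40); post <- random_dna_string(40)
    subs <- sample(2:29, sample(0:5, 1))   # interior, so no trimming
    paste0(pre, make_hairpin_seq(arm, "GAACTTCAA", sub_cols = subs), post)
  }, character(1))
  hits <- vapply(planted, has_premirna_like_hairpin, logical(1), params = par)
  expect_true(all(hits))   # 100% recovery
  shuffled <- vapply(planted, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  fpr <- mean(vapply(shuffled, has_premirna_like_hairpin, logical(1),
                     params = par))
  expect_lt(fpr, mean(hits))
})

test_that("length-matched controls reproduce the length multiset", {
  excl <- gr1("chr1", c(0, 5000), c(2000, 9000))
  sets <- sample_length_matched_controls(c(chr1 = 20000, chr2 = 10000),
                                         c(100, 240, 500), n_sets = 4,
                                         exclusions = excl, seed = 71)
  for (s in sets) {
    expect_equal(sort(BiocGenerics::width(s)), c(100L, 240L, 500L))
    expect_length(GenomicRanges::findOverlaps(s, excl), 0L)
  }
  again <- sample_length_matched_controls(c(chr1 = 20000, chr2 = 10000),
                                          c(100, 240, 500), n_sets = 4,
                                          exclusions = excl, seed = 71)
  expect_identical(lapply(sets, as.data.frame), lapply(again, as.data.frame))

  expect_error(sample_length_matched_controls(c(chr1 = 100), 500),
               "exceeds")
})

test_that("hairpin fraction equals the per-region tally", {
  set.seed(73)
  chrom <- paste0(
    random_dna_string(300),
    make_hairpin_seq(random_dna_string(30), "AAAAAAAA"),
    random_dna_string(300))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  regions <- c(gr1("chr1", 290, 380),    # contains the planted hairpin
               gr1("chr1", 0, 100),
               gr1("chr1", 500, 600))
  frac <- hairpin_fraction(regions, genome)
  tally <- mean(vapply(region_sequences(genome, regions),
                       has_premirna_like_hairpin, logical(1)))
  expect_equal(frac, tally)
  expect_gte(frac, 1 / 3)
})
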