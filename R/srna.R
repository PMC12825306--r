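#' Collapsed small-RNA reads as genomic positions
#'
#' Small-RNA libraries are represented as a `GRanges` of genomic positions
#' with one range per (sequence, position) pair and metadata columns:
#' `sequence` (the read sequence), `count` (copies of that sequence in the
#' library) and `k` (the sequence's total number of genomic positions, its
#' mapping multiplicity). The range width equals the read length and the
#' strand records the mapping orientation.
#'
#' `read_srna_table()` builds this object from a collapsed-read TSV
#' (columns `sequence`, `count`, `k`) plus a BED file of positions whose
#' `name` column holds the sequence.
#'
#' @param table_path TSV with columns `sequence`, `count`, `k`.
#' @param bed_path BED file of genomic positions, `name` = sequence.
#' @return `GRanges` as described above.
#' @export
read_srna_table <- function(table_path, bed_path) {
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "count", "k") %in% colnames(tab)))
  pos <- rtracklayer::import(bed_path)
  i <- match(pos$name, tab$sequence)
  if (anyNA(i)) stop("positions reference sequences absent from the table")
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(pos),
                                IRanges::ranges(pos),
                                strand = BiocGenerics::strand(pos))
  S4Vectors::mcols(out)$sequence <- tab$sequence[i]
  S4Vectors::mcols(out)$count <- tab$count[i]
  S4Vectors::mcols(out)$k <- tab$k[i]
  out
}

#' Filter small-RNA reads to the analysable length range
#'
#' Retains reads whose length lies in `[min_len, max_len]` (defaults 15-35
#' nt, the standard small-RNA size selection). Length is the genomic span of
#' each position, which for perfect full-length matches equals the sequence
#' length.
#'
#' @param reads sRNA `GRanges` (see [read_srna_table()]).
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return The filtered `GRanges`.
#' @export
filter_srna_reads <- function(reads, min_len = 15L, max_len = 35L) {
  reads[BiocGenerics::width(reads) >= min_len &
        BiocGenerics::width(reads) <= max_len]
}

#' Multimapper-weighted abundance in reads per million
#'
#' Normalizes a sequence's read count by its number of genomic positions
#' `k` and by the library size: each position receives
#' `(count / k) / total_mapped * 1e6` RPM, so summing a sequence's weight
#' over its `k` positions recovers `count / total_mapped * 1e6`.
#'
#' @param count Read count(s) of the sequence.
#' @param k Number of genomic positions (>= 1).
#' @param total_mapped Library size (total mapped reads), > 0.
#' @return Numeric per-position RPM weight(s).
#' @export
weighted_abundance <- function(count, k, total_mapped) {
  if (any(total_mapped <= 0)) stop("'total_mapped' must be positive")
  if (any(k < 1)) stop("'k' must be >= 1")
  (count / k) / total_mapped * 1e6
}

#' Summarize the small-RNA population of a region
#'
#' Considers reads fully contained in the region ("nested") and reports the
#' quantities the accumulation-pattern classifier consumes: total reads
#' `R`, per-strand reads, density per 100 nt, dominant-sequence fraction
#' `d`, presence of a uniquely-mapping sequence (`k == 1`), and the length
#' histogram over 20-24 nt. Counts are raw (unweighted) read counts.
#'
#' @param reads Filtered sRNA `GRanges`.
#' @param region Single-range `GRanges` (or coercible).
#' @return One-row `data.frame` with columns `width`, `R`, `R_plus`,
#'   `R_minus`, `density`, `dominant_fraction`, `has_unique_mapper`,
#'   `n_len_20` .. `n_len_24`.
#' @export
profile_region <- function(reads, region) {
  region <- methods::as(region, "GRanges")
  if (length(region) != 1L) stop("'region' must be a single interval")
  if (BiocGenerics::width(region) == 0L) stop("zero-length region")
  hits <- GenomicRanges::findOverlaps(reads, region, type = "within",
                                      ignore.strand = TRUE)
  inreg <- reads[S4Vectors::queryHits(hits)]
  cnt <- if (length(inreg)) inreg$count else numeric(0)
  R <- sum(cnt)
  minus <- as.character(BiocGenerics::strand(inreg)) == "-"
  R_minus <- sum(cnt[minus]); R_plus <- R - R_minus
  d <- if (R > 0) {
    max(tapply(cnt, inreg$sequence, sum)) / R
  } else NA_real_
  lens <- BiocGenerics::width(inreg)
  lh <- vapply(20:24, function(L) sum(cnt[lens == L]), numeric(1))
  data.frame(width = BiocGenerics::width(region), R = R, R_plus = R_plus,
             R_minus = R_minus,
             density = 100 * R / BiocGenerics::width(region),
             dominant_fraction = d,
             has_unique_mapper = length(inreg) > 0 && any(inreg$k == 1),
             n_len_20 = lh[1], n_len_21 = lh[2], n_len_22 = lh[3],
             n_len_23 = lh[4], n_len_24 = lh[5])
}

#' Classify a region's small-RNA accumulation pattern
#'
#' Four-rule decision tree over the region profile:
#' \describe{
#'   \item{CAT0 (no/few reads)}{density < 5 reads per 100 nt.}
#'   \item{CAT3 (siRNA-like)}{density >= 5 and strand bias
#'     `B = max(R+, R-) / min(R+, R-)` < 4.}
#'   \item{CAT1 (miRNA-like)}{density >= 5, B >= 10, dominant-sequence
#'     fraction > 0.4, and at least one contained sequence with a single
#'     genomic position.}
#'   \item{CAT2 (proto-miRNA)}{every other case with density >= 5 and
#'     B >= 4.}
#' }
#' `B` is `+Inf` when the minority strand has zero reads. Profiles falling
#' in the rule gaps (B in \[4, 10) with dominance > 0.4, or B >= 10 and
#' dominance > 0.4 without a unique mapper) are CAT2 with `ambiguous = TRUE`.
#'
#' @param profile One-row profile from [profile_region()] (or a list with
#'   fields `density`, `R_plus`, `R_minus`, `dominant_fraction`,
#'   `has_unique_mapper`).
#' @param min_density Density threshold in reads per 100 nt (default 5).
#' @param sirna_bias Strand-bias bound below which a populated region is
#'   siRNA-like (default 4).
#' @param mirna_bias Strand-bias bound for the miRNA-like call (default 10).
#' @param dominance Dominant-sequence fraction bound (default 0.4,
#'   strict `>` for the miRNA-like call).
#' @return List with `category` (`"CAT0"` .. `"CAT3"`) and `ambiguous`
#'   (logical).
#' @export
classify_region <- function(profile, min_density = 5, sirna_bias = 4,
                            mirna_bias = 10, dominance = 0.4) {
  dens <- profile$density
  if (dens < min_density) return(list(category = "CAT0", ambiguous = FALSE))
  hi <- max(profile$R_plus, profile$R_minus)
  lo <- min(profile$R_plus, profile$R_minus)
  B <- if (lo == 0) Inf else hi / lo
  if (B < sirna_bias) return(list(category = "CAT3", ambiguous = FALSE))
  d <- profile$dominant_fraction
  uniq <- isTRUE(profile$has_unique_mapper)
  if (B >= mirna_bias && d > dominance && uniq)
    return(list(category = "CAT1", ambiguous = FALSE))
  amb <- (B < mirna_bias && d > dominance) ||
    (B >= mirna_bias && d > dominance && !uniq)
  list(category = "CAT2", ambiguous = amb)
}

#' Profile and classify many regions at once
#'
#' @param reads Filtered sRNA `GRanges`.
#' @param regions `GRanges` of regions (binding sites).
#' @param ... Threshold overrides passed to [classify_region()].
#' @return `data.frame` with one row per region: the [profile_region()]
#'   columns plus `category` and `ambiguous`.
#' @export
classify_srna_regions <- function(reads, regions, ...) {
  rows <- lapply(seq_along(regions), function(i) {
    pr <- profile_region(reads, regions[i])
    cl <- classify_region(pr, ...)
    cbind(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(regions[i])),
      start = BiocGenerics::start(regions[i]),
      end = BiocGenerics::end(regions[i])), pr,
      data.frame(category = cl$category, ambiguous = cl$ambiguous))
  })
  do.call(rbind, rows)
}

#' Proportions of the 20/21-, 22- and 24-nt small-RNA classes
#'
#' Computes class proportions over reads of length 20, 21, 22 or 24 nt (the
#' biologically interpreted size classes); other lengths are tallied
#' separately and excluded from the denominator.
#'
#' @param reads Filtered sRNA `GRanges` (counts weighted by the `count`
#'   column).
#' @return List with `proportions` (named numeric over `"20-21"`, `"22"`,
#'   `"24"`, summing to 1), `n_in_classes` and `n_other` (read counts). When
#'   no read falls in the classes, `proportions` is empty.
#' @export
length_class_proportions <- function(reads) {
  lens <- BiocGenerics::width(reads)
  cnt <- reads$count
  n2021 <- sum(cnt[lens %in% c(20L, 21L)])
  n22 <- sum(cnt[lens == 22L])
  n24 <- sum(cnt[lens == 24L])
  tot <- n2021 + n22 + n24
  other <- sum(cnt) - tot
  if (tot == 0)
    return(list(proportions = numeric(0), n_in_classes = 0, n_other = other))
  list(proportions = c("20-21" = n2021 / tot, "22" = n22 / tot,
                       "24" = n24 / tot),
       n_in_classes = tot, n_other = other)
}

#' Average relative coverage over a set of features
#'
#' Metagene-style profile: for each feature the coverage over its body is
#' rescaled to `body_bins` bins on \[0, 1\] and the `flank` nt up- and
#' downstream are kept at fixed `flank_bin`-nt resolution; minus-strand
#' features are reversed so upstream is always on the left. Each locus is
#' normalized to its own maximum before averaging, so highly expressed loci
#' do not dominate the mean shape.
#'
#' @param cov `RleList` coverage (from [coverage_track()]).
#' @param features Stranded (or unstranded) `GRanges` of feature bodies.
#' @param flank Flank size in nt (default 500).
#' @param body_bins Number of bins over the scaled body (default 100).
#' @param flank_bin Flank bin width in nt (default 1).
#' @return List with `profile` (`data.frame` of `position` label, `bin`
#'   index and `value`) and `n_loci`. Features whose flanks run off the
#'   chromosome are clamped (zero-padded) with a message.
#' @export
metaprofile <- function(cov, features, flank = 500L, body_bins = 100L,
                        flank_bin = 1L) {
  if (length(features) == 0L) stop("no features")
  flank <- as.integer(flank); body_bins <- as.integer(body_bins)
  n_fl <- as.integer(ceiling(flank / flank_bin))
  prof <- matrix(0, nrow = length(features), ncol = n_fl + body_bins + n_fl)
  clamped <- 0L
  for (i in seq_along(features)) {
    f <- features[i]
    ch <- as.character(GenomeInfoDb::seqnames(f))
    v <- as.numeric(cov[[ch]])
    L <- length(v)
    s <- BiocGenerics::start(f); e <- BiocGenerics::end(f)
    up <- (s - flank):(s - 1L); dn <- (e + 1L):(e + flank)
    if (any(up < 1L) || any(dn > L)) clamped <- clamped + 1L
    getv <- function(idx) ifelse(idx >= 1L & idx <= L, v[pmax(pmin(idx, L), 1L)], 0)
    upv <- .bin_mean(getv(up), n_fl)
    body <- .bin_mean(v[s:e], body_bins)
    dnv <- .bin_mean(getv(dn), n_fl)
    row <- c(upv, body, dnv)
    if (as.character(BiocGenerics::strand(f)) == "-") row <- rev(row)
    m <- max(row)
    if (m > 0) row <- row / m
    prof[i, ] <- row
  }
  if (clamped > 0L)
    message(clamped, " feature(s) had flanks clamped at chromosome ends")
  avg <- colMeans(prof)
  pos <- c(rep("upstream", n_fl), rep("body", body_bins),
           rep("downstream", n_fl))
  list(profile = data.frame(position = pos,
                            bin = seq_along(avg), value = avg),
       n_loci = length(features))
}

.bin_mean <- function(v, nbins) {
  n <- length(v)
  if (n == nbins) return(as.numeric(v))
  if (n == 1L) return(rep(as.numeric(v), nbins))
  if (n < nbins) return(stats::approx(seq_len(n), v, n = nbins)$y)
  idx <- ceiling(seq_along(v) / n * nbins)  # n > nbins: every bin non-empty
  as.numeric(tapply(v, idx, mean))
}

#' Locate the maximum-coverage peak relative to a pre-miRNA
#'
#' Labels the position of the coverage maximum over the pre-miRNA body plus
#' its flanks as `"within"` (inside the body) or `"flanking"`. When tied
#' maxima occur both inside and outside the body the label is `"within"`.
#'
#' @param cov `RleList` coverage.
#' @param pre_mirna Single-range `GRanges` of the stem-loop body.
#' @param flank Flank size in nt (default 500), clamped at chromosome ends.
#' @return `"within"`, `"flanking"`, or `NA` when coverage is zero over the
#'   whole window.
#' @export
classify_peak_position <- function(cov, pre_mirna, flank = 500L) {
  pre_mirna <- methods::as(pre_mirna, "GRanges")
  stopifnot(length(pre_mirna) == 1L)
  ch <- as.character(GenomeInfoDb::seqnames(pre_mirna))
  v <- as.numeric(cov[[ch]])
  s <- BiocGenerics::start(pre_mirna); e <- BiocGenerics::end(pre_mirna)
  lo <- max(1L, s - flank); hi <- min(length(v), e + flank)
  w <- v[lo:hi]
  if (all(w == 0)) return(NA_character_)
  at <- lo:hi
  peak_pos <- at[w == max(w)]
  if (any(peak_pos >= s & peak_pos <= e)) "within" else "flanking"
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' tables with the observed margins, that do not exceed the observed
#' table's probability.
#'
#' @param tab 2x2 matrix of nonnegative integers.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must contain nonnegative integers")
  stats::fisher.test(tab)$p.value
}
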