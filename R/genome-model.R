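#' Tile a genome into constant-length sliding windows
#'
#' Divides each chromosome into windows of length `window` advancing by
#' `step`, the grid used for genome-wide RIP enrichment testing (defaults:
#' 100-bp windows overlapping by 50 bp). Terminal windows shorter than
#' `window` are not emitted, so every window has the same length and the
#' per-window read-count threshold stays comparable across the genome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (nt).
#' @param window Window length in nt (default 100).
#' @param step Step between window starts in nt (default 50); must satisfy
#'   `0 < step <= window`.
#'
#' @return A [GenomicRanges::GRanges] of windows, ordered by chromosome then
#'   start, with `seqlengths` set. A chromosome shorter than `window`
#'   contributes no windows.
#' @examples
#' tile_genome(c(chr1 = 1000))           # 19 windows
#' tile_genome(c(chr1 = 149))            # 1 window, no truncated tail
#' @export
tile_genome <- function(chrom_lengths, window = 100L, step = 50L) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("'chrom_lengths' must be a named vector")
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(window) || window <= 0L) stop("'window' must be a positive integer")
  if (is.na(step) || step <= 0L || step > window)
    stop("'step' must satisfy 0 < step <= window")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")

  chroms <- names(chrom_lengths)
  per_chrom <- lapply(chroms, function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    if (L < window) return(NULL)
    starts0 <- seq.int(0L, L - window, by = step)  # 0-based starts
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts0 + 1L, width = window))
  })
  gr <- do.call(c, c(per_chrom[!vapply(per_chrom, is.null, logical(1))],
                     list(GenomicRanges::GRanges())))
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_lengths)
  sort(gr, ignore.strand = TRUE)
}

#' Extend intervals by a fixed flank on both sides
#'
#' Enlarges each interval by `flank` nt upstream and downstream, clamping to
#' the chromosome bounds (the convention used for miRNA primary-transcript
#' annotations before overlap counting). Strand is preserved.
#'
#' @param x A [GenomicRanges::GRanges]; `seqlengths` should be set so the
#'   right ends can be clamped.
#' @param flank Nonnegative flank size in nt (default 100).
#' @return The enlarged `GRanges`.
#' @export
enlarge_intervals <- function(x, flank = 100L) {
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) stop("'flank' must be >= 0")
  if (flank == 0L) return(x)
  GenomicRanges::trim(suppressWarnings(x + flank))
}

#' Count reads over features for one or more samples
#'
#' Builds the feature-by-sample count matrix feeding the enrichment test.
#' Two overlap modes match the two counting rules used across the pipeline:
#' `"any"` increments a feature for every read sharing at least 1 nt with it
#' (RIP window counting), `"within"` only for reads fully contained in the
#' feature (sRNA reads nested into an annotation). Counting ignores strand;
#' reads on chromosomes absent from the features' seqinfo are skipped with a
#' warning.
#'
#' @param read_sets Named list (or [GenomicRanges::GRangesList]) of read
#'   intervals, one element per sample.
#' @param features `GRanges` of features (windows or annotations).
#' @param mode `"any"` or `"within"`.
#' @param groups Optional character vector (same length as `read_sets`) of
#'   group labels, e.g. `"IP"`/`"control"`, stored in the result's `colData`.
#' @return A [SummarizedExperiment::RangedSummarizedExperiment] with an
#'   integer `counts` assay, `rowRanges = features` and per-sample `colData`.
#' @export
count_reads <- function(read_sets, features, mode = c("any", "within"),
                        groups = NULL) {
  mode <- match.arg(mode)
  if (length(features) == 0L) stop("'features' must be nonempty")
  if (is.null(names(read_sets)))
    names(read_sets) <- paste0("sample", seq_along(read_sets))
  keep_levels <- GenomeInfoDb::seqlevels(features)

  counts <- vapply(names(read_sets), function(nm) {
    reads <- read_sets[[nm]]
    bad <- !(as.character(GenomeInfoDb::seqnames(reads)) %in% keep_levels)
    if (any(bad)) {
      warning(sprintf("%s: skipped %d read(s) on unknown chromosome(s)",
                      nm, sum(bad)))
      reads <- reads[!bad]
    }
    GenomeInfoDb::seqlevels(reads, pruning.mode = "coarse") <- keep_levels
    if (mode == "any") {
      GenomicRanges::countOverlaps(features, reads, ignore.strand = TRUE)
    } else {
      hits <- GenomicRanges::findOverlaps(reads, features, type = "within",
                                          ignore.strand = TRUE)
      tabulate(S4Vectors::subjectHits(hits), nbins = length(features))
    }
  }, integer(length(features)))
  counts <- matrix(as.integer(counts), nrow = length(features),
                   dimnames = list(NULL, names(read_sets)))

  cdata <- S4Vectors::DataFrame(sample = names(read_sets),
                                row.names = names(read_sets))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(read_sets))
    cdata$group <- groups
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = features, colData = cdata)
}

#' Per-base read coverage
#'
#' Single-nucleotide depth per chromosome: `depth(p)` is the number of read
#' intervals containing position `p`, so total depth mass equals the summed
#' read lengths.
#'
#' @param reads `GRanges` of read intervals.
#' @param chrom_lengths Named vector of chromosome lengths; defines the
#'   track extent.
#' @return An [IRanges::RleList] with one run-length-encoded depth vector
#'   per chromosome.
#' @export
coverage_track <- function(reads, chrom_lengths) {
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(reads),
                               IRanges::ranges(reads))
  GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_lengths)
  GenomicRanges::coverage(gr)
}
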