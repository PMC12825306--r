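# Shared in-code fixtures.

gr1 <- function(chrom, start0, end0, strand = "*", seqlen = NULL) {
  # convenience: build a GRanges from 0-based half-open coordinates, the
  # convention of the BED-facing documentation
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start0 + 1L, end0),
                              strand = strand)
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlevels(g) <- names(seqlen)
    GenomeInfoDb::seqlengths(g) <- as.integer(seqlen)
  }
  g
}

srna_gr <- function(chrom, start0, len, strand, sequence, count, k) {
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start0 + 1L, width = len),
                              strand = strand)
  S4Vectors::mcols(g)$sequence <- sequence
  S4Vectors::mcols(g)$count <- count
  S4Vectors::mcols(g)$k <- k
  g
}

meth_gr <- function(chrom, pos1, context, level) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos1, width = 1L))
  S4Vectors::mcols(g)$context <- context
  S4Vectors::mcols(g)$level <- level
  g
}

# A profile row for classifier tests without building reads.
fake_profile <- function(density, R_plus, R_minus, dominant_fraction,
                         has_unique_mapper = TRUE) {
  list(density = density, R_plus = R_plus, R_minus = R_minus,
       dominant_fraction = dominant_fraction,
       has_unique_mapper = has_unique_mapper)
}

# Small synthetic scenario for pipeline-level tests (fast to build).
small_scenario <- function(seed = 11L) {
  cfg <- default_scenario(seed = seed)
  cfg$chrom_lengths <- c(chr1 = 200000L)
  cfg$n_sites <- 8L
  cfg$n_hairpins <- 3L
  cfg
}
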