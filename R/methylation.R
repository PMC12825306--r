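#' Cytosine methylation contexts
#' @format Character vector: CG, CHG, CHH (H = A, C or T).
#' @export
METHYLATION_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a per-cytosine methylation track
#'
#' `read_methylation_track()` reads a bedGraph-style track of methylation
#' levels in `[0, 1]` for one sequence context. `read_methylation_counts()`
#' reads a TSV of `chrom`, `pos` (1-based), `meth`, `total` read counts and
#' divides to levels. Records outside `[0, 1]` or with `total == 0` are
#' rejected at parse time.
#'
#' @param path File path.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return `GRanges` of width-1 cytosine positions with metadata columns
#'   `context` and `level`.
#' @export
read_methylation_track <- function(path, context) {
  context <- match.arg(context, METHYLATION_CONTEXTS)
  gr <- rtracklayer::import(path, format = "bedGraph")
  level <- gr$score
  if (any(is.na(level)) || any(level < 0 | level > 1))
    stop("methylation levels must lie in [0, 1]")
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::IRanges(BiocGenerics::start(gr),
                                                 width = 1L))
  S4Vectors::mcols(out)$context <- context
  S4Vectors::mcols(out)$level <- level
  out
}

#' @rdname read_methylation_track
#' @export
read_methylation_counts <- function(path, context) {
  context <- match.arg(context, METHYLATION_CONTEXTS)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% colnames(tab)))
  if (any(tab$total <= 0) || any(tab$meth < 0) || any(tab$meth > tab$total))
    stop("malformed methylation counts")
  out <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(tab$pos, width = 1L))
  S4Vectors::mcols(out)$context <- context
  S4Vectors::mcols(out)$level <- tab$meth / tab$total
  out
}

#' Mean methylation level per region and sequence context
#'
#' Unweighted mean of the levels of cytosines falling inside each region,
#' computed independently per context. A context with no covered cytosine
#' in a region yields `NA` (absence of data, never 0).
#'
#' @param records `GRanges` of cytosines with `context` and `level`
#'   metadata (concatenate the per-context tracks).
#' @param regions `GRanges` of regions.
#' @return `data.frame` in long format: `chrom`, `start`, `end`, `context`,
#'   `mean_level`, `n_cytosines` — one row per region x context.
#' @export
region_methylation_levels <- function(records, regions) {
  stopifnot(!is.null(records$context), !is.null(records$level))
  bad <- !(records$context %in% METHYLATION_CONTEXTS) |
    records$level < 0 | records$level > 1
  if (any(bad)) stop("malformed cytosine record(s)")
  hits <- GenomicRanges::findOverlaps(records, regions, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  rows <- expand.grid(region = seq_along(regions),
                      context = METHYLATION_CONTEXTS,
                      stringsAsFactors = FALSE)
  key_hits <- paste(s, records$context[q])
  key_rows <- paste(rows$region, rows$context)
  sums <- tapply(records$level[q], key_hits, sum)
  ns <- tapply(rep(1L, length(q)), key_hits, sum)
  n_cyt <- as.integer(ifelse(is.na(ns[key_rows]), 0L, ns[key_rows]))
  mean_level <- as.numeric(sums[key_rows]) / n_cyt
  mean_level[n_cyt == 0L] <- NA_real_
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(regions))[rows$region],
    start = BiocGenerics::start(regions)[rows$region],
    end = BiocGenerics::end(regions)[rows$region],
    context = rows$context, mean_level = mean_level,
    n_cytosines = n_cyt, row.names = NULL)
}
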