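#' Hairpin scan parameters
#'
#' Criteria for a pre-miRNA-like ungapped stem-loop: a stem of at least
#' `min_stem` paired columns allowing at most `max_mismatch` mismatched
#' columns, a loop of at least `min_loop` nt, and an overall span of at
#' most `max_span` nt. A stem column pairs the i-th base of the left arm
#' with the i-th base (from the 3' end) of the right arm; Watson-Crick
#' pairs and the G-U wobble count as matches, everything else (including
#' any `N`) as a mismatch. No bulges or internal-loop gaps are modelled.
#'
#' @param min_stem Minimum stem length in paired columns (default 25).
#' @param max_mismatch Maximum mismatched columns in the stem (default 10).
#' @param min_loop Minimum loop length in nt (default 3, the sterically
#'   minimal hairpin loop).
#' @param max_span Maximum end-to-end span in nt; `NULL` (default) means
#'   the whole sequence.
#' @param wobble Should G-U count as a pair (default `TRUE`, as in folded
#'   plant pre-miRNA stems)? With `FALSE` only Watson-Crick columns match.
#' @return List of class `hairpin_params`.
#' @export
hairpin_params <- function(min_stem = 25L, max_mismatch = 10L,
                           min_loop = 3L, max_span = NULL, wobble = TRUE) {
  min_stem <- as.integer(min_stem); max_mismatch <- as.integer(max_mismatch)
  min_loop <- as.integer(min_loop)
  if (min_stem <= 0L) stop("'min_stem' must be positive")
  if (max_mismatch < 0L) stop("'max_mismatch' must be >= 0")
  if (min_loop < 3L) stop("'min_loop' must be >= 3")
  structure(list(min_stem = min_stem, max_mismatch = max_mismatch,
                 min_loop = min_loop,
                 max_span = if (is.null(max_span)) NULL
                            else as.integer(max_span),
                 wobble = isTRUE(wobble)),
            class = "hairpin_params")
}

# TRUE where bases a, b (integer codes 1=A 2=C 3=G 4=T/U, 0=N/other) can
# pair: A-U, C-G, and optionally the G-U wobble.
.pair_ok <- function(a, b, wobble = TRUE) {
  wc <- (a == 1L & b == 4L) | (a == 4L & b == 1L) |
    (a == 2L & b == 3L) | (a == 3L & b == 2L)
  if (!wobble) return(wc)
  wc | (a == 3L & b == 4L) | (a == 4L & b == 3L)
}

.encode_seq <- function(seq) {
  x <- chartr("U", "T", toupper(as.character(seq)))
  match(strsplit(x, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"),
        nomatch = 0L)
}

#' Scan a sequence for pre-miRNA-like ungapped stem-loops
#'
#' Enumerates all maximal ungapped arm pairings meeting the
#' [hairpin_params()] criteria. Internally, every candidate hairpin lies on
#' one anti-diagonal of the base-pairing matrix (paired positions `p`, `q`
#' satisfy `p + q = const`); per anti-diagonal a two-pointer sweep finds
#' the maximal runs of columns with at most `max_mismatch` mismatches.
#' Each run is trimmed so the reported stem starts and ends on a paired
#' column, and candidates wholly contained in another candidate's arms
#' with no fewer mismatches are suppressed, so only maximal, non-dominated
#' stems are reported.
#'
#' @param seq Character scalar (or `DNAString`/`RNAString`) over
#'   A/C/G/T/U/N, case-insensitive.
#' @param params A [hairpin_params()] object.
#' @return `data.frame`, ordered by position, with 1-based inclusive
#'   in-sequence coordinates: `left_start`, `left_end`, `right_start`,
#'   `right_end`, `stem` (columns), `mismatches`, `loop` (nt). Sequences
#'   shorter than `2 * min_stem + min_loop` yield zero rows.
#' @examples
#' arm <- paste(rep("ACGUG", 6), collapse = "")
#' hp <- paste0(arm, "GCUAAGCU",
#'              as.character(Biostrings::reverseComplement(Biostrings::DNAString(
#'                chartr("U", "T", arm)))))
#' scan_hairpins(hp)
#' @export
scan_hairpins <- function(seq, params = hairpin_params()) {
  code <- .encode_seq(seq)
  n <- length(code)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      stem = integer(), mismatches = integer(),
                      loop = integer())
  if (n < 2L * params$min_stem + params$min_loop) {
    message("sequence of ", n, " nt shorter than the minimal hairpin; ",
            "no scan performed")
    return(empty)
  }
  max_span <- if (is.null(params$max_span)) n else min(params$max_span, n)
  K <- params$max_mismatch
  cand <- vector("list", 64L); nc <- 0L

  # 0-based positions p (left) and q = D - p (right); columns ordered
  # outermost (small p) to innermost.
  for (D in seq_len(2L * n - 3L)) {        # D = p + q, 1 .. 2n-3
    p_lo <- max(0L, D - (n - 1L))
    p_hi <- (D - params$min_loop - 1L) %/% 2L
    p_lo <- max(p_lo, as.integer(ceiling((D + 1L - max_span) / 2)))
    m <- p_hi - p_lo + 1L
    if (m < params$min_stem) next
    p <- p_lo:p_hi
    mm <- !.pair_ok(code[p + 1L], code[D - p + 1L],
                    wobble = params$wobble)  # mismatch indicator
    runs <- .maximal_runs(mm, K)
    if (length(runs$from) == 0L) next
    # a stem starts and ends on a paired column: trim terminal mismatches
    runs <- .trim_runs(runs, mm)
    ok <- runs$len >= params$min_stem
    if (!any(ok)) next
    keep <- which(ok)
    keep <- keep[!duplicated(cbind(runs$from[keep], runs$to[keep]))]
    p1 <- p_lo + runs$from[keep] - 1L; p2 <- p_lo + runs$to[keep] - 1L
    nc <- nc + 1L
    if (nc > length(cand)) cand <- c(cand, vector("list", length(cand)))
    cand[[nc]] <- list(
      left_start = p1 + 1L, left_end = p2 + 1L,
      right_start = D - p2 + 1L, right_end = D - p1 + 1L,
      stem = p2 - p1 + 1L, mismatches = runs$mm[keep],
      loop = rep.int(D, length(keep)) - 2L * p2 - 1L)
  }
  if (nc == 0L) return(empty)
  cand <- cand[seq_len(nc)]
  out <- data.frame(
    left_start = unlist(lapply(cand, `[[`, "left_start")),
    left_end = unlist(lapply(cand, `[[`, "left_end")),
    right_start = unlist(lapply(cand, `[[`, "right_start")),
    right_end = unlist(lapply(cand, `[[`, "right_end")),
    stem = unlist(lapply(cand, `[[`, "stem")),
    mismatches = unlist(lapply(cand, `[[`, "mismatches")),
    loop = unlist(lapply(cand, `[[`, "loop")))
  out <- .suppress_dominated(out)
  out <- out[order(out$left_start, out$right_start, out$stem), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximal windows (two-pointer) with at most K TRUE entries in `mm`:
# windows that cannot be extended on either side without exceeding K.
.maximal_runs <- function(mm, K) {
  n <- length(mm)
  from <- integer(0); to <- integer(0); nmm <- integer(0)
  i <- 1L; j <- 0L; bad <- 0L
  last_j <- 0L
  while (i <= n) {
    if (j < i - 1L) { j <- i - 1L; bad <- 0L }
    while (j < n && (bad + mm[j + 1L]) <= K) {
      j <- j + 1L; bad <- bad + mm[j]
    }
    # window [i, j] is right-maximal; it is left-maximal iff i == 1 or
    # extending left would exceed K
    if (j >= i && (i == 1L || bad + mm[i - 1L] > K) && j > last_j) {
      from <- c(from, i); to <- c(to, j); nmm <- c(nmm, bad)
      last_j <- j
    }
    if (i <= j) bad <- bad - mm[i]
    i <- i + 1L
  }
  list(from = from, to = to, len = to - from + 1L, mm = nmm)
}

# Shrink each run to its first/last matching column and recount
# mismatches (vectorized); runs left without any match are dropped.
.trim_runs <- function(runs, mm) {
  cmm <- c(0L, cumsum(mm))
  match_pos <- which(!mm)
  if (!length(match_pos))
    return(list(from = integer(), to = integer(), len = integer(),
                mm = integer()))
  fi <- findInterval(runs$from - 1L, match_pos) + 1L  # first match >= from
  ti <- findInterval(runs$to, match_pos)              # last match <= to
  ok <- fi <= ti
  f <- match_pos[fi[ok]]; t <- match_pos[ti[ok]]
  list(from = f, to = t, len = t - f + 1L, mm = cmm[t + 1L] - cmm[f])
}

# Drop candidates whose both arms are contained in another candidate's
# arms that has no more mismatches.
.suppress_dominated <- function(x) {
  n <- nrow(x)
  if (n <= 1L) return(x)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dom <- x$left_start <= x$left_start[i] & x$left_end >= x$left_end[i] &
      x$right_start <= x$right_start[i] & x$right_end >= x$right_end[i] &
      x$mismatches <= x$mismatches[i]
    dom[i] <- FALSE
    strict <- x$left_start < x$left_start[i] | x$left_end > x$left_end[i] |
      x$right_start < x$right_start[i] | x$right_end > x$right_end[i] |
      x$mismatches < x$mismatches[i]
    if (any(dom & strict)) keep[i] <- FALSE
  }
  x[keep, , drop = FALSE]
}

#' Does a sequence contain a pre-miRNA-like hairpin?
#'
#' @inheritParams scan_hairpins
#' @return `TRUE` iff [scan_hairpins()] reports at least one candidate.
#' @export
has_premirna_like_hairpin <- function(seq, params = hairpin_params()) {
  nrow(suppressMessages(scan_hairpins(seq, params))) > 0L
}

#' Sample random genomic regions with a matched length distribution
#'
#' Draws `n_sets` sets of random intervals whose sorted length multiset
#' equals `lengths` exactly, uniformly over the genome (chromosomes chosen
#' proportionally to placeable length) while avoiding `exclusions`. Used to
#' estimate the hairpin scanner's false-positive frequency on random
#' sequence of the same lengths as the binding sites.
#'
#' @param chrom_lengths Named vector of chromosome lengths, or a
#'   `DNAStringSet` genome (lengths taken from it).
#' @param lengths Integer vector: the length multiset to reproduce.
#' @param n_sets Number of control sets (default 1).
#' @param exclusions `GRanges` the controls must not overlap (default none).
#' @param seed Optional integer; when given, placement is reproducible and
#'   the caller's RNG state is left untouched.
#' @param max_tries Rejection-sampling attempts per interval (default 1000).
#' @return List of `n_sets` `GRanges`, each carrying the input lengths.
#' @export
sample_length_matched_controls <- function(chrom_lengths, lengths,
                                           n_sets = 1L,
                                           exclusions = GenomicRanges::GRanges(),
                                           seed = NULL, max_tries = 1000L) {
  if (methods::is(chrom_lengths, "DNAStringSet"))
    chrom_lengths <- stats::setNames(BiocGenerics::width(chrom_lengths),
                                     names(chrom_lengths))
  lengths <- sort(as.integer(lengths))
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (max(lengths) > max(chrom_lengths))
    stop("a requested length exceeds every chromosome")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  chroms <- names(chrom_lengths)
  lapply(seq_len(n_sets), function(si) {
    placed <- GenomicRanges::GRanges()
    for (L in lengths) {
      capacity <- pmax(as.numeric(chrom_lengths) - L + 1, 0)
      if (sum(capacity) == 0) stop("no chromosome can hold length ", L)
      done <- FALSE
      for (tr in seq_len(max_tries)) {
        ch <- sample(chroms, 1L, prob = capacity)
        s <- sample.int(as.integer(chrom_lengths[[ch]]) - L + 1L, 1L)
        gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, width = L),
                                     seqinfo = GenomeInfoDb::Seqinfo(chroms))
        if (length(exclusions) &&
            length(suppressWarnings(GenomicRanges::findOverlaps(
              gr, exclusions, ignore.strand = TRUE))))
          next
        placed <- c(placed, gr)
        done <- TRUE
        break
      }
      if (!done)
        stop("could not place a length-", L, " control after ", max_tries,
             " tries; exclusions too dense?")
    }
    sort(placed, ignore.strand = TRUE)
  })
}

#' Fraction of regions containing a pre-miRNA-like hairpin
#'
#' @param regions `GRanges` of regions.
#' @param genome Named `DNAStringSet` (or object accepted by
#'   [Biostrings::getSeq()]).
#' @param params [hairpin_params()].
#' @return Fraction in `[0, 1]` of regions for which
#'   [has_premirna_like_hairpin()] is `TRUE`.
#' @export
hairpin_fraction <- function(regions, genome, params = hairpin_params()) {
  if (length(regions) == 0L) stop("'regions' must be nonempty")
  seqs <- region_sequences(genome, regions)
  mean(vapply(seqs, has_premirna_like_hairpin, logical(1), params = params))
}

#' Extract region sequences from a genome
#'
#' @param genome Named `DNAStringSet` (one entry per chromosome) or any
#'   object supported by [Biostrings::getSeq()].
#' @param regions `GRanges`.
#' @return Character vector of sequences, one per region.
#' @export
region_sequences <- function(genome, regions) {
  if (methods::is(genome, "DNAStringSet")) {
    vapply(seq_along(regions), function(i) {
      ch <- as.character(GenomeInfoDb::seqnames(regions[i]))
      if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
      as.character(Biostrings::subseq(genome[[ch]],
                                      BiocGenerics::start(regions[i]),
                                      BiocGenerics::end(regions[i])))
    }, character(1))
  } else {
    as.character(Biostrings::getSeq(genome, regions))
  }
}
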