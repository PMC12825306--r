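#' Default synthetic scenario configuration
#'
#' The study conditions the generators emulate: a desk-scale 1-Mb genome, a
#' 3 IP vs 3 control RIP design with negative-binomial window counts
#' (variance `mu + alpha * mu^2`), 50 planted binding sites of 8-fold
#' enrichment confined to a 200-nt fragment-capture span, sRNA region
#' populations sitting at least 2x inside each classifier threshold,
#' planted 30-bp-stem hairpins, and plant-like context-structured
#' methylation baselines.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   from it so stages are individually reproducible.
#' @return Named list of scenario parameters.
#' @export
default_scenario <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 1000000L),
    gc = 0.36,                      # Arabidopsis-like GC content
    # RIP experiment
    n_ip = 3L, n_control = 3L,
    mu = 30,                        # background mean reads per 100-bp block
    dispersion = 0.1,               # NB alpha
    fold = 8,                       # planted IP fold change
    n_sites = 50L,
    capture_span = 200L,            # IP fragment span around a binding point
    read_length = 36L,              # trimmed short-read length, <= block
    # sRNA populations (per-category parameters, >= 2x inside thresholds)
    srna_region_width = 200L,
    # hairpin planting
    hairpin_stem = 30L, hairpin_mismatches = 5L, hairpin_loop = 8L,
    n_hairpins = 10L,
    # methylation
    meth_mean_ranges = list(CG = c(0.5, 0.9), CHG = c(0.2, 0.6),
                            CHH = c(0.05, 0.3)),
    meth_sd = 0.1)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Random non-overlapping placement of widths on the genome, avoiding
# `occupied`; returns a GRanges (stops if space runs out). Overlap checks
# run on plain integer vectors for speed.
.place_nonoverlapping <- function(chrom_lengths, widths,
                                  occupied = GenomicRanges::GRanges(),
                                  min_gap = 0L, max_tries = 2000L) {
  chroms <- names(chrom_lengths)
  occ <- lapply(chroms, function(ch) {
    sub <- occupied[as.character(GenomeInfoDb::seqnames(occupied)) == ch]
    list(start = BiocGenerics::start(sub), end = BiocGenerics::end(sub))
  })
  names(occ) <- chroms
  out_ch <- character(length(widths)); out_s <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    cap <- pmax(as.numeric(chrom_lengths) - w + 1, 0)
    if (sum(cap) == 0) stop("no chromosome can hold width ", w)
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      ch <- if (length(chroms) == 1L) chroms else sample(chroms, 1L,
                                                         prob = cap)
      s <- sample.int(as.integer(chrom_lengths[[ch]]) - w + 1L, 1L)
      e <- s + w - 1L
      o <- occ[[ch]]
      if (length(o$start) &&
          any(s - min_gap <= o$end & e + min_gap >= o$start))
        next
      occ[[ch]]$start <- c(o$start, s)
      occ[[ch]]$end <- c(o$end, e)
      out_ch[i] <- ch; out_s[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place a width-", w, " interval; genome too full")
  }
  GenomicRanges::GRanges(out_ch, IRanges::IRanges(out_s, width = widths))
}

#' Simulate a genome with annotations and planted hairpins
#'
#' Generates a random genome at the configured GC content, places
#' non-overlapping annotation records of every vocabulary category, and
#' splices planted hairpin sequences (perfect inverted repeats of the
#' configured stem length carrying the configured number of arm
#' substitutions) into recorded positions.
#'
#' @param config Scenario list from [default_scenario()].
#' @return List with `genome` (`DNAStringSet`), `annotations` (`GRanges`
#'   with `category`/`id`), and `hairpin_truth` (`GRanges` of the planted
#'   hairpin-bearing segments).
#' @export
simulate_genome_and_annotations <- function(config = default_scenario()) {
  .with_seed(config$seed * 7L + 11L, {
    chrom_lengths <- config$chrom_lengths
    genome <- Biostrings::DNAStringSet(vapply(
      as.integer(chrom_lengths), .random_dna, character(1), gc = config$gc))
    names(genome) <- names(chrom_lengths)

    cat_widths <- c(tRNA = 80L, rRNA = 1500L, snoRNA = 120L, snRNA = 150L,
                    miRNA_primary_transcript = 500L, inverted_repeat = 400L,
                    transposable_element = 1200L, pseudogene = 800L,
                    ncRNA = 300L, protein_coding_gene = 2000L)
    n_each <- 5L
    widths <- rep(cat_widths, each = n_each)
    ann <- .place_nonoverlapping(chrom_lengths, widths, min_gap = 100L)
    S4Vectors::mcols(ann)$category <- rep(names(cat_widths), each = n_each)
    S4Vectors::mcols(ann)$id <- paste0(rep(names(cat_widths), each = n_each),
                                       "_", rep(seq_len(n_each),
                                                length(cat_widths)))
    BiocGenerics::strand(ann) <- sample(c("+", "-"), length(ann),
                                        replace = TRUE)

    hp_len <- 2L * config$hairpin_stem + config$hairpin_loop
    hp <- .place_nonoverlapping(chrom_lengths, rep(hp_len, config$n_hairpins),
                                occupied = ann, min_gap = 100L)
    for (i in seq_along(hp)) {
      seqs <- .planted_hairpin_seq(config$hairpin_stem, config$hairpin_loop,
                                   config$hairpin_mismatches, config$gc)
      ch <- as.character(GenomeInfoDb::seqnames(hp[i]))
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]],
        IRanges::IRanges(BiocGenerics::start(hp[i]), width = hp_len),
        Biostrings::DNAString(seqs))
    }
    S4Vectors::mcols(hp)$id <- paste0("hairpin_", seq_along(hp))
    ord <- order(as.character(GenomeInfoDb::seqnames(ann)),
                 BiocGenerics::start(ann))
    list(genome = genome, annotations = ann[ord], hairpin_truth = sort(hp))
  })
}

# One hairpin sequence: left arm, loop, reverse complement of the arm with
# `n_sub` substitutions introduced in the right arm.
.planted_hairpin_seq <- function(stem, loop, n_sub, gc) {
  arm <- .random_dna(stem, gc)
  loop_seq <- .random_dna(loop, gc)
  right <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm)))
  if (n_sub > 0) {
    pos <- sample.int(stem, n_sub)
    rs <- strsplit(right, "", fixed = TRUE)[[1]]
    for (p in pos) {
      # replace with a base that cannot pair (incl. wobble) with its partner
      partner <- substr(arm, stem - p + 1L, stem - p + 1L)
      nopair <- switch(partner, A = c("A", "C", "G"), C = c("A", "C", "T"),
                       G = c("G", "A"), T = c("T", "C"))
      rs[p] <- sample(nopair, 1L)
    }
    right <- paste(rs, collapse = "")
  }
  paste0(arm, loop_seq, right)
}

#' Simulate a RIP experiment with planted binding sites
#'
#' Draws per-sample aligned reads whose per-window counts follow an NB
#' distribution with the configured background mean and dispersion. Reads
#' are generated in non-overlapping 50-nt blocks (the tiling step), each
#' receiving an NB count with mean `mu/2` and dispersion `2 * alpha` and
#' holding its reads entirely inside the block; every 100-nt window then
#' covers exactly two blocks, giving marginal window mean `mu` and
#' variance `mu + alpha * mu^2` uniformly across the half-overlapping
#' grid (adjacent windows share one block, as overlapping windows share
#' reads in real data). In IP samples, blocks inside the planted
#' capture-span fragments have their mean multiplied by the planted fold,
#' so windows over a planted site have expected fold `config$fold`.
#'
#' @param config Scenario list.
#' @param sites Optional pre-chosen planted-site `GRanges`; chosen at
#'   random (capture-span wide, block-aligned) when `NULL`.
#' @return List with `read_sets` (named list of `GRanges`), `groups`
#'   (character vector, `"IP"`/`"control"`), and `truth` (`GRanges` of
#'   planted sites with a `fold` column).
#' @export
simulate_rip_experiment <- function(config = default_scenario(),
                                    sites = NULL) {
  .with_seed(config$seed * 7L + 13L, {
    chrom_lengths <- config$chrom_lengths
    block <- 50L
    if (is.null(sites)) {
      n_blocks_per_site <- max(1L, config$capture_span %/% block)
      w <- n_blocks_per_site * block
      # keep the tail of the first chromosome free: it hosts the sRNA
      # generator's multimapper decoy positions
      tail_zone <- GenomicRanges::GRanges(
        names(chrom_lengths)[1],
        IRanges::IRanges(max(1L, as.integer(chrom_lengths[[1]]) - 25000L),
                         as.integer(chrom_lengths[[1]])))
      raw <- .place_nonoverlapping(chrom_lengths, rep(w, config$n_sites),
                                   occupied = tail_zone, min_gap = 600L)
      # align to block boundaries
      s <- (BiocGenerics::start(raw) - 1L) %/% block * block + 1L
      sites <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(raw),
                                      IRanges::IRanges(s, width = w))
      sites <- sort(sites, ignore.strand = TRUE)
    }
    S4Vectors::mcols(sites)$fold <- config$fold

    samples <- c(paste0("IP_", seq_len(config$n_ip)),
                 paste0("control_", seq_len(config$n_control)))
    groups <- rep(c("IP", "control"), c(config$n_ip, config$n_control))
    rl <- config$read_length
    read_sets <- stats::setNames(vector("list", length(samples)), samples)
    for (si in seq_along(samples)) {
      per_chrom <- lapply(names(chrom_lengths), function(ch) {
        L <- as.integer(chrom_lengths[[ch]])
        nb <- L %/% block
        mu_b <- rep(config$mu / 2, nb)
        if (groups[si] == "IP") {
          ssites <- sites[GenomeInfoDb::seqnames(sites) == ch]
          if (length(ssites)) {
            for (j in seq_along(ssites)) {
              b1 <- (BiocGenerics::start(ssites[j]) - 1L) %/% block + 1L
              b2 <- min(nb, (BiocGenerics::end(ssites[j]) - 1L) %/% block + 1L)
              mu_b[b1:b2] <- mu_b[b1:b2] * config$fold
            }
          }
        }
        cnt <- stats::rnbinom(nb, mu = mu_b,
                              size = 1 / (2 * config$dispersion))
        total <- sum(cnt)
        block_of <- rep.int(seq_len(nb), cnt)
        offs <- sample.int(block - rl + 1L, total, replace = TRUE)
        starts <- (block_of - 1L) * block + offs
        GenomicRanges::GRanges(ch, IRanges::IRanges(starts, width = rl))
      })
      gr <- do.call(c, per_chrom)
      GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
      GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_lengths)
      read_sets[[si]] <- sort(gr, ignore.strand = TRUE)
    }
    list(read_sets = read_sets, groups = groups, truth = sites)
  })
}

# Per-category sRNA generation parameters, each at least 2x inside the
# classifier thresholds (density 5, bias 4/10, dominance 0.4).
.srna_category_params <- function() {
  list(
    CAT0 = list(total = 4L,  dom = 1L,  minority = 2L,  n_seq = 4L,
                len = 24L, k = 2L),
    CAT1 = list(total = 42L, dom = 34L, minority = 2L,  n_seq = 5L,
                len = 21L, k = 2L),   # dominant sequence gets k = 1
    CAT2 = list(total = 45L, dom = 5L,  minority = 5L,  n_seq = 9L,
                len = 21L, k = 2L),
    CAT3 = list(total = 40L, dom = 4L,  minority = 20L, n_seq = 10L,
                len = 24L, k = 3L))
}

.check_srna_margins <- function(par, min_density = 5, sirna_bias = 4,
                                mirna_bias = 10, dominance = 0.4,
                                width = 200L, category = "CAT?") {
  dens <- 100 * par$total / width
  B <- if (par$minority == 0) Inf else
    (par$total - par$minority) / par$minority
  d <- par$dom / par$total
  ok <- switch(category,
    CAT0 = dens <= min_density / 2,
    CAT3 = dens >= 2 * min_density && B <= sirna_bias / 2,
    CAT2 = dens >= 2 * min_density && B >= 2 * sirna_bias &&
      B < mirna_bias && d <= dominance / 2,
    CAT1 = dens >= 2 * min_density && B >= 2 * mirna_bias &&
      d >= 2 * dominance,
    FALSE)
  if (!ok)
    stop("sRNA parameters for ", category,
         " are not >= 2x inside the classifier thresholds ",
         "(or fall in an undefined classifier gap)")
  invisible(TRUE)
}

#' Simulate small-RNA populations with known categories
#'
#' For each region and target category, emits collapsed sRNA reads with a
#' fixed total count, strand split, dominant-sequence fraction and mapping
#' multiplicity sitting at least 2x inside the corresponding classifier
#' thresholds (a generation parameter landing in a classifier gap is
#' refused). CAT1 regions always contain a uniquely mapping dominant
#' sequence. Multimapper decoy positions are placed on a reserved segment
#' at the far end of the first chromosome.
#'
#' @param config Scenario list.
#' @param regions `GRanges` of regions to populate.
#' @param categories Character vector (`"CAT0"`..`"CAT3"`), one per region.
#' @return List with `reads` (sRNA `GRanges` as in [read_srna_table()]) and
#'   `truth` (`data.frame` of region coordinates and true category).
#' @export
simulate_srna_reads <- function(config = default_scenario(), regions,
                                categories) {
  stopifnot(length(regions) == length(categories))
  pars <- .srna_category_params()
  stopifnot(all(categories %in% names(pars)))
  .with_seed(config$seed * 7L + 17L, {
    alphabet <- c("A", "C", "G", "T")
    decoy_chrom <- names(config$chrom_lengths)[1]
    decoy_end <- as.integer(config$chrom_lengths[[1]])
    seen <- new.env(parent = emptyenv())
    out <- list(); oi <- 0L
    for (i in seq_along(regions)) {
      par <- pars[[categories[i]]]
      .check_srna_margins(par, width = BiocGenerics::width(regions[i]),
                          category = categories[i])
      # integer counts: dominant + (n_seq - 1) filler sequences
      filler <- par$total - par$dom
      n_fill <- par$n_seq - 1L
      base <- filler %/% n_fill
      cnts <- c(par$dom, rep(base, n_fill))
      cnts[1L + seq_len(filler - base * n_fill)] <-
        cnts[1L + seq_len(filler - base * n_fill)] + 1L
      # strand: assign whole sequences to the minority strand until its
      # total count is reached (filler sequences first)
      strands <- rep("+", par$n_seq)
      need <- par$minority
      for (j in rev(seq_len(par$n_seq))) {
        if (need <= 0) break
        if (cnts[j] <= need) { strands[j] <- "-"; need <- need - cnts[j] }
      }
      ks <- rep(par$k, par$n_seq)
      if (categories[i] == "CAT1") ks[1] <- 1L
      seqs <- character(par$n_seq)
      for (j in seq_len(par$n_seq)) {   # globally distinct sequences
        repeat {
          sq <- paste(sample(alphabet, par$len, replace = TRUE),
                      collapse = "")
          if (is.null(seen[[sq]])) { seen[[sq]] <- TRUE; break }
        }
        seqs[j] <- sq
      }
      s0 <- BiocGenerics::start(regions[i])
      e0 <- BiocGenerics::end(regions[i]) - par$len + 1L
      pos <- sample(seq.int(s0, e0), par$n_seq, replace = TRUE)
      ch <- as.character(GenomeInfoDb::seqnames(regions[i]))
      for (j in seq_len(par$n_seq)) {
        oi <- oi + 1L
        ranges <- IRanges::IRanges(pos[j], width = par$len)
        grs <- GenomicRanges::GRanges(ch, ranges, strand = strands[j])
        if (ks[j] > 1L) {   # decoy positions outside all regions
          dpos <- decoy_end - (oi * 40L) - seq_len(ks[j] - 1L) * 36L
          grs <- c(grs, GenomicRanges::GRanges(
            decoy_chrom, IRanges::IRanges(dpos, width = par$len),
            strand = "+"))
        }
        S4Vectors::mcols(grs)$sequence <- seqs[j]
        S4Vectors::mcols(grs)$count <- cnts[j]
        S4Vectors::mcols(grs)$k <- ks[j]
        out[[oi]] <- grs
      }
    }
    reads <- do.call(c, out)
    truth <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(regions)),
      start = BiocGenerics::start(regions),
      end = BiocGenerics::end(regions), category = categories)
    list(reads = reads, truth = truth)
  })
}

#' Simulate per-cytosine methylation tracks over regions
#'
#' Locates plus-strand cytosines of the genome inside each region, assigns
#' their CG/CHG/CHH context from the local trinucleotide, draws a per-region
#' true mean per context from the configured ranges, and emits levels as a
#' Gaussian around that mean (sd `config$meth_sd`) clipped to `[0, 1]`.
#'
#' @param config Scenario list.
#' @param genome Named `DNAStringSet`.
#' @param regions `GRanges` of regions.
#' @return List with `records` (cytosine `GRanges` with `context`/`level`)
#'   and `truth` (`data.frame` of per-region per-context true means).
#' @export
simulate_methylation_tracks <- function(config = default_scenario(), genome,
                                        regions) {
  .with_seed(config$seed * 7L + 19L, {
    recs <- list(); truth <- list()
    for (i in seq_along(regions)) {
      ch <- as.character(GenomeInfoDb::seqnames(regions[i]))
      s <- BiocGenerics::start(regions[i]); e <- BiocGenerics::end(regions[i])
      seqv <- strsplit(as.character(
        Biostrings::subseq(genome[[ch]], s, min(e + 2L, length(genome[[ch]])))),
        "", fixed = TRUE)[[1]]
      limit <- e - s + 1L
      cpos <- which(seqv == "C")
      cpos <- cpos[cpos <= limit & cpos + 2L <= length(seqv)]
      if (!length(cpos)) next
      ctx <- ifelse(seqv[cpos + 1L] == "G", "CG",
                    ifelse(seqv[cpos + 2L] == "G", "CHG", "CHH"))
      means <- vapply(METHYLATION_CONTEXTS, function(cc) {
        r <- config$meth_mean_ranges[[cc]]
        stats::runif(1, r[1], r[2])
      }, numeric(1))
      level <- pmin(pmax(stats::rnorm(length(cpos), means[ctx],
                                      config$meth_sd), 0), 1)
      gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s + cpos - 1L,
                                                        width = 1L))
      S4Vectors::mcols(gr)$context <- ctx
      S4Vectors::mcols(gr)$level <- level
      recs[[length(recs) + 1L]] <- gr
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        context = METHYLATION_CONTEXTS,
        true_mean = unname(means), row.names = NULL)
    }
    list(records = if (length(recs)) do.call(c, recs)
                   else GenomicRanges::GRanges(),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame())
  })
}

# Plain BED6 emission (0-based half-open starts); much faster than a
# generic exporter for the read volumes the generator produces.
.write_bed <- function(gr, path, name = ".", score = 0L) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  writeLines(paste(as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   name, score, strand, sep = "\t"), path)
  invisible(path)
}

#' Write a complete synthetic scenario to disk
#'
#' Runs every generator and writes the file set the pipeline consumes:
#' genome FASTA, annotation GFF3, per-sample read BEDs, collapsed sRNA
#' table + positions BED, per-context methylation bedGraphs, and the truth
#' tables. All outputs are deterministic functions of `config$seed`.
#'
#' @param config Scenario list from [default_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory objects (`genome`, `truth_sites`, ...).
#' @export
simulate_scenario <- function(config = default_scenario(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))

  ga <- simulate_genome_and_annotations(config)
  Biostrings::writeXStringSet(ga$genome, p("genome.fa"))
  ann <- ga$annotations
  writeLines(c("##gff-version 3",
               paste(as.character(GenomeInfoDb::seqnames(ann)), "ripscan",
                     ann$category, BiocGenerics::start(ann),
                     BiocGenerics::end(ann), ".",
                     as.character(BiocGenerics::strand(ann)), ".",
                     paste0("ID=", ann$id), sep = "\t")),
             p("annotations.gff3"))

  rip <- simulate_rip_experiment(config)
  read_paths <- character(0)
  for (nm in names(rip$read_sets)) {
    path <- p("reads_", nm, ".bed")
    .write_bed(rip$read_sets[[nm]], path)
    read_paths[nm] <- path
  }
  truth_sites <- rip$truth
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(truth_sites)),
               start = BiocGenerics::start(truth_sites),
               end = BiocGenerics::end(truth_sites),
               fold = truth_sites$fold),
    p("truth_sites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # sRNA populations over the planted sites, cycling the four categories
  cats <- rep(c("CAT0", "CAT1", "CAT2", "CAT3"),
              length.out = length(truth_sites))
  srna <- simulate_srna_reads(config, truth_sites, cats)
  tab <- unique(data.frame(sequence = srna$reads$sequence,
                           count = srna$reads$count, k = srna$reads$k))
  utils::write.table(tab, p("srna_reads.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_bed(srna$reads, p("srna_positions.bed"),
             name = srna$reads$sequence)
  utils::write.table(srna$truth, p("truth_srna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  meth <- simulate_methylation_tracks(config, ga$genome, truth_sites)
  meth_paths <- character(0)
  for (cc in METHYLATION_CONTEXTS) {
    sub <- meth$records[meth$records$context == cc]
    path <- p("meth_", cc, ".bedGraph")
    writeLines(paste(as.character(GenomeInfoDb::seqnames(sub)),
                     BiocGenerics::start(sub) - 1L,
                     BiocGenerics::end(sub),
                     format(sub$level, digits = 15, trim = TRUE),
                     sep = "\t"), path)
    meth_paths[cc] <- path
  }
  utils::write.table(meth$truth, p("truth_methylation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(
    genome_fasta = p("genome.fa"), annotation_gff3 = p("annotations.gff3"),
    read_paths = read_paths, groups = rip$groups,
    srna_table = p("srna_reads.tsv"), srna_bed = p("srna_positions.bed"),
    meth_paths = meth_paths,
    truth_sites_path = p("truth_sites.tsv"),
    genome = ga$genome, annotations = ga$annotations,
    hairpin_truth = ga$hairpin_truth, truth_sites = truth_sites,
    srna_truth = srna$truth, meth_truth = meth$truth))
}
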