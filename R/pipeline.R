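#' Default pipeline parameters
#'
#' All stage parameters with their standard values: 100-bp windows with
#' 50-bp step, adjusted-p cutoff 0.05, minimum mean normalized IP count 50,
#' merge gap 200 nt (strict), sRNA classifier thresholds
#' (density 5 / 100 nt, strand bias 4 and 10, dominance 0.4), hairpin stem
#' 25 with at most 10 mismatches, metaprofile flank 500 nt, annotation
#' miRNA flank 100 nt.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_config <- function() {
  list(window = 100L, step = 50L,
       alpha = 0.05, min_ip_mean = 50, merge_gap = 200L,
       min_density = 5, sirna_bias = 4, mirna_bias = 10, dominance = 0.4,
       min_stem = 25L, max_mismatch = 10L, min_loop = 3L,
       flank = 500L, mirna_flank = 100L,
       n_control_sets = 1L,
       seed = 1L)
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key=value`); blank lines and lines
#' starting with `#` are ignored. Values that parse as numbers are
#' converted; comma-separated values become vectors. Keys override the
#' defaults of [default_pipeline_config()].
#'
#' @param path Config file path.
#' @return Named list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- default_pipeline_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

#' Run the full binding-site analysis pipeline
#'
#' Executes count, test, filter, merge, annotate, sRNA-classify, hairpin and
#' methylation stages in order over the supplied inputs and writes every
#' stage's table plus a machine-readable run manifest (parameters and input
#' checksums) to `out_dir`. When a truth-site table is supplied the called
#' sites are scored against it. Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param config List from [default_pipeline_config()] /
#'   [read_pipeline_config()], additionally carrying the input paths:
#'   `genome_fasta`, `annotation` (GFF3/BED), `reads_ip` and
#'   `reads_control` (character vectors of BED paths), optionally
#'   `srna_table` + `srna_bed`, `meth_CG`/`meth_CHG`/`meth_CHH`,
#'   `truth_sites` (TSV with chrom/start/end), and `out_dir`.
#' @return Invisibly, a list with the principal results: `results`
#'   (window table), `sites` (annotated `GRanges`), `category_summary`,
#'   `srna`, `hairpins` (per-site calls + fractions), `methylation`,
#'   `scores` (when truth given), and `files` (written paths).
#' @export
run_pipeline <- function(config) {
  required <- c("genome_fasta", "annotation", "reads_ip", "reads_control",
                "out_dir")
  for (key in required)
    if (is.null(config[[key]])) stop("config lacks required key '", key, "'")
  inputs <- c(config$genome_fasta, config$annotation,
              config$reads_ip, config$reads_control,
              config$srna_table, config$srna_bed,
              config$meth_CG, config$meth_CHG, config$meth_CHH,
              config$truth_sites)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  defaults <- default_pipeline_config()
  for (key in names(defaults))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, paste0(...))
  files <- character(0)
  log_stage <- function(stage, ...)
    message("[", stage, "] ", ...)

  log_stage("load", "reading genome and reads")
  genome <- Biostrings::readDNAStringSet(config$genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_lengths <- stats::setNames(BiocGenerics::width(genome),
                                   names(genome))
  read_sets <- c(
    stats::setNames(lapply(config$reads_ip, rtracklayer::import),
                    paste0("IP_", seq_along(config$reads_ip))),
    stats::setNames(lapply(config$reads_control, rtracklayer::import),
                    paste0("control_", seq_along(config$reads_control))))
  groups <- rep(c("IP", "control"),
                c(length(config$reads_ip), length(config$reads_control)))

  log_stage("count", "tiling genome and counting reads")
  windows <- tile_genome(chrom_lengths, config$window, config$step)
  se <- count_reads(read_sets, windows, mode = "any", groups = groups)

  log_stage("test", "normalizing and testing windows")
  results <- nb_two_group_test(se, groups = groups)
  utils::write.table(results, out("window_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["window_results"] <- out("window_results.tsv")

  log_stage("merge", "filtering and merging significant windows")
  sig <- call_significant_windows(results, alpha = config$alpha,
                                  min_ip_mean = config$min_ip_mean)
  sites <- merge_windows_into_sites(sig, max_gap = config$merge_gap)

  log_stage("annotate", length(sites), " site(s)")
  annotations <- read_annotation_set(config$annotation,
                                     mirna_flank = config$mirna_flank)
  sites <- assign_annotation(sites, annotations)
  summary_tab <- category_summary(sites)
  site_tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    start = BiocGenerics::start(sites), end = BiocGenerics::end(sites),
    width = BiocGenerics::width(sites),
    n_windows = sites$n_windows, min_padj = sites$min_padj,
    mean_ip = sites$mean_ip, category = sites$category,
    annotation_id = sites$annotation_id)
  utils::write.table(site_tab, out("sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["sites"] <- out("sites.tsv")
  if (length(sites)) {
    bed <- sites
    S4Vectors::mcols(bed) <- S4Vectors::DataFrame(
      name = paste0("site_", seq_along(sites)),
      score = pmin(-log10(pmax(sites$min_padj, 1e-350)), 1000))
    rtracklayer::export(bed, out("sites.bed"), format = "BED")
    files["sites_bed"] <- out("sites.bed")
  }
  utils::write.table(summary_tab, out("category_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["category_summary"] <- out("category_summary.tsv")

  srna_tab <- NULL
  if (!is.null(config$srna_table) && length(sites)) {
    log_stage("classify", "sRNA accumulation patterns")
    reads <- read_srna_table(config$srna_table, config$srna_bed)
    reads <- filter_srna_reads(reads)
    srna_tab <- classify_srna_regions(reads, sites,
                                      min_density = config$min_density,
                                      sirna_bias = config$sirna_bias,
                                      mirna_bias = config$mirna_bias,
                                      dominance = config$dominance)
    utils::write.table(srna_tab, out("srna_categories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["srna_categories"] <- out("srna_categories.tsv")
  }

  hairpins <- NULL
  if (length(sites)) {
    log_stage("hairpin", "scanning sites and length-matched controls")
    params <- hairpin_params(min_stem = config$min_stem,
                             max_mismatch = config$max_mismatch,
                             min_loop = config$min_loop)
    site_frac <- hairpin_fraction(sites, genome, params)
    controls <- sample_length_matched_controls(
      chrom_lengths, BiocGenerics::width(sites),
      n_sets = config$n_control_sets, exclusions = sites,
      seed = config$seed)
    ctrl_frac <- vapply(controls, hairpin_fraction, numeric(1),
                        genome = genome, params = params)
    hairpins <- list(site_fraction = site_frac,
                     control_fractions = ctrl_frac)
    utils::write.table(
      data.frame(set = c("sites", paste0("control_", seq_along(ctrl_frac))),
                 fraction = c(site_frac, ctrl_frac)),
      out("hairpin_fractions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    files["hairpin_fractions"] <- out("hairpin_fractions.tsv")
  }

  meth_tab <- NULL
  meth_keys <- paste0("meth_", METHYLATION_CONTEXTS)
  if (any(meth_keys %in% names(config)) && length(sites)) {
    log_stage("methylation", "aggregating per-context levels")
    recs <- list()
    for (cc in METHYLATION_CONTEXTS) {
      path <- config[[paste0("meth_", cc)]]
      if (!is.null(path))
        recs[[cc]] <- read_methylation_track(path, cc)
    }
    meth_tab <- region_methylation_levels(do.call(c, unname(recs)), sites)
    utils::write.table(meth_tab, out("methylation_levels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["methylation_levels"] <- out("methylation_levels.tsv")
  }

  scores <- NULL
  if (!is.null(config$truth_sites)) {
    log_stage("score", "comparing called sites with planted truth")
    tt <- utils::read.delim(config$truth_sites)
    truth <- GenomicRanges::GRanges(tt$chrom,
                                    IRanges::IRanges(tt$start, tt$end))
    scores <- score_sites(sites, truth)
    utils::write.table(
      data.frame(metric = names(scores), value = unlist(scores)),
      out("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files["scores"] <- out("scores.tsv")
  }

  log_stage("manifest", "writing run manifest")
  param_keys <- names(default_pipeline_config())
  manifest <- c(
    paste0("parameter\t", param_keys, "\t",
           vapply(config[param_keys], function(x)
             paste(x, collapse = ","), character(1))),
    paste0("input\t", inputs, "\t", unname(tools::md5sum(inputs))))
  writeLines(manifest, out("manifest.tsv"))
  files["manifest"] <- out("manifest.tsv")

  invisible(list(results = results, sites = sites,
                 category_summary = summary_tab, srna = srna_tab,
                 hairpins = hairpins, methylation = meth_tab,
                 scores = scores, files = files))
}

#' Score called sites against planted truth
#'
#' A planted site counts as recovered when any called site overlaps it;
#' a called site is a false discovery when it overlaps no planted site.
#'
#' @param called `GRanges` of called sites.
#' @param truth `GRanges` of planted sites.
#' @return List with `sensitivity`, `fdp` (false-discovery proportion,
#'   0 when nothing is called), `n_called`, `n_truth`.
#' @export
score_sites <- function(called, truth) {
  if (length(truth) == 0L) stop("'truth' must be nonempty")
  recovered <- GenomicRanges::countOverlaps(truth, called,
                                            ignore.strand = TRUE) > 0
  fp <- if (length(called))
    GenomicRanges::countOverlaps(called, truth, ignore.strand = TRUE) == 0
  else logical(0)
  list(sensitivity = mean(recovered),
       fdp = if (length(called)) mean(fp) else 0,
       n_called = length(called), n_truth = length(truth))
}
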