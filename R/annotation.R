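#' Annotation category vocabulary, in priority order
#'
#' The closed category vocabulary used to label binding sites. When several
#' annotation records overlap one site, the category earliest in this vector
#' wins; sites overlapping nothing are labelled `"intergenic"`.
#'
#' @format Character vector of 10 categories, highest priority first.
#' @export
ANNOTATION_PRIORITY <- c(
  "tRNA", "rRNA", "snoRNA", "snRNA", "miRNA_primary_transcript",
  "inverted_repeat", "transposable_element", "pseudogene", "ncRNA",
  "protein_coding_gene")

#' Load an annotation set from GFF3/BED with category mapping
#'
#' Reads annotation records and maps their feature types onto the closed
#' category vocabulary ([ANNOTATION_PRIORITY]). GFF3 coordinates are
#' converted by the reader; records whose mapped category is not in the
#' vocabulary raise an error. miRNA primary-transcript records are stored
#' pre-enlarged by `mirna_flank` nt up- and downstream, the convention used
#' before overlap comparison.
#'
#' @param path GFF3 (or BED with a `name` column holding the type) file.
#' @param type_map Named character vector mapping file feature types to
#'   vocabulary categories; types absent from the map are dropped. Defaults
#'   to the identity map over the vocabulary.
#' @param mirna_flank Flank applied to miRNA_primary_transcript records
#'   (default 100 nt).
#' @return `GRanges` with metadata columns `category` and `id`.
#' @export
read_annotation_set <- function(path,
                                type_map = stats::setNames(
                                  ANNOTATION_PRIORITY, ANNOTATION_PRIORITY),
                                mirna_flank = 100L) {
  gr <- rtracklayer::import(path)
  type <- if (!is.null(gr$type)) as.character(gr$type)
          else as.character(gr$name)
  id <- if (!is.null(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$name)) as.character(gr$name)
        else paste0("rec", seq_along(gr))
  keep <- type %in% names(type_map)
  gr <- gr[keep]
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = BiocGenerics::strand(gr))
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(gr)
  S4Vectors::mcols(out)$category <- unname(type_map[type[keep]])
  S4Vectors::mcols(out)$id <- id[keep]
  validate_annotation_set(out)
  prepare_annotations(out, mirna_flank = mirna_flank)
}

#' @rdname read_annotation_set
#' @param annotations `GRanges` with `category` (and optionally `id`)
#'   metadata columns.
#' @export
validate_annotation_set <- function(annotations) {
  cat <- S4Vectors::mcols(annotations)$category
  if (is.null(cat)) stop("annotations need a 'category' metadata column")
  bad <- setdiff(unique(cat), ANNOTATION_PRIORITY)
  if (length(bad))
    stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  invisible(annotations)
}

#' @rdname read_annotation_set
#' @export
prepare_annotations <- function(annotations, mirna_flank = 100L) {
  validate_annotation_set(annotations)
  is_mirna <- annotations$category == "miRNA_primary_transcript"
  if (any(is_mirna) && mirna_flank > 0L)
    annotations[is_mirna] <- enlarge_intervals(annotations[is_mirna],
                                               flank = mirna_flank)
  annotations
}

#' Assign one category per binding site by priority
#'
#' Each site is compared (any-overlap, >= 1 nt, strand-ignored) with the
#' annotation records; among overlapping records the category earliest in
#' [ANNOTATION_PRIORITY] wins, ties within a category broken by largest
#' overlap then leftmost record start. Sites overlapping no record are
#' `"intergenic"`.
#'
#' @param sites `GRanges` of binding sites.
#' @param annotations `GRanges` with `category`/`id` metadata (see
#'   [read_annotation_set()]); pass through [prepare_annotations()] first if
#'   miRNA records still need their flanks.
#' @return `sites` with added metadata columns `category` and `annotation_id`
#'   (empty string when intergenic).
#' @export
assign_annotation <- function(sites, annotations) {
  validate_annotation_set(annotations)
  category <- rep("intergenic", length(sites))
  ann_id <- rep("", length(sites))
  if (length(sites) && length(annotations)) {
    hits <- GenomicRanges::findOverlaps(sites, annotations,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ov <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(sites)[q], IRanges::ranges(annotations)[s]))
      rank <- match(annotations$category[s], ANNOTATION_PRIORITY)
      ord <- order(q, rank, -ov, BiocGenerics::start(annotations)[s])
      first <- ord[!duplicated(q[ord])]
      category[q[first]] <- annotations$category[s[first]]
      id <- annotations$id
      if (is.null(id)) id <- rep("", length(annotations))
      ann_id[q[first]] <- id[s[first]]
    }
  }
  S4Vectors::mcols(sites)$category <- category
  S4Vectors::mcols(sites)$annotation_id <- ann_id
  sites
}

#' Per-category counts and proportions of annotated sites
#'
#' @param sites `GRanges` (or data frame) carrying a `category` column, as
#'   produced by [assign_annotation()].
#' @return `data.frame` with `category`, `count`, `proportion` (summing to
#'   1), ordered by the priority vocabulary with `intergenic` last; empty
#'   input yields an empty frame.
#' @export
category_summary <- function(sites) {
  cat <- if (methods::is(sites, "GRanges")) S4Vectors::mcols(sites)$category
         else sites$category
  if (is.null(cat) || length(cat) == 0L)
    return(data.frame(category = character(), count = integer(),
                      proportion = numeric()))
  lev <- c(ANNOTATION_PRIORITY, "intergenic")
  tab <- table(factor(cat, levels = lev))
  tab <- tab[tab > 0]
  data.frame(category = names(tab), count = as.integer(tab),
             proportion = as.integer(tab) / length(cat),
             row.names = NULL)
}
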