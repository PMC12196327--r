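#' Remove overlapping miRNA precursors
#'
#' Among same-scaffold precursors overlapping by at least 1 nt (any strand),
#' the one with the highest read count is kept and the others dropped;
#' read-count ties go to the smaller start coordinate. Chains of overlaps
#' are resolved within each connected component by descending count: the
#' current best is kept, everything still overlapping it is dropped, and
#' the rule recurses on the remainder, so a miRNA overlapping nothing is
#' never removed.
#'
#' @param mirnas precursor [GenomicRanges::GRanges] with `read_count`.
#' @return `list(kept, dropped)`, both [GenomicRanges::GRanges].
#' @export
dropOverlapping <- function(mirnas) {
  if (length(mirnas) < 2L) return(list(kept = mirnas,
                                       dropped = mirnas[0]))
  o <- order(-mirnas$read_count, GenomicRanges::start(mirnas))
  keptIdx <- integer(0)
  for (i in o) {
    if (!length(keptIdx) ||
        !any(IRanges::overlapsAny(mirnas[i], mirnas[keptIdx],
                                  ignore.strand = TRUE)))
      keptIdx <- c(keptIdx, i)
  }
  keptIdx <- sort(keptIdx)
  list(kept = mirnas[keptIdx], dropped = mirnas[-keptIdx])
}

#' Classify the genomic context of miRNA precursors
#'
#' Assigns each precursor exactly one context by overlap (>= 1 nt,
#' strand-agnostic) with the annotation, using most-specific-first
#' precedence: `pseudogene` > `exonic` > `intronic` > `intergenic`.
#' Introns are derived as gene spans minus exon spans.
#'
#' @param mirnas precursor [GenomicRanges::GRanges] with a `name` column.
#' @param annotation annotation [GenomicRanges::GRanges] as from
#'   [readGff3()].
#' @return data.frame with columns `mirna` and `context` (factor over
#'   `pseudogene`, `exonic`, `intronic`, `intergenic`).
#' @export
classifyContext <- function(mirnas, annotation) {
  lv <- c("pseudogene", "exonic", "intronic", "intergenic")
  if (!length(mirnas))
    return(data.frame(mirna = character(),
                      context = factor(character(), levels = lv)))
  genes <- annotation[annotation$ftype == "gene"]
  exons <- annotation[annotation$ftype == "exon"]
  introns <- GenomicRanges::setdiff(genes, exons, ignore.strand = TRUE)
  pseudo <- annotation[annotation$ftype == "pseudogene"]
  ctx <- rep("intergenic", length(mirnas))
  ctx[IRanges::overlapsAny(mirnas, introns, ignore.strand = TRUE)] <-
    "intronic"
  ctx[IRanges::overlapsAny(mirnas, exons, ignore.strand = TRUE)] <- "exonic"
  ctx[IRanges::overlapsAny(mirnas, pseudo, ignore.strand = TRUE)] <-
    "pseudogene"
  data.frame(mirna = mirnas$name, context = factor(ctx, levels = lv))
}

#' Detect genomic miRNA clusters
#'
#' Single-linkage chaining per scaffold: precursors sorted by start are
#' chained while the gap to the previous precursor (next start minus
#' previous end, minus one — i.e. the number of nucleotides strictly
#' between them) is at most `maxGap`. Components with at least two members
#' are reported; strand is ignored. Clustered miRNA genes are frequently
#' co-transcribed from one promoter, which is why adjacency at this scale
#' is biologically meaningful.
#'
#' @param mirnas precursor [GenomicRanges::GRanges] with `name`
#'   (overlap-filtered; see [dropOverlapping()]).
#' @param maxGap largest gap (nt) joining two precursors into a cluster.
#' @return data.frame with one row per cluster: `cluster_id`, `scaffold`,
#'   `span_start`, `span_end`, `n_members`, `members`
#'   (comma-separated names in genomic order).
#' @export
findClusters <- function(mirnas, maxGap = 5000L) {
  empty <- data.frame(cluster_id = character(), scaffold = character(),
                      span_start = integer(), span_end = integer(),
                      n_members = integer(), members = character())
  if (length(mirnas) < 2L) return(empty)
  comp <- GenomicRanges::reduce(GenomicRanges::granges(mirnas),
                                min.gapwidth = maxGap + 1L,
                                ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(mirnas, comp, ignore.strand = TRUE)
  rows <- lapply(unique(S4Vectors::subjectHits(hits)), function(cl) {
    idx <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == cl]
    if (length(idx) < 2L) return(NULL)
    idx <- idx[order(GenomicRanges::start(mirnas)[idx])]
    data.frame(
      scaffold = as.character(GenomeInfoDb::seqnames(comp))[cl],
      span_start = min(GenomicRanges::start(mirnas)[idx]),
      span_end = max(GenomicRanges::end(mirnas)[idx]),
      n_members = length(idx),
      members = paste(mirnas$name[idx], collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$span_start), , drop = FALSE]
  out <- cbind(cluster_id = sprintf("cluster-%d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Count miRNAs per scaffold
#'
#' @param mirnas precursor [GenomicRanges::GRanges] (overlap-filtered).
#' @return data.frame (`scaffold`, `n_mirnas`) sorted by descending count.
#' @export
perScaffoldCounts <- function(mirnas) {
  if (!length(mirnas))
    return(data.frame(scaffold = character(), n_mirnas = integer()))
  tab <- table(as.character(GenomeInfoDb::seqnames(mirnas)))
  out <- data.frame(scaffold = names(tab), n_mirnas = as.integer(tab))
  out <- out[order(-out$n_mirnas, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
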