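#' Exact k-mer index of a genome
#'
#' Builds a plain lookup table from every k-mer to its plus-strand start
#' positions, scaffold by scaffold. This is the inspectable R-level
#' counterpart of the index [mapReads()] builds internally in C++; both obey
#' the same contract (k-mers never span scaffold boundaries, k-mers with
#' non-ACGT characters are skipped, minus-strand hits are found by looking
#' up the reverse complement of the query).
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character).
#' @param k k-mer size; at most the shortest read length considered (15).
#' @return a list with elements `k` and `positions`, the latter an
#'   environment mapping k-mer strings to data.frames
#'   (`scaffold`, `start` 1-based).
#' @export
kmerIndex <- function(genome, k = 10L) {
  if (k < 4L) .stopf("k must be >= 4")
  if (k > 15L) .stopf("k must be <= 15")
  seqs <- .asDNAChar(genome)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (sc in names(seqs)) {
    s <- seqs[[sc]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", kmers)
    for (i in which(ok)) {
      km <- kmers[i]
      cur <- if (exists(km, envir = env, inherits = FALSE))
        get(km, envir = env) else NULL
      assign(km, rbind(cur, data.frame(scaffold = sc, start = starts[i])),
             envir = env)
    }
  }
  list(k = as.integer(k), positions = env)
}

#' Map reads to a genome with at most one mismatch
#'
#' Ungapped seed-and-extend mapping: each read is seeded with its first and
#' last k-mer (on both strands), candidate loci are verified by Hamming
#' distance, and all loci attaining the minimum mismatch count (0 preferred
#' over 1) are reported. Reads with more than `maxHits` best loci are
#' discarded as multi-mappers. Minus-strand alignments are reported on the
#' plus-strand coordinate system; the read sequence equals the reverse
#' complement of the reference slice.
#'
#' For reads shorter than `2 * k` the seeds fall back to 7-mers so that the
#' two-seed pigeonhole guarantee (any single mismatch leaves at least one
#' seed exact) holds down to 15 nt reads.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or named character vector.
#' @param genome a named [Biostrings::DNAStringSet] (or named character).
#' @param k seed length for reads of length >= 2k.
#' @param maxMm maximum mismatches (0 or 1).
#' @param maxHits maximum number of best loci before a read is discarded.
#' @return a [GenomicRanges::GRanges] of alignments with metadata columns
#'   `read_id`, `read_seq` (read bases, reverse complement of the reference
#'   slice on the minus strand) and `n_mismatch`; the attribute `status` is
#'   a named integer vector per read (0 unmapped, 1 mapped, 2 discarded
#'   multi-mapper) and `nMapped` counts mapped reads.
#' @export
mapReads <- function(reads, genome, k = 10L, maxMm = 1L, maxHits = 5L) {
  if (k < 4L) .stopf("k must be >= 4")
  rseq <- toupper(.asDNAChar(reads))
  rid <- names(rseq)
  if (is.null(rid)) rid <- paste0("read", seq_along(rseq))
  gseq <- toupper(.asDNAChar(genome))
  res <- cpp_map_reads(unname(rseq), unname(gseq), as.integer(k), 7L,
                       as.integer(maxMm), as.integer(maxHits))
  scafNames <- names(gseq)
  gr <- GenomicRanges::GRanges(
    scafNames[res$scaf],
    IRanges::IRanges(res$start, res$end),
    strand = res$strand,
    read_id = rid[res$read],
    read_seq = rseq[res$read],
    n_mismatch = res$mm,
    seqinfo = GenomeInfoDb::Seqinfo(scafNames, nchar(gseq)))
  status <- stats::setNames(res$status, rid)
  attr(gr, "status") <- status
  attr(gr, "nMapped") <- sum(status == 1L)
  gr
}

#' Size and 5'-base profile of mapped reads
#'
#' Counts each mapped read once (multi-locus reads contribute a single
#' count) by read length and 5' base of the read sequence. Lengths outside
#' 15-35 nt are ignored. This is the standard small-RNA size-distribution
#' panel: miRNA-dominated libraries show a 22 nt peak with U as the most
#' frequent 5' base.
#'
#' @param alignments a [GenomicRanges::GRanges] from [mapReads()].
#' @return an integer matrix with rows `15..35` (read length) and columns
#'   `A`, `C`, `G`, `T`.
#' @export
profileMapped <- function(alignments) {
  lens <- 15:35
  m <- matrix(0L, nrow = length(lens), ncol = 4,
              dimnames = list(as.character(lens), c("A", "C", "G", "T")))
  if (!length(alignments)) return(m)
  df <- unique(data.frame(read_id = alignments$read_id,
                          seq = alignments$read_seq))
  len <- nchar(df$seq)
  b5 <- substr(df$seq, 1L, 1L)
  ok <- len >= 15L & len <= 35L & b5 %in% colnames(m)
  tab <- table(factor(len[ok], levels = lens),
               factor(b5[ok], levels = colnames(m)))
  m[] <- as.integer(tab)
  m
}
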