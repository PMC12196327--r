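#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that upper-cases
#' sequences and enforces the package's record contract: non-empty ids and
#' non-empty sequences.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id (first whitespace
#'   token of the header; the full header is kept in
#'   `metadata(x)$description`).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  if (any(!nzchar(ids)))
    .stopf("malformed FASTA header (empty id) at record %d",
           which(!nzchar(ids))[1])
  if (any(Biostrings::width(x) == 0L))
    .stopf("empty sequence at FASTA record '%s'",
           ids[which(Biostrings::width(x) == 0L)[1]])
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  S4Vectors::metadata(x)$description <- desc
  x
}

#' Write a FASTA file
#'
#' @param x a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read a FASTQ file of small-RNA reads
#'
#' Parses plain (or gzipped) 4-line FASTQ into a
#' [Biostrings::QualityScaledDNAStringSet] with Phred+33 qualities. Each
#' record is validated: the quality string must be exactly as long as the
#' sequence, and the violating record is named in the error.
#'
#' @param path path to a FASTQ file.
#' @return a [Biostrings::QualityScaledDNAStringSet] named by read id.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) .stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(character(0)),
      Biostrings::PhredQuality(character(0))))
  if (length(lines) %% 4L != 0L)
    .stopf("truncated FASTQ: %d lines is not a multiple of 4", length(lines))
  i <- seq(1L, length(lines), by = 4L)
  hd <- lines[i]
  sq <- toupper(lines[i + 1L])
  ql <- lines[i + 3L]
  if (any(substr(hd, 1L, 1L) != "@"))
    .stopf("malformed FASTQ header at line %d", i[which(substr(hd, 1, 1) != "@")[1]])
  ids <- sub("\\s.*$", "", substring(hd, 2L))
  bad <- nchar(sq) != nchar(ql)
  if (any(bad))
    .stopf("sequence/quality length mismatch at record '%s'", ids[which(bad)[1]])
  if (any(nchar(sq) == 0L))
    .stopf("empty read at record '%s'", ids[which(nchar(sq) == 0L)[1]])
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(sq), Biostrings::PhredQuality(ql))
  names(out) <- ids
  out
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads a named [Biostrings::QualityScaledDNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    out <- rbind(paste0("@", ids),
                 as.character(reads),
                 "+",
                 as.character(Biostrings::quality(reads)))
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Default GFF3 feature-type alias table
#'
#' Annotation dialects differ in how they spell non-coding RNA, repeat and
#' pseudogene features; this configurable table maps raw GFF3 `type` values
#' onto the five feature classes the pipeline reasons about (`gene`, `exon`,
#' `ncRNA`, `repeat`, `pseudogene`). Types absent from the table are skipped
#' with a warning by [readGff3()].
#'
#' @return named character vector: raw GFF3 type -> internal feature class.
#' @export
defaultFtypeAliases <- function() {
  c(gene = "gene", exon = "exon",
    ncRNA = "ncRNA", tRNA = "ncRNA", rRNA = "ncRNA", snoRNA = "ncRNA",
    snRNA = "ncRNA", miRNA = "ncRNA", lnc_RNA = "ncRNA",
    ncRNA_gene = "ncRNA", SRP_RNA = "ncRNA",
    repeat_region = "repeat", dispersed_repeat = "repeat",
    tandem_repeat = "repeat", transposable_element = "repeat",
    pseudogene = "pseudogene", pseudogenic_transcript = "pseudogene",
    processed_pseudogene = "pseudogene")
}

#' Read a genome annotation (GFF3)
#'
#' Imports a 9-column GFF3 via [rtracklayer::import.gff3()] and maps feature
#' types onto the internal five-class vocabulary through a configurable alias
#' table. Exons inherit their parent gene id.
#'
#' @param path path to a GFF3 file.
#' @param aliases named character vector mapping raw GFF3 types to one of
#'   `gene`, `exon`, `ncRNA`, `repeat`, `pseudogene`;
#'   see [defaultFtypeAliases()].
#' @return a [GenomicRanges::GRanges] with metadata columns `ftype` (factor
#'   over the five classes) and `gene_id` (parent gene for exons, own id for
#'   genes, `NA` otherwise).
#' @export
readGff3 <- function(path, aliases = defaultFtypeAliases()) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import.gff3(path),
                 error = function(e) .stopf("malformed GFF3 (%s): %s",
                                            path, conditionMessage(e)))
  rawType <- as.character(gr$type)
  known <- rawType %in% names(aliases)
  if (any(!known)) {
    warning(sprintf("skipping %d feature(s) of unaliased type(s): %s",
                    sum(!known),
                    paste(unique(rawType[!known]), collapse = ", ")),
            call. = FALSE)
    gr <- gr[known]
    rawType <- rawType[known]
  }
  ftype <- factor(unname(aliases[rawType]),
                  levels = c("gene", "exon", "ncRNA", "repeat", "pseudogene"))
  id <- if ("ID" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(S4Vectors::mcols(gr)))
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)) else rep(NA_character_, length(gr))
  geneId <- ifelse(ftype == "gene", id,
                   ifelse(ftype == "exon", parent, NA_character_))
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr),
    ftype = ftype, gene_id = geneId)
  names(out) <- NULL
  out
}

#' Write an annotation GRanges as GFF3
#'
#' Inverse of [readGff3()] for generator output: `ftype` becomes the GFF3
#' `type` column, `gene_id` the `ID` (genes) or `Parent` (exons) attribute.
#'
#' @param features a [GenomicRanges::GRanges] with `ftype` and `gene_id`
#'   metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(features, path) {
  gr <- features
  # emit canonical GFF3 feature types (the reader maps them back via the
  # alias table)
  gr$type <- c(gene = "gene", exon = "exon", ncRNA = "ncRNA",
               "repeat" = "repeat_region",
               pseudogene = "pseudogene")[as.character(gr$ftype)]
  gr$source <- "mirforge"
  gr$ID <- ifelse(gr$ftype == "gene", gr$gene_id,
                  ifelse(gr$ftype == "exon", NA_character_,
                         paste0(gr$type, "_", seq_along(gr))))
  gr$Parent <- ifelse(as.character(gr$ftype) == "exon", gr$gene_id,
                      NA_character_)
  gr$ftype <- NULL
  gr$gene_id <- NULL
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Internal 1-based closed intervals are converted to BED's 0-based half-open
#' convention at this file boundary (start shifts by -1, end is preserved).
#'
#' @param x a [GenomicRanges::GRanges]; names (or a `name` metadata column)
#'   populate BED column 4.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  gr <- GenomicRanges::granges(x)
  nm <- if (!is.null(names(x))) names(x)
        else if ("name" %in% names(S4Vectors::mcols(x))) x$name
        else rep(".", length(x))
  names(gr) <- NULL
  gr$name <- nm
  gr$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Write a table as TSV with header
#'
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [writeTsv()]
#'
#' @param path input path.
#' @return a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
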