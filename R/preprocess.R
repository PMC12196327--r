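#' Trim the 3' adapter from small-RNA reads
#'
#' Finds, for each read, the leftmost position at which a prefix of the
#' adapter aligns to the read suffix with a mismatch fraction of at most
#' `maxErrRate` and an overlap of at least `minOverlap` bases, and truncates
#' the read (and its quality string) before that position. Reads without an
#' adapter occurrence pass through unchanged; trimming never lengthens a
#' read and always returns a prefix of the input.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param adapter adapter sequence (DNA string).
#' @param minOverlap minimum adapter/read overlap in nt.
#' @param maxErrRate maximum mismatch fraction within the overlap.
#' @return a [Biostrings::QualityScaledDNAStringSet] of trimmed reads, plus
#'   an integer attribute `nTrimmed` counting reads that lost bases.
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 3L, maxErrRate = 0.1) {
  if (!nzchar(adapter)) .stopf("adapter must be non-empty")
  adapter <- toupper(adapter)
  keep <- cpp_trim_adapter(as.character(reads), adapter,
                           as.integer(minOverlap), maxErrRate)
  out <- IRanges::narrow(reads, start = 1L,
                         width = pmax(keep, 0L))
  attr(out, "nTrimmed") <- sum(keep < Biostrings::width(reads))
  out
}

#' Filter pre-processed reads
#'
#' Applies the standard small-RNA read filters: reads with mean Phred
#' quality below `minMeanQ`, reads containing an ambiguous base (N), and
#' reads shorter than `minLen` nt are removed, in that order of precedence
#' (a read failing several filters is tallied once, under the first). Order
#' of the surviving reads is preserved and filtering is idempotent.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (adapter-trimmed).
#' @param minLen minimum read length kept (inclusive).
#' @param minMeanQ minimum mean Phred quality kept (inclusive).
#' @return `list(reads, report)` where `report` is a one-row data.frame with
#'   columns `n_input`, `n_trimmed` (filled by [preprocessReads()]),
#'   `n_removed_quality`, `n_removed_ambiguous`, `n_removed_short`,
#'   `n_kept`.
#' @export
filterReads <- function(reads, minLen = 15L, minMeanQ = 20) {
  n <- length(reads)
  w <- Biostrings::width(reads)
  if (n) {
    qm <- vapply(as(Biostrings::quality(reads), "IntegerList"),
                 function(q) if (length(q)) mean(q) else 0,
                 numeric(1))
    hasN <- Biostrings::alphabetFrequency(reads)[, "N"] > 0L
  } else {
    qm <- numeric(0)
    hasN <- logical(0)
  }
  lowq <- qm < minMeanQ
  amb <- !lowq & hasN
  short <- !lowq & !amb & w < minLen
  keep <- !(lowq | amb | short)
  report <- data.frame(
    n_input = n,
    n_trimmed = NA_integer_,
    n_removed_quality = sum(lowq),
    n_removed_ambiguous = sum(amb),
    n_removed_short = sum(short),
    n_kept = sum(keep))
  list(reads = reads[keep], report = report)
}

#' Adapter-trim and filter a read set
#'
#' Convenience wrapper running [trimAdapter()] then [filterReads()] and
#' completing the preprocessing report.
#'
#' @inheritParams trimAdapter
#' @inheritParams filterReads
#' @return `list(reads, report)` as in [filterReads()], with `n_trimmed`
#'   filled in.
#' @export
preprocessReads <- function(reads, adapter, minOverlap = 3L,
                            maxErrRate = 0.1, minLen = 15L, minMeanQ = 20) {
  trimmed <- trimAdapter(reads, adapter, minOverlap, maxErrRate)
  out <- filterReads(trimmed, minLen, minMeanQ)
  out$report$n_trimmed <- attr(trimmed, "nTrimmed")
  out
}
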