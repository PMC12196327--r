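#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom data.table data.table := .N
#' @importFrom stats setNames
#' @useDynLib mirforge, .registration = TRUE
NULL

#' Simulation configuration
#'
#' Holds every tunable of the synthetic small-RNA study generator. The
#' defaults (see [simConfig()]) define the reference study conditions used
#' throughout the test suite: three 50 kb scaffolds, 40 planted pre-miRNA
#' hairpins whose mature arms dominate a 200,000-read pool with a 22 nt size
#' peak and a 5' U bias, plus 20 decoy loci engineered to fail curation.
#'
#' @slot seed integer; master seed, fixed seed gives byte-identical outputs.
#' @slot nScaffolds,scaffoldLen integer; genome shape.
#' @slot gcContent numeric; i.i.d. base composition of the simulated genome.
#' @slot nTrueMirnas,nDecoys integer; planted true and decoy locus counts.
#' @slot contextProportions named numeric; fractions of planted precursors per
#'   genomic context (`intronic`, `intergenic`, `exonic`, `pseudogene`),
#'   must sum to 1.
#' @slot abundanceAlpha numeric; Zipf exponent for per-miRNA expression.
#' @slot homogeneity5p numeric; fraction of a miRNA's reads sharing the modal
#'   5' end.
#' @slot frac5pU numeric; fraction of mature sequences starting with U (T).
#' @slot nMirnaReads,nBackgroundReads integer; read pool composition.
#' @slot adapter character; 3' adapter sequence appended to every read.
#' @slot fracLowq,fracAmbiguous numeric; fractions of reads given mean
#'   quality < 20 or one N.
#' @slot readLen integer; machine read length after adapter ligation.
#' @slot nClustered integer; planted miRNAs arranged as one close cluster.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer",
  nScaffolds = "integer",
  scaffoldLen = "integer",
  gcContent = "numeric",
  nTrueMirnas = "integer",
  nDecoys = "integer",
  contextProportions = "numeric",
  abundanceAlpha = "numeric",
  homogeneity5p = "numeric",
  frac5pU = "numeric",
  nMirnaReads = "integer",
  nBackgroundReads = "integer",
  adapter = "character",
  fracLowq = "numeric",
  fracAmbiguous = "numeric",
  readLen = "integer",
  nClustered = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@gcContent, object@homogeneity5p, object@frac5pU,
          object@fracLowq, object@fracAmbiguous)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must lie in [0, 1]")
  cp <- object@contextProportions
  if (!setequal(names(cp), c("intronic", "intergenic", "exonic", "pseudogene")))
    msg <- c(msg, "contextProportions must be named intronic/intergenic/exonic/pseudogene")
  if (abs(sum(cp) - 1) > 1e-9)
    msg <- c(msg, "contextProportions must sum to 1")
  if (any(cp < 0)) msg <- c(msg, "contextProportions must be non-negative")
  if (object@nScaffolds < 1L || object@scaffoldLen < 1000L)
    msg <- c(msg, "need >= 1 scaffold of >= 1000 nt")
  if (!grepl("^[ACGT]+$", object@adapter))
    msg <- c(msg, "adapter must be a non-empty ACGT string")
  if (length(msg)) msg else TRUE
})

#' RNA secondary structure from base-pair maximisation
#'
#' Result of folding a candidate precursor with the Nussinov dynamic program
#' (minimum hairpin loop 3, pairs over AU/GC/GU). Terminal loops are hairpin
#' loops: pairs enclosing no further pair.
#'
#' @slot seq character; the folded sequence (T treated as U).
#' @slot pairs two-column integer matrix of 1-based paired positions (i < j),
#'   nested (no pseudoknots).
#' @slot dotbracket character; dot-bracket rendering of `pairs`.
#' @slot nTerminalLoops integer; number of hairpin loops.
#' @slot pairedFraction numeric; `2 * nrow(pairs) / nchar(seq)`.
#' @slot score numeric; objective value of the fold (pair count for the
#'   default unit weights).
#' @exportClass HairpinStructure
setClass("HairpinStructure", representation(
  seq = "character",
  pairs = "matrix",
  dotbracket = "character",
  nTerminalLoops = "integer",
  pairedFraction = "numeric",
  score = "numeric"
))

setValidity("HairpinStructure", function(object) {
  msg <- character()
  p <- object@pairs
  n <- nchar(object@seq)
  if (nrow(p)) {
    if (any(p[, 2] - p[, 1] < 4)) msg <- c(msg, "minimum loop of 3 violated")
    if (any(p < 1) || any(p > n)) msg <- c(msg, "pair index out of range")
    if (anyDuplicated(as.vector(p))) msg <- c(msg, "a base pairs twice")
    # nestedness: no crossing pairs
    if (nrow(p) > 1) {
      o <- order(p[, 1])
      p <- p[o, , drop = FALSE]
      for (i in seq_len(nrow(p) - 1)) {
        later <- p[-seq_len(i), , drop = FALSE]
        cross <- later[, 1] < p[i, 2] & later[, 2] > p[i, 2]
        if (any(cross)) { msg <- c(msg, "crossing pairs (pseudoknot)"); break }
      }
    }
  }
  if (nchar(object@dotbracket) != n) msg <- c(msg, "dotbracket length mismatch")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HairpinStructure", function(object) {
  cat("HairpinStructure of", nchar(object@seq), "nt:",
      nrow(object@pairs), "pairs,",
      object@nTerminalLoops, "terminal loop(s), paired fraction",
      sprintf("%.2f", object@pairedFraction), "\n")
  cat(" ", object@seq, "\n ", object@dotbracket, "\n")
})

#' A candidate miRNA precursor with curation state
#'
#' One excised hairpin candidate: its genomic interval, sense-strand sequence,
#' fold, mature (and predicted star) placement, and the six curation criteria
#' with the three-of-six verdict. Offsets are 1-based positions in the
#' sense-oriented precursor sequence.
#'
#' @slot scaffold,start,end,strand genomic interval of the precursor
#'   (1-based closed coordinates, plus-strand coordinate system).
#' @slot seq character; precursor sequence, 5'->3' in transcript sense.
#' @slot structure [HairpinStructure-class] of `seq`.
#' @slot matureStart,matureLength integer; mature arm placement in `seq`.
#' @slot starStart,starLength integer; predicted star placement (NA if no
#'   plausible duplex).
#' @slot criteria named logical of length 6 (`c1`..`c6`); NA before
#'   [evaluateCriteria()].
#' @slot nMet integer; number of criteria met.
#' @slot verdict character; `"kept"`, `"discarded"` or `"unevaluated"`.
#' @exportClass HairpinCandidate
setClass("HairpinCandidate", representation(
  scaffold = "character",
  start = "integer",
  end = "integer",
  strand = "character",
  seq = "character",
  structure = "HairpinStructure",
  matureStart = "integer",
  matureLength = "integer",
  starStart = "integer",
  starLength = "integer",
  criteria = "logical",
  nMet = "integer",
  verdict = "character"
))

setValidity("HairpinCandidate", function(object) {
  msg <- character()
  n <- nchar(object@seq)
  if (object@end - object@start + 1L != n)
    msg <- c(msg, "interval width must equal precursor length")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (object@matureStart < 1L ||
      object@matureStart + object@matureLength - 1L > n)
    msg <- c(msg, "mature must lie within the precursor")
  if (length(object@criteria) != 6L ||
      !identical(names(object@criteria), paste0("c", 1:6)))
    msg <- c(msg, "criteria must be a named logical c1..c6")
  if (!object@verdict %in% c("kept", "discarded", "unevaluated"))
    msg <- c(msg, "bad verdict")
  if (object@verdict != "unevaluated") {
    if (object@nMet != sum(object@criteria))
      msg <- c(msg, "nMet must equal the number of TRUE criteria")
    want <- if (object@nMet >= 3L) "kept" else "discarded"
    if (object@verdict != want)
      msg <- c(msg, "verdict must be kept iff >= 3 criteria are met")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HairpinCandidate", function(object) {
  cat(sprintf("HairpinCandidate %s:%d-%d(%s), %d nt\n", object@scaffold,
              object@start, object@end, object@strand, nchar(object@seq)))
  cat(sprintf("  mature at %d..%d; star %s\n", object@matureStart,
              object@matureStart + object@matureLength - 1L,
              if (is.na(object@starStart)) "not predicted" else
                sprintf("at %d..%d", object@starStart,
                        object@starStart + object@starLength - 1L)))
  if (object@verdict == "unevaluated") {
    cat("  criteria not yet evaluated\n")
  } else {
    cat("  criteria:", paste(names(object@criteria)[object@criteria],
                             collapse = " "),
        sprintf("(%d/6) -> %s\n", object@nMet, object@verdict))
  }
})

#' @describeIn HairpinStructure-class dot-bracket string of the fold.
#' @param x a `HairpinStructure`.
#' @export
dotBracket <- function(x) x@dotbracket

#' @describeIn HairpinStructure-class two-column matrix of paired positions.
#' @export
basePairs <- function(x) x@pairs

#' @describeIn HairpinStructure-class number of terminal (hairpin) loops.
#' @export
nTerminalLoops <- function(x) x@nTerminalLoops

#' @describeIn HairpinStructure-class fraction of bases that are paired.
#' @export
pairedFraction <- function(x) x@pairedFraction

#' @describeIn HairpinCandidate-class named logical vector of the six
#'   curation criteria.
#' @param object a `HairpinCandidate`.
#' @export
criteria <- function(object) object@criteria

#' @describeIn HairpinCandidate-class curation verdict string.
#' @export
verdict <- function(object) object@verdict
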