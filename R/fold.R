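#' Fold a candidate precursor by base-pair maximisation
#'
#' Predicts a nested secondary structure with the Nussinov dynamic program:
#' the returned structure maximises the number of base pairs over AU, GC and
#' GU wobble pairs, with a minimum hairpin loop of 3 unpaired bases
#' (`j - i >= 4` for every pair). The traceback is deterministic and
#' stem-biased: at every subinterval the leftmost base is paired to its
#' largest admissible partner among score-optimal choices, so the many
#' degenerate optima of pair maximisation resolve to long nested stems
#' (hairpins) rather than branched local structures, matching how a
#' precursor fold is read. Base-pair maximisation is self-contained and
#' exactly checkable by enumeration; a free-energy backend could be swapped in
#' behind the same `HairpinStructure` contract.
#'
#' @param seq a DNA or RNA string (character or XString), 5-200 nt (below
#'   5 nt no pair can satisfy the minimum loop).
#' @param weights optional numeric of length 3, pair weights for
#'   `c(GC, AU, GU)`; the default `c(1, 1, 1)` maximises the raw pair count.
#' @param blocked optional integer vector of 1-based positions forbidden from
#'   pairing (used for site-accessibility scoring).
#' @return a [HairpinStructure-class].
#' @examples
#' foldHairpin("GGGAAACCC")
#' @export
foldHairpin <- function(seq, weights = c(1, 1, 1), blocked = integer(0)) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < 5L || n > 200L)
    .stopf("foldHairpin expects 5-200 nt, got %d", n)
  if (!grepl("^[ACGUTN]+$", seq))
    .stopf("foldHairpin: sequence contains non-ACGUTN characters")
  res <- cpp_nussinov(seq, weights[1], weights[2], weights[3],
                      as.integer(blocked))
  .structureFromPairs(seq, res$pairs, res$score)
}

# assemble a HairpinStructure from a pair list
.structureFromPairs <- function(seq, pairs, score) {
  n <- nchar(seq)
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  methods::new("HairpinStructure",
               seq = seq,
               pairs = pairs,
               dotbracket = paste(db, collapse = ""),
               nTerminalLoops = .countTerminalLoops(pairs),
               pairedFraction = if (n) 2 * nrow(pairs) / n else 0,
               score = as.numeric(score))
}

# hairpin loops: pairs that enclose no other pair
.countTerminalLoops <- function(pairs) {
  if (!nrow(pairs)) return(0L)
  n <- nrow(pairs)
  cnt <- 0L
  for (i in seq_len(n)) {
    inner <- pairs[, 1] > pairs[i, 1] & pairs[, 2] < pairs[i, 2]
    if (!any(inner)) cnt <- cnt + 1L
  }
  cnt
}

# weighted fold score only (no traceback object), used by the accessibility
# predictor; weights are c(GC, AU, GU)
.foldScore <- function(seq, weights, blocked = integer(0)) {
  res <- cpp_nussinov(toupper(as.character(seq)),
                      weights[1], weights[2], weights[3],
                      as.integer(blocked))
  res$score
}
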