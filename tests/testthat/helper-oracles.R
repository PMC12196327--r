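# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (enumeration / quadratic scans / third-party matchers)
# and never share code with the implementation they check.

# exhaustive enumeration of the maximum base-pair count over all nested
# structures with minimum loop 3 and pairs in {AU, GC, GU}; pure recursion,
# no DP table
enumMaxPairs <- function(seq) {
  b <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  canPair <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (canPair(b[i], b[k])) {
        inner <- if (i + 1L <= k - 1L) rec(i + 1L, k - 1L) else 0L
        outer <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  if (length(b) < 5L) 0L else rec(1L, length(b))
}

# all-positions/all-strands scan for <=1-mismatch loci via Biostrings
# matchPattern; returns a data.frame(scaffold, start, end, strand, mm)
# holding every locus at the minimum mismatch level
bruteMapOracle <- function(readSeq, genome, maxMm = 1L) {
  hits <- list()
  for (sc in names(genome)) {
    subj <- genome[[sc]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") readSeq else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(readSeq)))
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMm,
                                    with.indels = FALSE)
      if (length(m)) {
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                          starting.at = BiocGenerics::start(m))
        hits[[length(hits) + 1L]] <- data.frame(
          scaffold = sc, start = BiocGenerics::start(m),
          end = BiocGenerics::end(m), strand = strand, mm = mm)
      }
    }
  }
  if (!length(hits))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(), mm = integer()))
  df <- do.call(rbind, hits)
  df <- df[df$mm <= maxMm, , drop = FALSE]
  if (!nrow(df)) return(df)
  df[df$mm == min(df$mm), , drop = FALSE]
}

# quadratic transitive-closure clustering oracle: chain any two intervals on
# the same scaffold whose gap (bases strictly between) is <= maxGap, then
# report connected components with >= 2 members as sorted member-name strings
bruteClusterOracle <- function(df, maxGap = 5000L) {
  n <- nrow(df)
  if (n < 2L) return(character())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (df$scaffold[i] != df$scaffold[j]) next
      gap <- max(df$start[i], df$start[j]) -
        min(df$end[i], df$end[j]) - 1L
      if (gap <= maxGap) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- vapply(split(df$name, comp), function(m)
    paste(sort(m), collapse = ","), character(1))
  sort(unname(out[vapply(split(df$name, comp), length, integer(1)) >= 2L]))
}

# brute-force ungapped shift-and-count matcher (all offsets, no early exit),
# mirroring the conservation matcher's contract
bruteMatchOracle <- function(query, subject, maxMm = 2L, maxShift = 2L) {
  q <- strsplit(chartr("U", "T", toupper(query)), "")[[1]]
  s <- strsplit(chartr("U", "T", toupper(subject)), "")[[1]]
  L <- length(q)
  best <- Inf
  bestOff <- NA_integer_
  seedBest <- FALSE
  for (off in -maxShift:maxShift) {
    i1 <- max(1L, 1L - off)
    i2 <- min(L, length(s) - off)
    if (i2 - i1 + 1L < L - maxShift) next
    mm <- sum(q[i1:i2] != s[(i1 + off):(i2 + off)])
    seedId <- i1 <= 2L && i2 >= 8L && all(q[2:8] == s[2:8 + off])
    if (mm < best || (mm == best && abs(off) < abs(bestOff))) {
      best <- mm
      bestOff <- off
      seedBest <- seedId
    }
  }
  list(mm = best, offset = bestOff,
       matched = is.finite(best) &&
         (best <= maxMm || (seedBest && best <= 4L)))
}

# naive seed-site scan: check every UTR offset for the reverse complement of
# miRNA nt 2-7 by direct substring comparison
bruteSeedScan <- function(mir, utr) {
  mir <- chartr("U", "T", toupper(mir))
  core <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(mir, 2, 7))))
  n <- nchar(utr)
  which(vapply(seq_len(n - 5L), function(t)
    substr(utr, t, t + 5L) == core, logical(1)))
}

randomSeq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# quality-scaled read set from plain character vectors
makeReads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(out) <- if (!is.null(names(seqs))) names(seqs) else
    paste0("r", seq_along(seqs))
  out
}

# one-row stack GRanges as produced by callReadStacks, for direct
# evaluateCriteria tests
makeStack <- function(scaffold, start, end, strand, nReads, fivePrime,
                      lenHist, modalSeq = "", matureStart = start,
                      matureEnd = end) {
  gr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    n_reads = nReads, modal_seq = modalSeq,
    mature_start = matureStart, mature_end = matureEnd,
    five_prime = I(list(fivePrime)), len_hist = I(list(lenHist)))
  gr
}

# a clean constructed hairpin candidate of chosen precursor length
# (2 * matureLen + loopLen) built with the generator's duplex geometry;
# redraws the mature until the fold is a single stem-loop with a readable
# mature/star duplex
makeCandidate <- function(matureLen = 22L, loopLen = 16L, seed = 1L,
                          scaffold = "s1", start = 1001L, strand = "+") {
  set.seed(seed)
  for (try in 1:50) {
    mature <- paste0("T", randomSeq(matureLen - 3L),
                     randomSeq(2L, c("A", "C")))
    hp <- mirforge:::.buildHairpin(mature, loopLen, 0L)
    st <- foldHairpin(hp$prec)
    if (st@nTerminalLoops == 1L &&
        mirforge:::.predictStar(st, hp$matureStart, hp$matureLen)$ok)
      break
  }
  methods::new("HairpinCandidate",
               scaffold = scaffold, start = start,
               end = start + nchar(hp$prec) - 1L, strand = strand,
               seq = hp$prec, structure = st,
               matureStart = hp$matureStart, matureLength = hp$matureLen,
               starStart = NA_integer_, starLength = NA_integer_,
               criteria = stats::setNames(rep(NA, 6), paste0("c", 1:6)),
               nMet = NA_integer_, verdict = "unevaluated")
}

emptyAlignments <- function() {
  gr <- GenomicRanges::GRanges()
  gr$read_id <- character(0)
  gr$read_seq <- character(0)
  gr$n_mismatch <- integer(0)
  gr
}

emptyAnnotation <- function() {
  GenomicRanges::GRanges(
    ftype = factor(character(),
                   levels = c("gene", "exon", "ncRNA", "repeat",
                              "pseudogene")),
    gene_id = character())
}
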