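#' Call read stacks from alignments
#'
#' A read stack is a maximal run of overlapping same-strand alignments
#' (gaps of at most `mergeGap` nt are bridged) holding at least `minReads`
#' alignments — the raw evidence for an expressed small-RNA locus.
#'
#' @param alignments a [GenomicRanges::GRanges] from [mapReads()].
#' @param minReads minimum alignments per stack.
#' @param mergeGap largest gap (nt) bridged when merging alignments.
#' @return a [GenomicRanges::GRanges] of stack spans with metadata columns:
#'   `n_reads`, `modal_seq` (most frequent read sequence, ties resolved to
#'   the lexicographically smallest), `mature_start`/`mature_end` (most
#'   frequent alignment interval of the modal sequence), `five_prime` (list
#'   column: named counts of read 5' positions) and `len_hist` (list
#'   column: counts over read lengths 15-35).
#' @export
callReadStacks <- function(alignments, minReads = 5L, mergeGap = 0L) {
  empty <- GenomicRanges::GRanges(
    seqinfo = GenomeInfoDb::seqinfo(alignments))
  if (!length(alignments)) return(empty)
  regions <- GenomicRanges::reduce(alignments,
                                   min.gapwidth = mergeGap + 1L,
                                   ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(alignments, regions,
                                      ignore.strand = FALSE)
  dt <- data.table::data.table(
    stack = S4Vectors::subjectHits(hits),
    start = GenomicRanges::start(alignments)[S4Vectors::queryHits(hits)],
    end = GenomicRanges::end(alignments)[S4Vectors::queryHits(hits)],
    strand = as.character(BiocGenerics::strand(
      alignments))[S4Vectors::queryHits(hits)],
    seq = alignments$read_seq[S4Vectors::queryHits(hits)])
  dt[, five := ifelse(strand == "+", start, end)]
  dt[, len := end - start + 1L]
  nPer <- dt[, .N, by = stack]
  keep <- nPer[N >= minReads, stack]
  if (!length(keep)) return(empty)
  keep <- sort(keep)
  dt <- dt[stack %in% keep]

  lens <- 15:35
  per <- lapply(keep, function(s) {
    d <- dt[stack == s]
    fp <- table(d$five)
    lh <- table(factor(d$len[d$len >= 15 & d$len <= 35], levels = lens))
    seqTab <- sort(table(d$seq), decreasing = TRUE)
    top <- names(seqTab)[seqTab == max(seqTab)]
    modal <- sort(top)[1]
    dm <- d[seq == modal, .N, by = .(start, end)]
    dm <- dm[order(-N, start)]
    list(n = nrow(d), fp = stats::setNames(as.integer(fp), names(fp)),
         lh = stats::setNames(as.integer(lh), lens), modal = modal,
         ms = dm$start[1], me = dm$end[1])
  })
  out <- regions[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    n_reads = vapply(per, `[[`, integer(1), "n"),
    modal_seq = vapply(per, `[[`, character(1), "modal"),
    mature_start = vapply(per, `[[`, integer(1), "ms"),
    mature_end = vapply(per, `[[`, integer(1), "me"),
    five_prime = I(lapply(per, `[[`, "fp")),
    len_hist = I(lapply(per, `[[`, "lh")))
  out
}

# Predict the star arm from a fold and the mature placement, using the
# canonical Dicer geometry: the star is the region pairing with the mature,
# shifted to leave 2 nt 3' overhangs at both duplex ends. All coordinates
# are 1-based offsets in the sense-oriented precursor. Returns ok = FALSE
# when the structure offers no plausible duplex (mature insufficiently
# paired, partners on both arms, broken register, star out of bounds or
# colliding with the mature).
.predictStar <- function(structure, matureStart, matureLen) {
  fail <- list(ok = FALSE, starStart = NA_integer_, starEnd = NA_integer_)
  p <- structure@pairs
  if (!nrow(p)) return(fail)
  a <- matureStart
  b <- matureStart + matureLen - 1L
  n <- nchar(structure@seq)
  pos <- c(p[, 1], p[, 2])
  partner <- c(p[, 2], p[, 1])
  inM <- pos >= a & pos <= b
  mp <- pos[inM]
  mpart <- partner[inM]
  outside <- mpart < a | mpart > b
  mp <- mp[outside]
  mpart <- mpart[outside]
  if (length(mp) < 0.6 * matureLen) return(fail)
  # majority arm: a busy fold may pair a few mature bases into the flanks;
  # the duplex is read from the dominant side at a consistent antiparallel
  # register (pos + partner approximately constant)
  side <- mpart > b
  useUp <- sum(side) >= sum(!side)
  mp2 <- mp[side == useUp]
  mpart2 <- mpart[side == useUp]
  reg <- mp2 + mpart2
  keep <- abs(reg - stats::median(reg)) <= 4L
  mp2 <- mp2[keep]
  mpart2 <- mpart2[keep]
  if (length(mp2) < 0.6 * matureLen) return(fail)
  aP <- min(mp2); bP <- max(mp2)
  qa <- mpart2[which.min(mp2)]
  qb <- mpart2[which.max(mp2)]
  s1 <- qb - (b - bP) + 2L
  s2 <- qa + (aP - a) + 2L
  if (s1 > s2) return(fail)
  if (s1 < 1L || s2 > n) return(fail)
  starLen <- s2 - s1 + 1L
  if (starLen < matureLen - 4L || starLen > matureLen + 4L) return(fail)
  # disjoint from mature, with a loop of >= 3 nt in between
  if (s1 <= b + 3L && s2 >= a - 3L) {
    if (!(s2 < a - 3L || s1 > b + 3L)) return(fail)
  }
  list(ok = TRUE, starStart = as.integer(s1), starEnd = as.integer(s2))
}

#' Excise candidate precursors around read stacks
#'
#' For each stack two windows around the mature placement are extracted and
#' folded — one with the long flank upstream
#' (`[mature - flankLong, mature + flankShort]` in transcript sense) and one
#' with the long flank downstream — and the window with the higher paired
#' fraction wins (ties: fewer terminal loops, then the upstream window).
#' If the winning fold supports a mature/star duplex, the candidate is
#' trimmed to the mature..star span (the presumptive Drosha/Dicer product)
#' and refolded, so that the hairpin-length criterion is evaluated on the
#' precursor proper rather than on the excision window. Windows are clipped
#' at scaffold edges.
#'
#' @param stacks a [GenomicRanges::GRanges] from [callReadStacks()].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param flankLong,flankShort window flank sizes (nt).
#' @return a list of unevaluated [HairpinCandidate-class] objects, parallel
#'   to `stacks`.
#' @export
exciseCandidates <- function(stacks, genome, flankLong = 70L,
                             flankShort = 20L) {
  scafLens <- stats::setNames(Biostrings::width(genome), names(genome))
  lapply(seq_along(stacks), function(i) {
    sc <- as.character(GenomeInfoDb::seqnames(stacks))[i]
    strand <- as.character(BiocGenerics::strand(stacks))[i]
    ms <- stacks$mature_start[i]
    me <- stacks$mature_end[i]
    lim <- scafLens[[sc]]
    if (strand == "+") {
      wins <- list(c(ms - flankLong, me + flankShort),
                   c(ms - flankShort, me + flankLong))
    } else {
      wins <- list(c(ms - flankShort, me + flankLong),
                   c(ms - flankLong, me + flankShort))
    }
    wins <- lapply(wins, function(w) c(max(1L, w[1]), min(lim, w[2])))
    seqs <- vapply(wins, function(w)
      .senseSeq(genome, sc, w[1], w[2], strand), character(1))
    folds <- lapply(seqs, foldHairpin)
    mLen <- me - ms + 1L
    mOffs <- vapply(wins, function(w)
      if (strand == "+") ms - w[1] + 1L else w[2] - me + 1L, integer(1))
    stars <- lapply(1:2, function(k)
      .predictStar(folds[[k]], mOffs[k], mLen))
    # a window whose fold supports a mature/star duplex wins outright
    # (maximum pairing rewards random sequence, so raw paired fraction
    # cannot identify the hairpin-bearing window); paired fraction, then
    # terminal-loop count, then the upstream window break remaining ties
    ok <- vapply(stars, `[[`, logical(1), "ok")
    pick <- if (xor(ok[1], ok[2])) which(ok)
      else if (folds[[1]]@pairedFraction > folds[[2]]@pairedFraction) 1L
      else if (folds[[2]]@pairedFraction > folds[[1]]@pairedFraction) 2L
      else if (folds[[1]]@nTerminalLoops <= folds[[2]]@nTerminalLoops) 1L
      else 2L
    w <- wins[[pick]]
    fold <- folds[[pick]]
    seq <- seqs[[pick]]
    mOff <- mOffs[pick]
    star <- stars[[pick]]
    if (star$ok) {
      lo <- min(mOff, star$starStart)
      hi <- max(mOff + mLen - 1L, star$starEnd)
      if (strand == "+") {
        g1 <- w[1] + lo - 1L
        g2 <- w[1] + hi - 1L
      } else {
        g1 <- w[2] - hi + 1L
        g2 <- w[2] - lo + 1L
      }
      seq <- .senseSeq(genome, sc, g1, g2, strand)
      fold <- foldHairpin(seq)
      mOff <- mOff - lo + 1L
      star <- .predictStar(fold, mOff, mLen)
      w <- c(g1, g2)
    }
    methods::new("HairpinCandidate",
                 scaffold = sc, start = as.integer(w[1]),
                 end = as.integer(w[2]), strand = strand, seq = seq,
                 structure = fold, matureStart = as.integer(mOff),
                 matureLength = as.integer(mLen),
                 starStart = as.integer(star$starStart),
                 starLength = if (star$ok)
                   as.integer(star$starEnd - star$starStart + 1L)
                 else NA_integer_,
                 criteria = stats::setNames(rep(NA, 6), paste0("c", 1:6)),
                 nMet = NA_integer_, verdict = "unevaluated")
  })
}

#' Three-of-six curation verdict
#'
#' Pure decision rule over the six criteria flags: a candidate is kept iff
#' at least `minCriteria` flags are TRUE. Unevaluable criteria (NA) count
#' as not met. The rule is monotone: turning any flag from FALSE to TRUE
#' can never flip a kept candidate to discarded.
#'
#' @param flags logical vector of length 6 (`c1`..`c6`), NAs allowed.
#' @param minCriteria minimum number of criteria met.
#' @return `"kept"` or `"discarded"`.
#' @export
curationVerdict <- function(flags, minCriteria = 3L) {
  if (sum(flags, na.rm = TRUE) >= minCriteria) "kept" else "discarded"
}

#' Evaluate the six curation criteria on a candidate
#'
#' The criteria, evaluated with inclusive boundaries:
#' \describe{
#'   \item{c1}{hairpin-like fold: exactly one terminal loop and a paired
#'     fraction of at least 0.45;}
#'   \item{c2}{precursor length between 60 and 80 nt;}
#'   \item{c3}{a structure-predicted star whose duplex leaves 2-3 nt 3'
#'     overhangs, supported by at least one read whose 5' end lies within
#'     1 nt of the predicted star 5' end;}
#'   \item{c4}{at least 70% of the stack's reads share the modal 5' end;}
#'   \item{c5}{the stack's read-length histogram peaks between 20 and
#'     24 nt;}
#'   \item{c6}{no overlap (>= 1 nt) with annotated ncRNA or repeat
#'     features.}
#' }
#' The verdict is `"kept"` iff at least `minCriteria` (default 3) hold.
#'
#' @param candidate an unevaluated [HairpinCandidate-class].
#' @param stack the corresponding row of [callReadStacks()] output.
#' @param alignments alignments near the candidate (a superset is fine;
#'   same-strand reads overlapping the precursor are examined for star
#'   support).
#' @param annotation annotation [GenomicRanges::GRanges] as from
#'   [readGff3()].
#' @param minCriteria minimum criteria met for a kept verdict.
#' @return the evaluated [HairpinCandidate-class].
#' @export
evaluateCriteria <- function(candidate, stack, alignments, annotation,
                             minCriteria = 3L) {
  st <- candidate@structure
  c1 <- st@nTerminalLoops == 1L && st@pairedFraction >= 0.45
  n <- nchar(candidate@seq)
  c2 <- n >= 60L && n <= 80L
  fp <- stack$five_prime[[1]]
  c4 <- max(fp) / stack$n_reads >= 0.70
  lh <- stack$len_hist[[1]]
  peak <- as.integer(names(lh)[which.max(lh)])
  c5 <- sum(lh) > 0L && peak >= 20L && peak <= 24L
  bad <- annotation[annotation$ftype %in% c("ncRNA", "repeat")]
  cgr <- GenomicRanges::GRanges(candidate@scaffold,
                                IRanges::IRanges(candidate@start,
                                                 candidate@end))
  c6 <- !any(IRanges::overlapsAny(cgr, bad, ignore.strand = TRUE))

  c3 <- FALSE
  star <- .predictStar(st, candidate@matureStart, candidate@matureLength)
  if (star$ok) {
    star5g <- if (candidate@strand == "+")
      candidate@start + star$starStart - 1L
    else candidate@end - star$starStart + 1L
    near <- IRanges::subsetByOverlaps(
      alignments, cgr + 5L, ignore.strand = TRUE)
    near <- near[as.character(BiocGenerics::strand(near)) ==
                   candidate@strand]
    if (length(near)) {
      ends5 <- if (candidate@strand == "+") GenomicRanges::start(near)
               else GenomicRanges::end(near)
      c3 <- any(abs(ends5 - star5g) <= 1L)
    }
  }
  flags <- stats::setNames(c(c1, c2, c3, c4, c5, c6), paste0("c", 1:6))
  candidate@criteria <- flags
  candidate@nMet <- sum(flags)
  candidate@verdict <- curationVerdict(flags, minCriteria)
  if (star$ok) {
    candidate@starStart <- star$starStart
    candidate@starLength <- star$starEnd - star$starStart + 1L
  }
  methods::validObject(candidate)
  candidate
}

#' Summarise candidates as a table
#'
#' @param candidates list of [HairpinCandidate-class].
#' @return data.frame with interval, mature placement, criteria flags,
#'   `n_met` and `verdict` per candidate.
#' @export
candidateTable <- function(candidates) {
  if (!length(candidates))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), mature_start = integer(),
                      mature_len = integer(), c1 = logical(),
                      c2 = logical(), c3 = logical(), c4 = logical(),
                      c5 = logical(), c6 = logical(), n_met = integer(),
                      verdict = character()))
  do.call(rbind, lapply(candidates, function(x) {
    data.frame(scaffold = x@scaffold, start = x@start, end = x@end,
               strand = x@strand, length = nchar(x@seq),
               mature_start = x@matureStart, mature_len = x@matureLength,
               t(as.data.frame(x@criteria)), n_met = x@nMet,
               verdict = x@verdict, row.names = NULL)
  }))
}

#' Quantify curated mature miRNAs
#'
#' Counts, for each curated mature locus, the alignments on the same strand
#' overlapping it by at least (mature length - 2) nt. A read assignable to
#' two matures goes to the one with the larger overlap; exact ties are
#' dropped from all counts. Shares are percentages of total miRNA-assigned
#' reads and sum to 100; rpm normalises to the total mapped reads.
#'
#' @param mirnas precursor [GenomicRanges::GRanges] with metadata columns
#'   `name`, `mature_start`, `mature_end` (as built by [discoverMirnas()]).
#' @param alignments alignment [GenomicRanges::GRanges] from [mapReads()].
#' @param totalMapped total mapped read count (defaults to the number of
#'   distinct read ids in `alignments`).
#' @return `mirnas` with `read_count`, `rpm` and `share` metadata columns
#'   filled in.
#' @export
quantifyMirnas <- function(mirnas, alignments,
                           totalMapped = length(unique(alignments$read_id))) {
  if (!length(mirnas)) {
    mirnas$read_count <- integer(0)
    mirnas$rpm <- numeric(0)
    mirnas$share <- numeric(0)
    return(mirnas)
  }
  mat <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(mirnas),
    IRanges::IRanges(mirnas$mature_start, mirnas$mature_end),
    strand = BiocGenerics::strand(mirnas))
  need <- GenomicRanges::width(mat) - 2L
  hits <- GenomicRanges::findOverlaps(alignments, mat,
                                      ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(alignments)[q], GenomicRanges::ranges(mat)[s]))
  ok <- ow >= need[s]
  dt <- data.table::data.table(read = alignments$read_id[q][ok],
                               mir = s[ok], ow = ow[ok])
  counts <- integer(length(mirnas))
  if (nrow(dt)) {
    dt <- unique(dt)  # a read aligned twice to the same mature counts once
    best <- dt[, {
      m <- max(ow)
      w <- mir[ow == m]
      .(mir = if (length(unique(w)) == 1L) w[1] else NA_integer_)
    }, by = read]
    best <- best[!is.na(mir)]
    tab <- best[, .N, by = mir]
    counts[tab$mir] <- tab$N
  }
  mirnas$read_count <- counts
  mirnas$rpm <- counts * 1e6 / max(totalMapped, 1L)
  tot <- sum(counts)
  mirnas$share <- if (tot > 0) 100 * counts / tot else rep(0, length(counts))
  mirnas
}

#' Discover and curate miRNAs from alignments
#'
#' End-to-end discovery stage: call read stacks, excise and fold candidate
#' precursors, evaluate the six curation criteria, keep candidates meeting
#' at least `minCriteria`, name them in genomic order and quantify their
#' mature abundance.
#'
#' @inheritParams callReadStacks
#' @inheritParams exciseCandidates
#' @inheritParams evaluateCriteria
#' @param namePrefix prefix for assigned miRNA names (`<prefix>-1`, ...).
#' @return a list with `stacks`, `candidates` (all, evaluated),
#'   `mirnas` (kept precursors as [GenomicRanges::GRanges] with mature
#'   placement, sequence and quantification) and `table` (per-candidate
#'   criteria table).
#' @export
discoverMirnas <- function(alignments, genome, annotation, minReads = 5L,
                           mergeGap = 0L, flankLong = 70L, flankShort = 20L,
                           minCriteria = 3L, namePrefix = "mir") {
  stacks <- callReadStacks(alignments, minReads, mergeGap)
  candidates <- exciseCandidates(stacks, genome, flankLong, flankShort)
  if (length(candidates)) {
    cgr <- GenomicRanges::GRanges(
      vapply(candidates, methods::slot, character(1), "scaffold"),
      IRanges::IRanges(vapply(candidates, methods::slot, integer(1), "start"),
                       vapply(candidates, methods::slot, integer(1), "end")))
    fo <- GenomicRanges::findOverlaps(alignments, cgr + 5L,
                                      ignore.strand = TRUE)
    byCand <- split(S4Vectors::queryHits(fo), S4Vectors::subjectHits(fo))
    candidates <- lapply(seq_along(candidates), function(i) {
      idx <- byCand[[as.character(i)]]
      sub <- if (is.null(idx)) alignments[0] else alignments[idx]
      evaluateCriteria(candidates[[i]], stacks[i], sub, annotation,
                       minCriteria)
    })
  }
  keep <- vapply(candidates, verdict, character(1)) == "kept"
  kc <- candidates[keep]
  if (length(kc)) {
    mir <- GenomicRanges::GRanges(
      vapply(kc, methods::slot, character(1), "scaffold"),
      IRanges::IRanges(vapply(kc, methods::slot, integer(1), "start"),
                       vapply(kc, methods::slot, integer(1), "end")),
      strand = vapply(kc, methods::slot, character(1), "strand"),
      seqinfo = GenomeInfoDb::seqinfo(alignments))
    mOff <- vapply(kc, methods::slot, integer(1), "matureStart")
    mLen <- vapply(kc, methods::slot, integer(1), "matureLength")
    plus <- as.character(BiocGenerics::strand(mir)) == "+"
    mir$mature_start <- ifelse(plus,
                               GenomicRanges::start(mir) + mOff - 1L,
                               GenomicRanges::end(mir) - mOff - mLen + 2L)
    mir$mature_end <- mir$mature_start + mLen - 1L
    mir$mature_seq <- vapply(kc, function(x)
      substr(x@seq, x@matureStart, x@matureStart + x@matureLength - 1L),
      character(1))
    o <- order(as.factor(GenomeInfoDb::seqnames(mir)),
               GenomicRanges::start(mir))
    mir <- mir[o]
    mir$name <- sprintf("%s-%d", namePrefix, seq_along(mir))
    mir <- quantifyMirnas(mir, alignments)
  } else {
    mir <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(alignments))
    mir$mature_start <- integer(0)
    mir$mature_end <- integer(0)
    mir$mature_seq <- character(0)
    mir$name <- character(0)
    mir$read_count <- integer(0)
    mir$rpm <- numeric(0)
    mir$share <- numeric(0)
  }
  list(stacks = stacks, candidates = candidates, mirnas = mir,
       table = candidateTable(candidates))
}
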