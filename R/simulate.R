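#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class]. The defaults are the package's
#' reference study conditions: a three-scaffold 150 kb genome emulating a
#' fragmented insect assembly, 40 planted pre-miRNA hairpins and 20 decoy
#' loci, and a 200,000-read small-RNA pool (180k miRNA-derived, 20k
#' background/decoy) whose miRNA reads peak at 22 nt with a 5' U bias and a
#' Zipf abundance law whose rank-1 share is about 42%.
#'
#' @param seed master seed; every derived stream stays below 2^31.
#' @param nScaffolds,scaffoldLen genome shape (count, nt).
#' @param gcContent genome GC fraction.
#' @param nTrueMirnas,nDecoys planted locus counts.
#' @param contextProportions named fractions over
#'   `intronic`/`intergenic`/`exonic`/`pseudogene`; must sum to 1.
#' @param abundanceAlpha Zipf exponent of miRNA expression; 1.47 puts the
#'   analytic rank-1 share near 42% for 40 miRNAs.
#' @param homogeneity5p fraction of a miRNA's reads sharing the modal 5' end.
#' @param frac5pU fraction of mature sequences starting with U (T in DNA).
#' @param nMirnaReads,nBackgroundReads read-pool composition; decoy reads are
#'   drawn from the background budget.
#' @param adapter 3' adapter ligated to every read.
#' @param fracLowq,fracAmbiguous fractions of reads degraded to mean
#'   quality < 20 or given one N in the insert.
#' @param readLen machine read length.
#' @param nClustered number of planted miRNAs laid out as one sub-5 kb
#'   genomic cluster (capped at the intergenic quota).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nScaffolds = 3L, scaffoldLen = 50000L,
                      gcContent = 0.38, nTrueMirnas = 40L, nDecoys = 20L,
                      contextProportions = c(intronic = 0.50,
                                             intergenic = 0.38,
                                             exonic = 0.11,
                                             pseudogene = 0.01),
                      abundanceAlpha = 1.47, homogeneity5p = 0.9,
                      frac5pU = 0.9, nMirnaReads = 180000L,
                      nBackgroundReads = 20000L,
                      adapter = "AGATCGGAAGAGC", fracLowq = 0.02,
                      fracAmbiguous = 0.02, readLen = 50L,
                      nClustered = 6L) {
  methods::new("SimConfig",
    seed = as.integer(seed), nScaffolds = as.integer(nScaffolds),
    scaffoldLen = as.integer(scaffoldLen), gcContent = gcContent,
    nTrueMirnas = as.integer(nTrueMirnas), nDecoys = as.integer(nDecoys),
    contextProportions = contextProportions,
    abundanceAlpha = abundanceAlpha, homogeneity5p = homogeneity5p,
    frac5pU = frac5pU, nMirnaReads = as.integer(nMirnaReads),
    nBackgroundReads = as.integer(nBackgroundReads), adapter = adapter,
    fracLowq = fracLowq, fracAmbiguous = fracAmbiguous,
    readLen = as.integer(readLen), nClustered = as.integer(nClustered))
}

# integer apportionment by largest remainder; remainder ties favour
# categories that would otherwise get zero, so every positive proportion is
# represented when n allows
.apportion <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(round(raw - base, 9), base == 0, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}

.randSeq <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# weakly pairable sequence: A/C only cannot form AU/GC/GU pairs with itself
.randSeqAC <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")

#' Simulate a genome with annotation
#'
#' Generates `nScaffolds` scaffolds of i.i.d. bases at the configured GC
#' content and lays down non-overlapping gene models (three exons, two
#' introns each) plus scattered ncRNA, repeat and pseudogene features in the
#' intergenic space. The tail of each scaffold is left as a long intergenic
#' stretch so clustered loci can be planted later. Deterministic under the
#' config seed.
#'
#' @param cfg a [SimConfig-class].
#' @return `list(genome = DNAStringSet, annotation = GRanges)`; the
#'   annotation carries `ftype` and `gene_id` metadata columns as produced by
#'   [readGff3()].
#' @export
simulateGenome <- function(cfg) {
  methods::validObject(cfg)
  set.seed(.subSeed(cfg@seed, 1L))
  len <- cfg@scaffoldLen
  nGenes <- max(1L, len %/% 6000L)
  nNc <- max(1L, len %/% 16000L)
  nRep <- max(2L, len %/% 12000L)
  nPseudo <- max(1L, len %/% 25000L)
  scafNames <- sprintf("scaffold_%d", seq_len(cfg@nScaffolds))
  genome <- Biostrings::DNAStringSet(vapply(
    scafNames, function(s) .randSeq(len, cfg@gcContent), character(1)))
  names(genome) <- scafNames

  feats <- list()
  geneCounter <- 0L
  for (sc in scafNames) {
    queue <- sample(c(rep("gene", nGenes), rep("ncRNA", nNc),
                      rep("repeat", nRep), rep("pseudogene", nPseudo)))
    pos <- 1L
    for (ft in queue) {
      pos <- pos + sample(500:1500, 1)
      if (ft == "gene") {
        exLen <- sample(250:350, 3, replace = TRUE)
        inLen <- sample(800:1200, 2, replace = TRUE)
        gl <- sum(exLen) + sum(inLen)
        if (pos + gl > len - 200L)
          .stopf("scaffold too short (%d nt) to host the requested features",
                 len)
        geneCounter <- geneCounter + 1L
        gid <- sprintf("gene%04d", geneCounter)
        strand <- sample(c("+", "-"), 1)
        e1 <- c(pos, pos + exLen[1] - 1L)
        e2 <- c(e1[2] + inLen[1] + 1L, e1[2] + inLen[1] + exLen[2])
        e3 <- c(e2[2] + inLen[2] + 1L, e2[2] + inLen[2] + exLen[3])
        feats[[length(feats) + 1L]] <- data.frame(
          scaffold = sc,
          start = c(pos, e1[1], e2[1], e3[1]),
          end = c(e3[2], e1[2], e2[2], e3[2]),
          strand = strand,
          ftype = c("gene", "exon", "exon", "exon"),
          gene_id = gid)
        pos <- e3[2] + 1L
      } else {
        fl <- switch(ft, ncRNA = 120L, "repeat" = 250L, pseudogene = 300L)
        if (pos + fl > len - 200L)
          .stopf("scaffold too short (%d nt) to host the requested features",
                 len)
        feats[[length(feats) + 1L]] <- data.frame(
          scaffold = sc, start = pos, end = pos + fl - 1L,
          strand = "+", ftype = ft, gene_id = NA_character_)
        pos <- pos + fl
      }
    }
  }
  fd <- do.call(rbind, feats)
  annotation <- GenomicRanges::GRanges(
    fd$scaffold, IRanges::IRanges(fd$start, fd$end), strand = fd$strand,
    ftype = factor(fd$ftype,
                   levels = c("gene", "exon", "ncRNA", "repeat",
                              "pseudogene")),
    gene_id = fd$gene_id,
    seqinfo = GenomeInfoDb::Seqinfo(scafNames, rep(len, length(scafNames))))
  list(genome = genome, annotation = annotation)
}

# -- hairpin construction ----------------------------------------------------

# Build a precursor around a mature arm: mature + loop + star, where the star
# is the reverse complement of mature[1..L-2] (optionally with injected
# mutations) followed by a 2 nt 3' overhang. The loop and overhang are drawn
# from {A, C} so they cannot extend the stem; together with the A/C mature
# tail this also keeps the reverse complement of the star region two
# mismatches away from the mature read, so mapping stays unambiguous.
.buildHairpin <- function(mature, loopLen, nMut) {
  L <- nchar(mature)
  mb <- strsplit(mature, "")[[1]]
  loop <- .randSeqAC(loopLen)
  starBody <- strsplit(.revcomp(substr(mature, 1L, L - 2L)), "")[[1]]
  # mutations stay in the middle of the star body so the duplex keeps >= 5
  # intact closing pairs at both ends (mismatch bulges near the loop would
  # let loop bases re-pair and split the terminal loop)
  if (nMut > 0 && L >= 15L) {
    at <- sample(6:(L - 8L), nMut)
    for (p in at) starBody[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                starBody[p]), 1)
  }
  # overhang bases must not pair the mature 5' end (positions 1-2): the
  # stem-biased traceback would otherwise pair them as the outermost pair
  # and shift the inferred star beyond the precursor end. When both A and C
  # are excluded (mature starts TG/GT) the draw is left to the caller's
  # rejection loop.
  bad <- c(T = "A", G = "C")[c(mb[1], mb[2])]
  pool <- setdiff(c("A", "C"), bad[!is.na(bad)])
  if (!length(pool)) pool <- c("A", "C")
  o1 <- sample(pool, 1)
  o2 <- sample(pool, 1)
  star <- paste0(paste(starBody, collapse = ""), o1, o2)
  list(prec = paste0(mature, loop, star),
       matureStart = 1L, matureLen = L,
       starStart = L + loopLen + 1L, starLen = nchar(star))
}

# eligible placement spans per context, shrunk by a safety margin wider than
# the excision flank (70 nt), so even an untrimmed candidate window cannot
# leak into a neighbouring feature and confuse context classification
.contextSpans <- function(annotation, scafLens, margin = 75L) {
  genes <- annotation[annotation$ftype == "gene"]
  exons <- annotation[annotation$ftype == "exon"]
  all <- GenomicRanges::reduce(annotation, ignore.strand = TRUE)
  whole <- GenomicRanges::GRanges(names(scafLens),
                                  IRanges::IRanges(1L, unname(scafLens)))
  spans <- list(
    intronic = GenomicRanges::setdiff(genes, exons, ignore.strand = TRUE),
    intergenic = GenomicRanges::setdiff(whole, all, ignore.strand = TRUE),
    exonic = GenomicRanges::reduce(exons, ignore.strand = TRUE),
    pseudogene = GenomicRanges::reduce(
      annotation[annotation$ftype == "pseudogene"], ignore.strand = TRUE),
    repeat_nc = GenomicRanges::reduce(
      annotation[annotation$ftype %in% c("repeat", "ncRNA")],
      ignore.strand = TRUE))
  mapply(function(g, m) {
    g <- g[GenomicRanges::width(g) > 2 * m]
    GenomicRanges::resize(g, GenomicRanges::width(g) - 2L * m,
                          fix = "center")
  }, spans,
  # decoys planted in repeats only need to stay inside the feature (c6 is
  # strand- and extent-agnostic), so that class keeps a nominal margin
  c(rep(margin, 4), 12L))
}

# choose a start position for a locus of length n inside `spans`, avoiding
# `occupied` (with separation); returns c(scaffold, start) or NULL
.placeLocus <- function(spans, n, occupied, sep = 150L) {
  ok <- spans[GenomicRanges::width(spans) >= n]
  if (!length(ok)) return(NULL)
  for (try in 1:200) {
    i <- sample(length(ok), 1)
    sp <- ok[i]
    start <- GenomicRanges::start(sp) +
      sample.int(GenomicRanges::width(sp) - n + 1L, 1) - 1L
    cand <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(sp),
                                   IRanges::IRanges(start, start + n - 1L))
    if (length(occupied) == 0L ||
        !any(IRanges::overlapsAny(cand + sep, occupied)))
      return(list(scaffold = as.character(GenomeInfoDb::seqnames(sp)),
                  start = start))
  }
  NULL
}

#' Plant miRNA hairpins and decoy loci into a simulated genome
#'
#' Overwrites genome sequence with constructed pre-miRNA hairpins whose
#' contexts follow `contextProportions`, including one sub-5 kb cluster of
#' `nClustered` members in an intergenic tail. Three decoy classes are
#' planted as a falsifiable negative set, each violating at least four of the
#' six curation criteria by construction: (a) non-hairpin A/C-only loci
#' served by heterogeneous-5' reads, (b) genuine hairpins inside annotated
#' repeat/ncRNA features, and (c) 110 nt over-long hairpins.
#'
#' @param genome,annotation output of [simulateGenome()].
#' @param cfg the same [SimConfig-class].
#' @return `list(genome, planted, decoys)`: the modified genome, a manifest
#'   data.frame of planted miRNAs (name, interval, strand, mature/star
#'   placement and sequences, context) and a decoy manifest (name, interval,
#'   strand, class, read length range).
#' @export
plantHairpins <- function(genome, annotation, cfg) {
  set.seed(.subSeed(cfg@seed, 2L))
  scafLens <- stats::setNames(Biostrings::width(genome), names(genome))
  si <- GenomeInfoDb::Seqinfo(names(genome), unname(scafLens))
  spans <- .contextSpans(annotation, scafLens)
  quota <- .apportion(cfg@nTrueMirnas, cfg@contextProportions)
  names(quota) <- names(cfg@contextProportions)
  contexts <- rep(names(quota), quota)

  occupied <- GenomicRanges::GRanges(seqinfo = si)
  rows <- list()
  planti <- 0L

  addPlanted <- function(scaffold, start, strand, hp, context, name) {
    precEnd <- start + nchar(hp$prec) - 1L
    gseq <- if (strand == "+") hp$prec else .revcomp(hp$prec)
    Biostrings::subseq(genome[[scaffold]], start, precEnd) <<-
      Biostrings::DNAString(gseq)
    # neutralise the 2 nt immediately 5' (in sense) of the precursor so star
    # reads cannot co-map to the mature locus within one mismatch
    if (strand == "+" && start > 2L) {
      Biostrings::subseq(genome[[scaffold]], start - 2L, start - 1L) <<-
        Biostrings::DNAString("AA")
    } else if (strand == "-" && precEnd + 2L <= scafLens[[scaffold]]) {
      Biostrings::subseq(genome[[scaffold]], precEnd + 1L, precEnd + 2L) <<-
        Biostrings::DNAString("TT")
    }
    occupied <<- c(occupied, GenomicRanges::GRanges(
      scaffold, IRanges::IRanges(start, precEnd)))
    # genomic mature/star intervals (sense offsets -> plus coordinates)
    off2g <- function(o, l) {
      if (strand == "+") c(start + o - 1L, start + o + l - 2L)
      else c(precEnd - o - l + 2L, precEnd - o + 1L)
    }
    m <- off2g(hp$matureStart, hp$matureLen)
    s <- off2g(hp$starStart, hp$starLen)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, scaffold = scaffold, prec_start = start,
      prec_end = precEnd, strand = strand,
      mature_start = m[1], mature_end = m[2],
      star_start = s[1], star_end = s[2],
      mature_seq = substr(hp$prec, hp$matureStart,
                          hp$matureStart + hp$matureLen - 1L),
      star_seq = substr(hp$prec, hp$starStart,
                        hp$starStart + hp$starLen - 1L),
      context = context)
  }

  newMature <- function(L = NULL) {
    # last two bases are loop-adjacent and drawn from {A, C} so the hairpin
    # loop region (tail + loop, all A/C) admits no internal base pair
    if (is.null(L)) L <- sample(21:23, 1, prob = c(0.15, 0.7, 0.15))
    first <- if (stats::runif(1) < cfg@frac5pU) "T" else sample(c("A", "C", "G"), 1)
    paste0(first, .randSeq(L - 3L, 0.5), .randSeqAC(2L))
  }
  # rejection sampling: self-complementary matures can give precursors whose
  # maximum-pairing fold is not the designed stem; redraw until the planted
  # precursor folds to a clean single stem-loop
  newHairpin <- function(forceLen = NULL) {
    for (try in 1:100) {
      mature <- newMature(forceLen)
      L <- nchar(mature)
      loopLen <- sample(max(16L, 60L - 2L * L):20L, 1)
      hp <- .buildHairpin(mature, loopLen, sample(0:2, 1))
      st <- foldHairpin(hp$prec)
      if (!(st@nTerminalLoops == 1L && st@pairedFraction >= 0.5)) next
      # self-complementary arms can make the fold of a flank-embedded window
      # branch away from the mature/star duplex; probe with random flanks
      # and keep only hairpins whose duplex stays readable
      probe <- paste0(.randSeq(20L, 0.5), hp$prec, .randSeq(29L, 0.5))
      stW <- foldHairpin(probe)
      if (.predictStar(stW, hp$matureStart + 20L, hp$matureLen)$ok)
        return(hp)
    }
    .stopf("could not construct a clean planted hairpin")
  }

  # cluster first: consecutive intergenic members with ~1 kb gaps in the
  # widest intergenic span
  nClust <- min(cfg@nClustered, sum(contexts == "intergenic"))
  if (nClust >= 2L) {
    ig <- spans$intergenic
    ig <- ig[order(GenomicRanges::width(ig), decreasing = TRUE)]
    need <- nClust * 70L + (nClust - 1L) * 1300L
    if (length(ig) && GenomicRanges::width(ig[1]) >= need) {
      pos <- GenomicRanges::start(ig[1])
      sc <- as.character(GenomeInfoDb::seqnames(ig[1]))
      for (i in seq_len(nClust)) {
        planti <- planti + 1L
        hp <- newHairpin(forceLen = if (planti == 1L) 22L else NULL)
        addPlanted(sc, pos, sample(c("+", "-"), 1), hp, "intergenic",
                   sprintf("true-mir-%02d", planti))
        pos <- pos + nchar(hp$prec) + sample(800:1200, 1)
      }
      drop <- which(contexts == "intergenic")[seq_len(nClust)]
      contexts <- contexts[-drop]
      # keep a 5 kb exclusion zone around the planted cluster so no other
      # planted locus joins it
      occupied <- c(occupied, GenomicRanges::GRanges(
        sc, IRanges::IRanges(max(1L, GenomicRanges::start(ig[1]) - 5000L),
                             min(scafLens[[sc]], pos + 5000L))))
    }
  }

  for (ctx in contexts) {
    planti <- planti + 1L
    hp <- newHairpin(forceLen = if (planti == 1L) 22L else NULL)
    loc <- .placeLocus(spans[[ctx]], nchar(hp$prec) + 4L, occupied)
    if (is.null(loc))
      .stopf("cannot satisfy context quota for '%s'", ctx)
    addPlanted(loc$scaffold, loc$start + 2L, sample(c("+", "-"), 1), hp,
               ctx, sprintf("true-mir-%02d", planti))
  }
  planted <- do.call(rbind, rows)

  # decoys
  rows <- list()
  # the long-hairpin class needs the widest repeat features, so it is
  # placed first
  dclass <- rep(c("c_long_hairpin", "b_repeat_overlap", "a_nonhairpin"),
                length.out = cfg@nDecoys)
  for (i in seq_along(dclass)) {
    cls <- dclass[i]
    name <- sprintf("decoy-%02d", i)
    if (cls == "a_nonhairpin") {
      n <- 66L
      loc <- .placeLocus(spans$intergenic, n + 4L, occupied)
      if (is.null(loc)) .stopf("cannot place decoy in intergenic space")
      start <- loc$start + 2L
      Biostrings::subseq(genome[[loc$scaffold]], start, start + n - 1L) <-
        Biostrings::DNAString(.randSeqAC(n))
      occupied <- c(occupied, GenomicRanges::GRanges(
        loc$scaffold, IRanges::IRanges(start, start + n - 1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        name = name, scaffold = loc$scaffold, prec_start = start,
        prec_end = start + n - 1L, strand = "+", class = cls,
        read_min = 15L, read_max = 19L)
    } else {
      # both hairpin decoy classes sit in annotated repeats/ncRNAs (c6
      # fails by construction): together with heterogeneous 5' ends (c4),
      # off-peak read lengths (c5) and an out-of-band hairpin length (56 or
      # ~110 nt; c2), each violates four criteria no matter how the
      # stochastic star-support check lands
      longarm <- cls == "c_long_hairpin"
      matureLen <- if (longarm) 46L else 22L
      mature <- paste0("T", .randSeq(matureLen - 3L, 0.5), .randSeqAC(2L))
      hp <- .buildHairpin(mature, if (longarm) 18L else 12L, 0L)
      sp <- spans$repeat_nc
      loc <- .placeLocus(sp, nchar(hp$prec) + 4L, occupied)
      if (is.null(loc)) .stopf("cannot place decoy of class %s", cls)
      start <- loc$start + 2L
      strand <- "+"
      Biostrings::subseq(genome[[loc$scaffold]], start,
                         start + nchar(hp$prec) - 1L) <-
        Biostrings::DNAString(hp$prec)
      occupied <- c(occupied, GenomicRanges::GRanges(
        loc$scaffold, IRanges::IRanges(start, start + nchar(hp$prec) - 1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        name = name, scaffold = loc$scaffold, prec_start = start,
        prec_end = start + nchar(hp$prec) - 1L, strand = strand, class = cls,
        read_min = 25L, read_max = 30L)
    }
  }
  decoys <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), scaffold = character(),
               prec_start = integer(), prec_end = integer(),
               strand = character(), class = character(),
               read_min = integer(), read_max = integer())
  rownames(planted) <- NULL
  rownames(decoys) <- NULL
  list(genome = genome, planted = planted, decoys = decoys)
}

#' Simulate adapter-bearing small-RNA reads
#'
#' Draws per-miRNA read counts from a Zipf law (exponent
#' `abundanceAlpha`, rank assigned in planting order), emits mature reads
#' (star reads with probability 0.1) with configurable 5' homogeneity and
#' +/-2 nt 3' jitter, heterogeneous-5' decoy reads, and uniform random genome
#' fragments as background. Every read is the genomic (sense) sequence plus
#' the 3' adapter and random filler, truncated to the machine read length;
#' `fracLowq` reads get mean quality below 20 and `fracAmbiguous` get one N
#' inside the insert.
#'
#' @param sim output of [plantHairpins()].
#' @param cfg the same [SimConfig-class].
#' @return `list(reads, counts)`: a named
#'   [Biostrings::QualityScaledDNAStringSet] in randomised order, and a
#'   data.frame of true per-miRNA read counts (`name`, `true_read_count`,
#'   `true_share`).
#' @export
simulateReads <- function(sim, cfg) {
  set.seed(.subSeed(cfg@seed, 3L))
  genome <- sim$genome
  planted <- sim$planted
  decoys <- sim$decoys
  if (nrow(planted) == 0L) .stopf("no planted miRNAs to simulate reads from")
  scafLens <- stats::setNames(Biostrings::width(genome), names(genome))

  n <- nrow(planted)
  p <- (seq_len(n))^(-cfg@abundanceAlpha)
  p <- p / sum(p)
  counts <- as.integer(stats::rmultinom(1, cfg@nMirnaReads, p))

  nDecoyReads <- if (nrow(decoys)) min(nrow(decoys) * 300L,
                                       cfg@nBackgroundReads %/% 2L) else 0L
  nBg <- cfg@nBackgroundReads - nDecoyReads

  jitter5 <- function(m, hom) {
    d <- integer(m)
    off <- stats::runif(m) >= hom
    d[off] <- sample(c(-2L, -1L, 1L, 2L), sum(off), replace = TRUE)
    d
  }

  frames <- list()
  # miRNA-derived reads
  for (i in seq_len(n)) {
    m <- counts[i]
    if (m == 0L) next
    isStar <- stats::runif(m) < 0.1
    useS <- ifelse(isStar, planted$star_start[i], planted$mature_start[i])
    useE <- ifelse(isStar, planted$star_end[i], planted$mature_end[i])
    d5 <- jitter5(m, cfg@homogeneity5p)
    d3 <- sample(c(-2L, -1L, 0L, 1L, 2L), m, replace = TRUE,
                 prob = c(.05, .15, .6, .15, .05))
    strand <- planted$strand[i]
    if (strand == "+") {
      start <- useS + d5
      end <- useE + d3
    } else {
      start <- useS - d3
      end <- useE - d5
    }
    frames[[length(frames) + 1L]] <- data.frame(
      scaffold = planted$scaffold[i], start = start, end = end,
      strand = strand)
  }
  # decoy reads: heterogeneous 5' ends (modal frequency ~0.3), lengths
  # outside the 20-24 nt band
  if (nrow(decoys)) {
    per <- .apportion(nDecoyReads, rep(1, nrow(decoys)))
    for (i in seq_len(nrow(decoys))) {
      m <- per[i]
      if (m == 0L) next
      d5 <- jitter5(m, 0.3)
      len <- sample(decoys$read_min[i]:decoys$read_max[i], m, replace = TRUE)
      start <- decoys$prec_start[i] + d5
      frames[[length(frames) + 1L]] <- data.frame(
        scaffold = decoys$scaffold[i], start = start,
        end = start + len - 1L, strand = decoys$strand[i])
    }
  }
  # uniform background fragments
  if (nBg > 0L) {
    sc <- sample(names(genome), nBg, replace = TRUE)
    len <- sample(15:35, nBg, replace = TRUE)
    start <- floor(stats::runif(nBg) * (scafLens[sc] - len - 1)) + 1L
    frames[[length(frames) + 1L]] <- data.frame(
      scaffold = sc, start = as.integer(start),
      end = as.integer(start + len - 1L),
      strand = sample(c("+", "-"), nBg, replace = TRUE))
  }
  rf <- do.call(rbind, frames)
  rf$start <- pmax(rf$start, 1L)
  rf$end <- pmin(rf$end, unname(scafLens[rf$scaffold]))

  # pull sequences scaffold-by-scaffold, then orient to sense
  ins <- character(nrow(rf))
  for (sc in unique(rf$scaffold)) {
    idx <- which(rf$scaffold == sc)
    v <- Biostrings::Views(genome[[sc]], rf$start[idx], rf$end[idx])
    ins[idx] <- as.character(v)
  }
  minus <- rf$strand == "-"
  if (any(minus))
    ins[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(ins[minus])))

  nr <- length(ins)
  # adapter + random filler, truncated to machine length
  pool <- .randSeq(200000L, 0.5)
  tail <- paste0(cfg@adapter,
                 substring(pool,
                           s <- sample.int(150000L, nr, replace = TRUE),
                           s + cfg@readLen))
  seqs <- substr(paste0(ins, tail), 1L, cfg@readLen)

  quals <- strrep("I", nchar(seqs))
  lowq <- stats::runif(nr) < cfg@fracLowq
  quals[lowq] <- strrep("0", nchar(seqs[lowq]))
  amb <- !lowq & stats::runif(nr) < cfg@fracAmbiguous
  if (any(amb)) {
    pos <- vapply(pmin(nchar(ins[amb]), nchar(seqs[amb])),
                  function(k) sample.int(max(k, 1L), 1), integer(1))
    substr(seqs[amb], pos, pos) <- "N"
  }

  ord <- sample.int(nr)
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs[ord]),
    Biostrings::PhredQuality(quals[ord]))
  names(reads) <- sprintf("r%07d", seq_len(nr))
  list(reads = reads,
       counts = data.frame(name = planted$name,
                           true_read_count = counts,
                           true_share = 100 * counts / sum(counts)))
}

#' Build per-species reference mature-miRNA catalogs
#'
#' For each species in the panel, each planted mature sequence is deposited
#' with the species' sharing probability, carrying 0-2 substitutions outside
#' the seed (nt 2-8); species-private decoy matures are added on top. The
#' returned truth table records which (miRNA, species) pairs were actually
#' deposited.
#'
#' @param planted planted-miRNA manifest (needs `name`, `mature_seq`), or any
#'   data.frame with those columns.
#' @param cfg a [SimConfig-class] (seed source).
#' @param speciesPanel data.frame with columns `species` and `prob`; the
#'   default emulates the relative conservation of a stingless bee miRNA set
#'   with other bees, model insects, a mite and human.
#' @param nPrivate species-private decoy matures per catalog.
#' @return `list(catalogs, truth)`: a named list of
#'   [Biostrings::DNAStringSet] and a logical sharing truth data.frame.
#' @export
makeReferenceCatalogs <- function(planted, cfg,
                                  speciesPanel = data.frame(
                                    species = c("bte", "bim", "ame", "dme",
                                                "bmo", "vde", "hsa"),
                                    prob = c(0.17, 0.20, 0.09, 0.06, 0.06,
                                             0.02, 0.01)),
                                  nPrivate = 30L) {
  set.seed(.subSeed(cfg@seed, 4L))
  catalogs <- list()
  truth <- list()
  for (k in seq_len(nrow(speciesPanel))) {
    sp <- speciesPanel$species[k]
    keep <- stats::runif(nrow(planted)) < speciesPanel$prob[k]
    seqs <- character(0)
    nms <- character(0)
    for (i in which(keep)) {
      s <- strsplit(planted$mature_seq[i], "")[[1]]
      L <- length(s)
      nsub <- sample(0:2, 1)
      if (nsub > 0 && L >= 12L) {
        at <- sample(10:(L - 2L), nsub)
        for (p2 in at) s[p2] <- sample(setdiff(c("A", "C", "G", "T"), s[p2]), 1)
      }
      seqs <- c(seqs, paste(s, collapse = ""))
      nms <- c(nms, sprintf("%s-miR-%d", sp, i))
    }
    if (nPrivate > 0L) {
      seqs <- c(seqs, vapply(seq_len(nPrivate),
                             function(j) .randSeq(22L, 0.5), character(1)))
      nms <- c(nms, sprintf("%s-miR-p%d", sp, seq_len(nPrivate)))
    }
    cat <- Biostrings::DNAStringSet(seqs)
    names(cat) <- nms
    catalogs[[sp]] <- cat
    truth[[sp]] <- data.frame(name = planted$name, species = sp,
                              shared = keep)
  }
  list(catalogs = catalogs, truth = do.call(rbind, truth))
}

#' Simulate 3'UTRs with planted consensus-grade target sites
#'
#' Builds one UTR per "target" gene containing a strong site for one of the
#' supplied miRNAs (8mer seed, extended 3' complementarity, embedded in a
#' weakly structured A/C pocket so the site is accessible) and additional
#' all-random decoy UTRs.
#'
#' @param mirnaSeqs named character vector of mature miRNA sequences (DNA).
#' @param nTargets,nDecoys UTR counts.
#' @param utrLen UTR length in nt.
#' @param seed integer seed.
#' @return `list(utrs, truth)`: a named [Biostrings::DNAStringSet] and a
#'   data.frame (`gene_id`, `mirna`, `site_start` 1-based or NA,
#'   `is_target`).
#' @export
simulateTargetUtrs <- function(mirnaSeqs, nTargets = 30L, nDecoys = 70L,
                               utrLen = 500L, seed = 1L) {
  set.seed(.subSeed(seed, 5L))
  stopifnot(length(mirnaSeqs) >= 1L, utrLen >= 120L)
  utrs <- character(0)
  rows <- list()
  for (i in seq_len(nTargets)) {
    gid <- sprintf("tgene%03d", i)
    mi <- sample(length(mirnaSeqs), 1)
    mir <- toupper(chartr("U", "T", mirnaSeqs[[mi]]))
    # full-length complement (capped at miRNA nt 22) with the A1 anchor, so
    # even A/U-rich miRNAs clear the duplex-score bar
    site <- paste0(.revcomp(substr(mir, 2L, min(nchar(mir), 22L))), "A")
    pocket <- paste0(.randSeqAC(30L), site, .randSeqAC(30L))
    pos <- sample(20:(utrLen - nchar(pocket) - 20L), 1)
    utr <- paste0(.randSeq(pos - 1L, 0.5), pocket,
                  .randSeq(utrLen - pos + 1L - nchar(pocket), 0.5))
    utrs <- c(utrs, utr)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, mirna = names(mirnaSeqs)[mi],
      site_start = pos + 30L, is_target = TRUE)
  }
  for (i in seq_len(nDecoys)) {
    gid <- sprintf("dgene%03d", i)
    utrs <- c(utrs, .randSeq(utrLen, 0.5))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, mirna = NA_character_, site_start = NA_integer_,
      is_target = FALSE)
  }
  truth <- do.call(rbind, rows)
  out <- Biostrings::DNAStringSet(utrs)
  names(out) <- truth$gene_id
  list(utrs = out, truth = truth)
}

#' Write a complete simulated study to a run directory
#'
#' Runs [simulateGenome()], [plantHairpins()], [simulateReads()] and
#' [makeReferenceCatalogs()] and writes `genome.fa`, `annotation.gff3`,
#' `reads.fastq`, `truth_mirnas.tsv`, `truth_decoys.tsv`,
#' `truth_sharing.tsv` and `catalogs/<species>.fa` under `dir`. With a fixed
#' seed the outputs are byte-identical across runs.
#'
#' @param cfg a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
writeSimulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "catalogs"), showWarnings = FALSE)
  g <- simulateGenome(cfg)
  sim <- plantHairpins(g$genome, g$annotation, cfg)
  rd <- simulateReads(sim, cfg)
  cats <- makeReferenceCatalogs(sim$planted, cfg)
  writeFasta(sim$genome, file.path(dir, "genome.fa"))
  writeGff3(g$annotation, file.path(dir, "annotation.gff3"))
  writeFastq(rd$reads, file.path(dir, "reads.fastq"))
  truth <- merge(sim$planted, rd$counts, by = "name", sort = FALSE)
  writeTsv(truth, file.path(dir, "truth_mirnas.tsv"))
  writeTsv(sim$decoys, file.path(dir, "truth_decoys.tsv"))
  writeTsv(cats$truth, file.path(dir, "truth_sharing.tsv"))
  for (sp in names(cats$catalogs))
    writeFasta(cats$catalogs[[sp]],
               file.path(dir, "catalogs", paste0(sp, ".fa")))
  invisible(list(genome = sim$genome, annotation = g$annotation,
                 planted = truth, decoys = sim$decoys, reads = rd$reads,
                 catalogs = cats$catalogs, sharingTruth = cats$truth,
                 dir = dir))
}
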