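#' Extract putative 3'UTRs as fixed downstream flanks
#'
#' Under annotation-poor conditions the 3'UTR of each gene is approximated
#' by the `flank` nucleotides immediately downstream of its annotated end:
#' plus-strand genes yield the genomic slice after the gene end,
#' minus-strand genes the reverse complement of the slice before the gene
#' start. The window is clipped at scaffold edges (never at neighbouring
#' genes), so edge genes yield shorter records; exactly one record per gene
#' is returned.
#'
#' @param annotation annotation [GenomicRanges::GRanges] as from
#'   [readGff3()] (gene features with strand are used).
#' @param genome a named [Biostrings::DNAStringSet].
#' @param flank UTR length in nt.
#' @return a named [Biostrings::DNAStringSet] (names are gene ids) with the
#'   source interval in `mcols()` (`scaffold`, `start`, `end`, `strand`).
#' @export
extract3UTRs <- function(annotation, genome, flank = 1000L) {
  genes <- annotation[annotation$ftype == "gene"]
  scafLens <- stats::setNames(Biostrings::width(genome), names(genome))
  sc <- as.character(GenomeInfoDb::seqnames(genes))
  missing <- !(sc %in% names(genome))
  if (any(missing))
    .stopf("gene '%s' lies on unknown scaffold '%s'",
           genes$gene_id[missing][1], sc[missing][1])
  strand <- as.character(BiocGenerics::strand(genes))
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  us <- ifelse(strand == "-", pmax(1L, gs - flank), pmin(ge + 1L, scafLens[sc] + 1L))
  ue <- ifelse(strand == "-", gs - 1L, pmin(ge + flank, scafLens[sc]))
  seqs <- character(length(genes))
  for (i in seq_along(genes)) {
    seqs[i] <- if (ue[i] >= us[i])
      .senseSeq(genome, sc[i], us[i], ue[i], strand[i]) else ""
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    scaffold = sc, start = as.integer(us), end = as.integer(ue),
    strand = strand)
  out
}

# canonical pairing helpers in DNA space
.isWC <- function(mirB, utrB) {
  (mirB == "A" & utrB == "T") | (mirB == "T" & utrB == "A") |
    (mirB == "G" & utrB == "C") | (mirB == "C" & utrB == "G")
}
.isGU <- function(mirB, utrB) {
  (mirB == "G" & utrB == "T") | (mirB == "T" & utrB == "G")
}

#' Seed-match site scan (pattern predictor)
#'
#' Scans a UTR for Watson-Crick matches to the miRNA seed (nt 2-7) and
#' classifies each site into the canonical classes: `6mer`, `7mer-m8`
#' (nt 8 also pairs), `7mer-A1` (an A faces miRNA nt 1) or `8mer` (both).
#' The predictor's positive call (`p1_hit`) requires at least a 7mer.
#'
#' @param mirnaSeq mature miRNA, DNA or RNA string (>= 8 nt).
#' @param utr UTR sequence (character or XString).
#' @param mirna,gene_id optional labels stored in the output.
#' @return data.frame with one row per site: `mirna`, `gene_id`,
#'   `seed_start` (1-based UTR position pairing miRNA nt 7), `utr_pos`
#'   (0-based position of the last matched UTR nucleotide), `site_type`,
#'   `p1_hit`.
#' @export
predictSeedSites <- function(mirnaSeq, utr, mirna = "mir", gene_id = "gene") {
  mir <- toupper(chartr("U", "T", as.character(mirnaSeq)))
  if (nchar(mir) < 8L) .stopf("miRNA must be >= 8 nt")
  utr <- toupper(as.character(utr))
  empty <- data.frame(mirna = character(), gene_id = character(),
                      seed_start = integer(), utr_pos = integer(),
                      site_type = character(), p1_hit = logical())
  n <- nchar(utr)
  core <- .revcomp(substr(mir, 2L, 7L))
  if (n < 6L) return(empty)
  # all occurrences, overlapping ones included
  hits <- BiocGenerics::start(Biostrings::matchPattern(
    core, Biostrings::DNAString(utr)))
  if (!length(hits)) return(empty)
  ub <- strsplit(utr, "")[[1]]
  mb <- strsplit(mir, "")[[1]]
  rows <- lapply(as.integer(hits), function(t) {
    m8 <- t > 1L && ub[t - 1L] == .complementBase(mb[8])
    a1 <- t + 6L <= n && ub[t + 6L] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    lastPos <- if (a1) t + 5L else t + 4L  # 0-based last matched nucleotide
    data.frame(mirna = mirna, gene_id = gene_id, seed_start = t,
               utr_pos = lastPos, site_type = type,
               p1_hit = type %in% c("7mer-m8", "7mer-A1", "8mer"))
  })
  do.call(rbind, rows)
}

#' Ungapped duplex score (complementarity predictor)
#'
#' Scores the miRNA:UTR duplex anchored at a seed site, extending to at
#' most 14 nt of 3'-compensatory pairing (miRNA nt 1-22): each aligned
#' position contributes +3 (GC), +2 (AU), +1 (GU) or -2 (mismatch);
#' positions falling outside the UTR contribute nothing. The positive call
#' requires a score of at least 25 and at most one non-Watson-Crick
#' position within the seed (nt 2-8).
#'
#' @param mirnaSeq mature miRNA (DNA/RNA string).
#' @param utr UTR sequence.
#' @param site one row of [predictSeedSites()] output.
#' @return `list(p2_score, p2_hit)`.
#' @export
predictDuplex <- function(mirnaSeq, utr, site) {
  mir <- toupper(chartr("U", "T", as.character(mirnaSeq)))
  utr <- toupper(as.character(utr))
  mb <- strsplit(mir, "")[[1]]
  ub <- strsplit(utr, "")[[1]]
  t <- site$seed_start
  L <- min(length(mb), 22L)
  score <- 0
  seedNonWC <- 0L
  for (m in seq_len(L)) {
    u <- t + 7L - m
    if (u < 1L || u > length(ub)) {
      if (m >= 2L && m <= 8L) seedNonWC <- seedNonWC + 1L
      next
    }
    wc <- .isWC(mb[m], ub[u])
    gu <- .isGU(mb[m], ub[u])
    score <- score +
      if (wc && mb[m] %in% c("G", "C")) 3
      else if (wc) 2
      else if (gu) 1
      else -2
    if (m >= 2L && m <= 8L && !wc) seedNonWC <- seedNonWC + 1L
  }
  list(p2_score = score, p2_hit = score >= 25 && seedNonWC <= 1L)
}

#' Site accessibility score (structure predictor)
#'
#' Energy-proxy accessibility in the spirit of ddG scoring: the duplex gain
#' is taken as minus the complementarity score, and the opening cost is the
#' weighted pairing score (GC 3, AU 2, GU 1) lost when the site region is
#' forced unpaired in the base-pair-maximisation fold of the surrounding
#' `window` nt of UTR. `p3_ddg = -p2_score + dG_open`; the positive call
#' requires `p3_ddg <= -10`. Windows are clipped at UTR edges.
#'
#' @param utr UTR sequence.
#' @param site one row of [predictSeedSites()] output.
#' @param p2Score the duplex score of the site (see [predictDuplex()]).
#' @param window folding window width (nt), centred on the seed site.
#' @return `list(p3_ddg, p3_hit, dg_open)`.
#' @export
predictAccessibility <- function(utr, site, p2Score, window = 70L) {
  utr <- toupper(as.character(utr))
  n <- nchar(utr)
  t <- site$seed_start
  siteLo <- max(1L, t - 1L)
  siteHi <- min(n, t + 6L)
  mid <- t + 2L
  lo <- max(1L, mid - (window %/% 2L - 1L))
  hi <- min(n, mid + window %/% 2L)
  win <- substr(utr, lo, hi)
  if (nchar(win) < 10L) {
    dgOpen <- 0
  } else {
    blocked <- (siteLo:siteHi) - lo + 1L
    w1 <- .foldScore(win, c(3, 2, 1))
    w2 <- .foldScore(win, c(3, 2, 1), blocked = blocked)
    dgOpen <- w1 - w2
  }
  ddg <- -p2Score + dgOpen
  list(p3_ddg = ddg, p3_hit = ddg <= -10, dg_open = dgOpen)
}

#' Consensus flag over the three predictors
#'
#' Retains the strict intersection rule: a site is a consensus call iff all
#' three predictors call it (`p1_hit & p2_hit & p3_hit`), so the consensus
#' set is a subset of every predictor's positive set. Gene-level targets
#' are genes with at least one consensus site.
#'
#' @param sites data.frame with `p1_hit`, `p2_hit`, `p3_hit` (as built by
#'   [predictTargets()]).
#' @return `list(sites, target_genes)`: the sites with a `consensus`
#'   column, and the character vector of consensus target genes.
#' @export
consensusTargets <- function(sites) {
  if (!nrow(sites)) {
    sites$consensus <- logical(0)
    return(list(sites = sites, target_genes = character()))
  }
  sites$consensus <- sites$p1_hit & sites$p2_hit & sites$p3_hit
  list(sites = sites,
       target_genes = sort(unique(sites$gene_id[sites$consensus])))
}

#' Run the three-predictor consensus over miRNA x UTR pairs
#'
#' For every miRNA and UTR, seed sites are enumerated and scored by the
#' three independent signals (seed pattern, duplex complementarity, site
#' accessibility); the consensus flag marks sites positive under all
#' three.
#'
#' @param mirnas named character vector of mature sequences, or a
#'   discovery [GenomicRanges::GRanges].
#' @param utrs a named [Biostrings::DNAStringSet] from [extract3UTRs()] or
#'   [simulateTargetUtrs()].
#' @param window accessibility folding window (nt).
#' @return as [consensusTargets()]: `list(sites, target_genes)`.
#' @export
predictTargets <- function(mirnas, utrs, window = 70L) {
  seqs <- .mirnaSeqs(mirnas)
  utrc <- .asDNAChar(utrs)
  rows <- list()
  for (mi in seq_along(seqs)) {
    for (ui in seq_along(utrc)) {
      if (nchar(utrc[[ui]]) < 20L) next
      s <- predictSeedSites(seqs[[mi]], utrc[[ui]], names(seqs)[mi],
                            names(utrc)[ui])
      if (!nrow(s)) next
      for (k in seq_len(nrow(s))) {
        p2 <- predictDuplex(seqs[[mi]], utrc[[ui]], s[k, ])
        p3 <- predictAccessibility(utrc[[ui]], s[k, ], p2$p2_score, window)
        rows[[length(rows) + 1L]] <- cbind(
          s[k, ], p2_score = p2$p2_score, p2_hit = p2$p2_hit,
          p3_ddg = p3$p3_ddg, p3_hit = p3$p3_hit)
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), gene_id = character(),
               seed_start = integer(), utr_pos = integer(),
               site_type = character(), p1_hit = logical(),
               p2_score = numeric(), p2_hit = logical(),
               p3_ddg = numeric(), p3_hit = logical())
  rownames(sites) <- NULL
  consensusTargets(sites)
}

#' Count GO terms among target genes
#'
#' Word-frequency summary of the GO labels attached to predicted target
#' genes (counting only, suitable for word-cloud rendering); genes without
#' any annotation are tallied under `"unannotated"`.
#'
#' @param targetGenes character vector of gene ids.
#' @param gene2go data.frame with columns `gene_id` and `go_term`.
#' @return data.frame (`go_term`, `count`) in descending count order.
#' @export
summarizeGo <- function(targetGenes, gene2go) {
  if (!length(targetGenes))
    return(data.frame(go_term = character(), count = integer()))
  ann <- gene2go[gene2go$gene_id %in% targetGenes, , drop = FALSE]
  un <- setdiff(targetGenes, gene2go$gene_id)
  terms <- c(ann$go_term, rep("unannotated", length(un)))
  tab <- sort(table(terms), decreasing = TRUE)
  data.frame(go_term = names(tab), count = as.integer(tab),
             row.names = NULL)
}
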