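#' Analytic Zipf abundance share
#'
#' Expected share (in percent) of the rank-`rank` miRNA when per-miRNA read
#' counts follow a Zipf law with exponent `alpha` over `n` ranks.
#'
#' @param alpha Zipf exponent.
#' @param n number of ranks.
#' @param rank queried rank.
#' @return expected share in percent.
#' @export
zipfShare <- function(alpha, n, rank = 1L) {
  p <- (seq_len(n))^(-alpha)
  100 * p[rank] / sum(p)
}

#' Assemble a pipeline configuration
#'
#' Collects file paths and per-stage parameters (with the package defaults)
#' into a plain list accepted by [runPipeline()]. Parameters mirror the
#' stage functions; any can be overridden via `...`.
#'
#' @param fastq,genome,gff3 input paths (FASTQ reads, FASTA genome, GFF3
#'   annotation).
#' @param outdir output directory.
#' @param catalogsDir optional directory of per-species catalogs
#'   (`<species>.fa`); when absent the conservation stage is skipped with a
#'   warning.
#' @param gene2go optional TSV path (`gene_id`, `go_term`).
#' @param seed integer seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @param ... per-stage parameter overrides: `adapter`, `minOverlap`,
#'   `maxErrRate`, `minLen`, `minMeanQ`, `k`, `maxMm`, `maxHits`,
#'   `minReads`, `mergeGap`, `flankLong`, `flankShort`, `minCriteria`,
#'   `namePrefix`, `clusterGap`, `utrFlank`, `targetTop`,
#'   `accessWindow`, `writeOutputs`.
#' @return a named list (class `"mirforge_config"`).
#' @export
pipelineConfig <- function(fastq, genome, gff3, outdir,
                           catalogsDir = NULL, gene2go = NULL, seed = 1L,
                           ...) {
  cfg <- list(fastq = fastq, genome = genome, gff3 = gff3,
              outdir = outdir, catalogsDir = catalogsDir,
              gene2go = gene2go, seed = as.integer(seed),
              adapter = "AGATCGGAAGAGC", minOverlap = 3L, maxErrRate = 0.1,
              minLen = 15L, minMeanQ = 20, k = 10L, maxMm = 1L,
              maxHits = 5L, minReads = 5L, mergeGap = 0L, flankLong = 70L,
              flankShort = 20L, minCriteria = 3L, namePrefix = "mir",
              clusterGap = 5000L, utrFlank = 1000L, targetTop = 1L,
              accessWindow = 70L, writeOutputs = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) .stopf("unknown config field(s): %s",
                          paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "mirforge_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of [pipelineConfig()] fields
#'   (paths plus parameter overrides).
#' @return a config list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("fastq", "genome", "gff3", "outdir")
  miss <- setdiff(need, names(y))
  if (length(miss)) .stopf("config is missing: %s",
                           paste(miss, collapse = ", "))
  do.call(pipelineConfig, y)
}

.logStage <- function(...) message(sprintf("[mirforge] %s", sprintf(...)))

#' Run the full analysis pipeline
#'
#' Executes preprocess -> map -> profile -> discover -> genomic context and
#' clusters -> conservation -> targets, writes every intermediate table to
#' `outdir` and returns a structured report. With identical inputs and
#' config the report (and `report.json` on disk) is byte-identical across
#' runs. A missing catalogs directory skips the conservation stage with a
#' warning and leaves its report fields NULL.
#'
#' @param config a list from [pipelineConfig()] or [readPipelineConfig()].
#' @return the report: a named list with elements `preprocess`, `mapping`,
#'   `profile`, `discovery`, `mirnas`, `context`, `clusters`,
#'   `scaffold_counts`, `top10`, `conservation`, `targets`, `go`.
#' @export
runPipeline <- function(config) {
  for (f in c("fastq", "genome", "gff3"))
    if (!file.exists(config[[f]]))
      .stopf("input '%s' not found: %s", f, config[[f]])
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x) file.path(config$outdir, x)

  .logStage("preprocess: reading %s", config$fastq)
  reads <- readFastq(config$fastq)
  pre <- preprocessReads(reads, config$adapter, config$minOverlap,
                         config$maxErrRate, config$minLen, config$minMeanQ)
  .logStage("preprocess: %d reads in, %d kept", pre$report$n_input,
            pre$report$n_kept)

  genome <- readFasta(config$genome)
  annotation <- readGff3(config$gff3)
  aln <- mapReads(pre$reads, genome, config$k, config$maxMm, config$maxHits)
  nMapped <- attr(aln, "nMapped")
  .logStage("mapping: %d/%d reads mapped (%d alignments)", nMapped,
            length(pre$reads), length(aln))

  profile <- profileMapped(aln)

  disc <- discoverMirnas(aln, genome, annotation, config$minReads,
                         config$mergeGap, config$flankLong,
                         config$flankShort, config$minCriteria,
                         config$namePrefix)
  nCand <- length(disc$candidates)
  nKept <- length(disc$mirnas)
  .logStage("discovery: %d stacks -> %d candidates, %d kept",
            length(disc$stacks), nCand, nKept)

  ov <- dropOverlapping(disc$mirnas)
  mirnas <- ov$kept
  # re-quantify on the final set so shares sum to 100 over reported miRNAs
  mirnas <- quantifyMirnas(mirnas, aln)
  ctx <- classifyContext(mirnas, annotation)
  ctxFrac <- if (nrow(ctx))
    100 * table(ctx$context) / nrow(ctx) else table(ctx$context)
  clusters <- findClusters(mirnas, config$clusterGap)
  scafCounts <- perScaffoldCounts(mirnas)
  .logStage("context: %d mirnas after overlap removal, %d cluster(s)",
            length(mirnas), nrow(clusters))

  mirTab <- data.frame(
    name = mirnas$name,
    scaffold = as.character(GenomeInfoDb::seqnames(mirnas)),
    prec_start = GenomicRanges::start(mirnas),
    prec_end = GenomicRanges::end(mirnas),
    strand = as.character(BiocGenerics::strand(mirnas)),
    mature_start = mirnas$mature_start, mature_end = mirnas$mature_end,
    mature_seq = mirnas$mature_seq, read_count = mirnas$read_count,
    rpm = mirnas$rpm, share = mirnas$share)
  top10 <- utils::head(mirTab[order(-mirTab$share),
                              c("name", "read_count", "share")], 10L)
  rownames(top10) <- NULL

  conservation <- NULL
  if (!is.null(config$catalogsDir) && dir.exists(config$catalogsDir)) {
    files <- list.files(config$catalogsDir, pattern = "\\.fa$",
                        full.names = TRUE)
    cats <- lapply(files, readFasta)
    names(cats) <- sub("\\.fa$", "", basename(files))
    if (length(cats) && length(mirnas)) {
      combined <- do.call(c, unname(lapply(cats, as.character)))
      kn <- callKnownNovel(mirnas, combined)
      sm <- sharingMatrix(mirnas, cats)
      conservation <- list(
        n_known = length(kn$known), n_specific = length(kn$specific),
        known = kn$known, specific = kn$specific,
        per_species = as.list(sm$perSpecies),
        intersections = sm$intersections)
      .logStage("conservation: %d known / %d specific over %d catalogs",
                length(kn$known), length(kn$specific), length(cats))
    }
  } else {
    warning("catalogs directory missing; conservation stage skipped",
            call. = FALSE)
  }

  utrs <- extract3UTRs(annotation, genome, config$utrFlank)
  topMir <- mirTab[order(-mirTab$share), ]
  topMir <- utils::head(topMir, max(config$targetTop, 0L))
  targets <- if (nrow(topMir)) {
    predictTargets(stats::setNames(topMir$mature_seq, topMir$name), utrs,
                   config$accessWindow)
  } else list(sites = consensusTargets(
    data.frame(p1_hit = logical(), p2_hit = logical(),
               p3_hit = logical()))$sites, target_genes = character())
  .logStage("targets: %d sites, %d consensus gene(s)",
            nrow(targets$sites), length(targets$target_genes))

  go <- NULL
  if (!is.null(config$gene2go) && file.exists(config$gene2go)) {
    g2g <- readTsv(config$gene2go)
    go <- summarizeGo(targets$target_genes, g2g)
  }

  report <- list(
    seed = config$seed,
    preprocess = pre$report,
    mapping = list(n_mapped = nMapped, n_alignments = length(aln),
                   n_multimapper_discarded =
                     sum(attr(aln, "status") == 2L)),
    profile = as.data.frame.matrix(profile),
    discovery = list(n_stacks = length(disc$stacks),
                     n_candidates = nCand, n_kept = nKept,
                     n_discarded = nCand - nKept,
                     n_after_overlap_removal = length(mirnas)),
    mirnas = mirTab,
    context = list(calls = ctx,
                   fractions = as.list(round(unclass(ctxFrac), 6))),
    clusters = clusters,
    scaffold_counts = scafCounts,
    top10 = top10,
    conservation = conservation,
    targets = list(n_sites = nrow(targets$sites),
                   n_consensus_sites = sum(targets$sites$consensus),
                   target_genes = targets$target_genes),
    go = go)

  if (isTRUE(config$writeOutputs)) {
    writeTsv(pre$report, out("preprocess_report.tsv"))
    writeTsv(cbind(length = rownames(profile),
                   as.data.frame.matrix(profile)), out("profile.tsv"))
    writeTsv(disc$table, out("candidates.tsv"))
    writeTsv(mirTab, out("quantification.tsv"))
    if (nrow(mirTab)) {
      writeFasta(stats::setNames(mirTab$mature_seq, mirTab$name),
                 out("mirnas.fa"))
      prec <- vapply(seq_len(nrow(mirTab)), function(i)
        .senseSeq(genome, mirTab$scaffold[i], mirTab$prec_start[i],
                  mirTab$prec_end[i], mirTab$strand[i]), character(1))
      writeFasta(stats::setNames(prec, mirTab$name), out("precursors.fa"))
    }
    writeTsv(ctx, out("context.tsv"))
    writeTsv(clusters, out("clusters.tsv"))
    writeTsv(scafCounts, out("scaffold_counts.tsv"))
    if (nrow(clusters)) {
      cgr <- GenomicRanges::GRanges(
        clusters$scaffold,
        IRanges::IRanges(clusters$span_start, clusters$span_end))
      names(cgr) <- clusters$cluster_id
      writeBed(cgr, out("clusters.bed"))
    }
    if (!is.null(conservation)) {
      writeTsv(data.frame(mirna = c(conservation$known,
                                    conservation$specific),
                          status = rep(c("known", "specific"),
                                       c(conservation$n_known,
                                         conservation$n_specific))),
               out("known_novel.tsv"))
      writeTsv(data.frame(species = names(conservation$per_species),
                          shared = unlist(conservation$per_species)),
               out("sharing_totals.tsv"))
      writeTsv(conservation$intersections, out("upset_counts.tsv"))
    }
    writeFasta(utrs[Biostrings::width(utrs) > 0], out("utrs.fa"))
    writeTsv(targets$sites, out("target_sites.tsv"))
    writeTsv(data.frame(gene_id = targets$target_genes),
             out("target_genes.tsv"))
    if (!is.null(go)) writeTsv(go, out("go_counts.tsv"))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  report
}

#' Simulate a study, run the pipeline, and score against ground truth
#'
#' Generates a complete synthetic dataset under `simCfg`, runs
#' [runPipeline()] on the files, joins predictions to the truth manifests
#' and reports recall/precision for discovery, decoy acceptance, context
#' classification accuracy and recovered fractions, abundance-share
#' recovery, sharing-matrix accuracy and (on separately simulated UTRs)
#' target-site recall and false-positive gene rate.
#'
#' @param simCfg a [SimConfig-class].
#' @param dir run directory (simulation inputs and pipeline outputs are
#'   written beneath it).
#' @param targetEval also evaluate the target predictor on synthetic UTRs
#'   planted for the top discovered miRNAs.
#' @param ... pipeline parameter overrides passed to [pipelineConfig()].
#' @return `list(truth, report, evaluation)`.
#' @export
simulateAndRun <- function(simCfg, dir = tempfile("mirforge_run"),
                           targetEval = TRUE, ...) {
  sim <- writeSimulation(simCfg, dir)
  config <- pipelineConfig(
    fastq = file.path(dir, "reads.fastq"),
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    outdir = file.path(dir, "out"),
    catalogsDir = file.path(dir, "catalogs"),
    seed = simCfg@seed,
    adapter = simCfg@adapter, ...)
  report <- runPipeline(config)

  mir <- report$mirnas
  mirGR <- if (nrow(mir)) GenomicRanges::GRanges(
    mir$scaffold, IRanges::IRanges(mir$prec_start, mir$prec_end),
    strand = mir$strand) else GenomicRanges::GRanges()
  truthGR <- GenomicRanges::GRanges(
    sim$planted$scaffold,
    IRanges::IRanges(sim$planted$prec_start, sim$planted$prec_end),
    strand = sim$planted$strand)
  decoyGR <- GenomicRanges::GRanges(
    sim$decoys$scaffold,
    IRanges::IRanges(sim$decoys$prec_start, sim$decoys$prec_end),
    strand = sim$decoys$strand)

  hitTruth <- GenomicRanges::findOverlaps(truthGR, mirGR,
                                          ignore.strand = FALSE)
  recovered <- unique(S4Vectors::queryHits(hitTruth))
  recall <- length(recovered) / nrow(sim$planted)
  # a decoy counts as accepted only if a kept candidate arose from its own
  # read stack, i.e. the kept mature 5' end coincides (within the 5' read
  # jitter) with the decoy's planted read 5' end on the same strand;
  # background stacks that merely overlap a decoy interval are ordinary
  # false positives instead
  decoyHit <- if (nrow(sim$decoys) && nrow(mir)) {
    sum(vapply(seq_len(nrow(sim$decoys)), function(i) {
      d <- sim$decoys[i, ]
      d5 <- if (d$strand == "+") d$prec_start else d$prec_end
      m5 <- ifelse(mir$strand == "+", mir$mature_start, mir$mature_end)
      any(mir$scaffold == d$scaffold & mir$strand == d$strand &
            abs(m5 - d5) <= 4L)
    }, logical(1)))
  } else 0L
  decoyAcc <- if (nrow(sim$decoys)) decoyHit / nrow(sim$decoys) else 0
  truePos <- unique(S4Vectors::subjectHits(hitTruth))
  precision <- if (length(mirGR)) length(truePos) / length(mirGR) else NA

  # context: classify the recovered planted loci and compare to the quota
  ctxEval <- NULL
  if (length(recovered)) {
    m <- S4Vectors::queryHits(hitTruth)
    first <- !duplicated(m)
    tIdx <- m[first]
    pIdx <- S4Vectors::subjectHits(hitTruth)[first]
    pred <- report$context$calls
    predCtx <- pred$context[match(mir$name[pIdx], pred$mirna)]
    trueCtx <- sim$planted$context[tIdx]
    lv <- c("pseudogene", "exonic", "intronic", "intergenic")
    frac <- 100 * table(factor(as.character(predCtx), levels = lv)) /
      length(predCtx)
    ctxEval <- list(
      accuracy = mean(as.character(predCtx) == trueCtx),
      recovered_fractions = as.list(round(unclass(frac), 6)),
      planted_fractions = as.list(round(
        100 * unclass(table(factor(sim$planted$context, levels = lv))) /
          nrow(sim$planted), 6)))
  }

  # abundance: observed share of the true rank-1 miRNA vs the analytic one
  shareEval <- NULL
  if (length(recovered)) {
    topTruth <- sim$planted[which.max(sim$planted$true_read_count), ]
    tg <- GenomicRanges::GRanges(topTruth$scaffold,
                                 IRanges::IRanges(topTruth$prec_start,
                                                  topTruth$prec_end),
                                 strand = topTruth$strand)
    hit <- GenomicRanges::findOverlaps(tg, mirGR)
    obs <- if (length(hit))
      max(mir$share[S4Vectors::subjectHits(hit)]) else NA
    shareEval <- list(
      rank1_share_observed = obs,
      rank1_share_analytic = zipfShare(simCfg@abundanceAlpha,
                                       simCfg@nTrueMirnas, 1L),
      shares_sum = sum(mir$share))
  }

  # sharing: per-species totals among truth-matched mirnas vs planted truth
  sharingEval <- NULL
  if (!is.null(report$conservation)) {
    truthTab <- sim$sharingTruth
    expected <- tapply(truthTab$shared, truthTab$species, sum)
    sharingEval <- list(
      observed = report$conservation$per_species,
      expected_planted = as.list(as.integer(expected)[
        order(names(expected))]),
      n_known = report$conservation$n_known,
      n_specific = report$conservation$n_specific)
    names(sharingEval$expected_planted) <- sort(names(expected))
  }

  targetsEval <- NULL
  if (targetEval && nrow(mir)) {
    top <- utils::head(mir[order(-mir$share), ], 5L)
    tu <- simulateTargetUtrs(stats::setNames(top$mature_seq, top$name),
                             seed = simCfg@seed)
    res <- predictTargets(stats::setNames(top$mature_seq, top$name),
                          tu$utrs)
    planted <- tu$truth[tu$truth$is_target, ]
    siteHit <- vapply(seq_len(nrow(planted)), function(i) {
      s <- res$sites
      any(s$consensus & s$gene_id == planted$gene_id[i] &
            s$mirna == planted$mirna[i] &
            s$seed_start >= planted$site_start[i] &
            s$seed_start <= planted$site_start[i] + 40L)
    }, logical(1))
    decoyGenes <- tu$truth$gene_id[!tu$truth$is_target]
    fpRate <- mean(decoyGenes %in% res$target_genes)
    targetsEval <- list(site_recall = mean(siteHit),
                        fp_gene_rate = fpRate)
  }

  evaluation <- list(
    discovery = list(recall = recall, precision = precision,
                     decoy_acceptance = decoyAcc,
                     n_planted = nrow(sim$planted),
                     n_recovered = length(recovered),
                     n_decoys = nrow(sim$decoys),
                     n_decoys_kept = decoyHit),
    context = ctxEval,
    abundance = shareEval,
    sharing = sharingEval,
    targets = targetsEval)
  list(truth = sim, report = report, evaluation = evaluation)
}
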