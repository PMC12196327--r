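test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- simConfig(seed = 17L, nScaffolds = 1L, scaffoldLen = 20000L,
                   nTrueMirnas = 5L, nDecoys = 3L, nMirnaReads = 3000L,
                   nBackgroundReads = 500L, nClustered = 0L)
  d1 <- file.path(tempdir(), "sim_det_1")
  d2 <- file.path(tempdir(), "sim_det_2")
  writeSimulation(cfg, d1)
  writeSimulation(cfg, d2)
  for (f in c("genome.fa", "annotation.gff3", "reads.fastq",
              "truth_mirnas.tsv", "truth_sharing.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("simulated genomes match the configured shape and GC content", {
  cfg <- simConfig(seed = 2L, gcContent = 0.35)
  g <- simulateGenome(cfg)
  expect_length(g$genome, 3L)
  expect_true(all(Biostrings::width(g$genome) == 50000L))
  gc <- Biostrings::letterFrequency(g$genome, "GC", as.prob = TRUE)
  expect_true(all(abs(gc - 0.35) < 0.02))
  # gene models have 3 exons each; all five feature classes present
  expect_true(all(table(g$annotation$gene_id[
    g$annotation$ftype == "exon"]) == 3L))
  expect_setequal(as.character(unique(g$annotation$ftype)),
                  c("gene", "exon", "ncRNA", "repeat", "pseudogene"))
})

test_that("a degenerate context quota plants everything in introns", {
  cfg <- simConfig(seed = 9L, nScaffolds = 1L, scaffoldLen = 30000L,
                   nTrueMirnas = 6L, nDecoys = 0L, nClustered = 0L,
                   contextProportions = c(intronic = 1, intergenic = 0,
                                          exonic = 0, pseudogene = 0))
  g <- simulateGenome(cfg)
  sim <- plantHairpins(g$genome, g$annotation, cfg)
  expect_true(all(sim$planted$context == "intronic"))
  introns <- GenomicRanges::setdiff(
    g$annotation[g$annotation$ftype == "gene"],
    g$annotation[g$annotation$ftype == "exon"], ignore.strand = TRUE)
  pgr <- GenomicRanges::GRanges(sim$planted$scaffold,
                                IRanges::IRanges(sim$planted$prec_start,
                                                 sim$planted$prec_end))
  within <- IRanges::overlapsAny(pgr, introns, type = "within",
                                 ignore.strand = TRUE)
  expect_true(all(within))
})

test_that("planted manifest and genome agree; hairpins fold to one loop", {
  run <- smallRun()
  pl <- run$truth$planted
  for (i in seq_len(nrow(pl))) {
    prec <- mirforge:::.senseSeq(run$truth$genome, pl$scaffold[i],
                                 pl$prec_start[i], pl$prec_end[i],
                                 pl$strand[i])
    expect_equal(substr(prec, 1, nchar(pl$mature_seq[i])), pl$mature_seq[i])
    expect_true(nchar(prec) >= 60 && nchar(prec) <= 80)
    st <- foldHairpin(prec)
    expect_equal(nTerminalLoops(st), 1L)
    expect_gte(pairedFraction(st), 0.45)
  }
})

test_that("5' U bias and homogeneity follow the configuration", {
  cfg <- simConfig(seed = 4L, nScaffolds = 1L, scaffoldLen = 25000L,
                   nTrueMirnas = 8L, nDecoys = 0L, nClustered = 0L,
                   frac5pU = 1, homogeneity5p = 1, nMirnaReads = 4000L,
                   nBackgroundReads = 0L, fracLowq = 0, fracAmbiguous = 0)
  g <- simulateGenome(cfg)
  sim <- plantHairpins(g$genome, g$annotation, cfg)
  expect_true(all(substr(sim$planted$mature_seq, 1, 1) == "T"))
  rd <- simulateReads(sim, cfg)
  pre <- preprocessReads(rd$reads, cfg@adapter)
  al <- mapReads(pre$reads, sim$genome)
  # with no background/noise every read maps, and each mature's reads share
  # a single 5' coordinate
  expect_equal(attr(al, "nMapped"), length(pre$reads))
  for (i in seq_len(nrow(sim$planted))) {
    p <- sim$planted[i, ]
    m5 <- if (p$strand == "+") p$mature_start else p$mature_end
    same <- as.character(GenomeInfoDb::seqnames(al)) == p$scaffold &
      as.character(BiocGenerics::strand(al)) == p$strand
    ends5 <- if (p$strand == "+") GenomicRanges::start(al)[same] else
      GenomicRanges::end(al)[same]
    near <- abs(ends5 - m5) <= 2
    if (any(near)) {
      star5 <- if (p$strand == "+") p$star_start else p$star_end
      expect_true(all(ends5[near] %in% c(m5, star5)))
    }
  }
})

test_that("reference catalogs honour sharing probabilities", {
  planted <- data.frame(
    name = paste0("m", 1:30),
    mature_seq = vapply(1:30, function(i)
      paste0("T", randomSeq(21)), character(1)))
  cfg <- simConfig(seed = 12L)
  cats <- makeReferenceCatalogs(planted, cfg,
                                speciesPanel = data.frame(
                                  species = c("all", "none"),
                                  prob = c(1, 0)),
                                nPrivate = 5L)
  expect_equal(sum(cats$truth$shared[cats$truth$species == "all"]), 30L)
  expect_equal(sum(cats$truth$shared[cats$truth$species == "none"]), 0L)
  expect_length(cats$catalogs$all, 35L)  # 30 shared + 5 private
  expect_length(cats$catalogs$none, 5L)
  kn <- callKnownNovel(stats::setNames(planted$mature_seq, planted$name),
                       cats$catalogs$all)
  expect_length(kn$known, 30L)
  kn0 <- callKnownNovel(stats::setNames(planted$mature_seq, planted$name),
                        cats$catalogs$none)
  expect_length(kn0$known, 0L)
})

test_that("miRNA-derived read lengths peak at the planted mature length", {
  run <- smallRun()
  prof <- as.matrix(run$report$profile)
  lens <- as.integer(rownames(prof))
  expect_equal(lens[which.max(rowSums(prof))], 22L)
  expect_equal(colnames(prof)[which.max(prof["22", ])], "T")
})
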