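revc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("3'UTR extraction is strand-aware and clipped at scaffold edges", {
  g <- Biostrings::DNAStringSet(c(s1 = randomSeq(3000)))
  ann <- GenomicRanges::GRanges(
    "s1", IRanges::IRanges(c(101, 1500, 2500), c(700, 2100, 2800)),
    strand = c("+", "-", "+"),
    ftype = factor(rep("gene", 3),
                   levels = c("gene", "exon", "ncRNA", "repeat",
                              "pseudogene")),
    gene_id = c("gp", "gm", "edge"))
  utrs <- extract3UTRs(ann, g, flank = 1000L)
  expect_equal(names(utrs), c("gp", "gm", "edge"))
  expect_true(all(Biostrings::width(utrs) <= 1000L))
  # plus strand: the kilobase right after the gene end
  expect_equal(as.character(utrs[["gp"]]),
               as.character(Biostrings::subseq(g[[1]], 701, 1700)))
  # minus strand: reverse complement of the kilobase before the gene start
  expect_equal(as.character(utrs[["gm"]]),
               revc(as.character(Biostrings::subseq(g[[1]], 500, 1499))))
  # a gene 200 nt from the scaffold end yields a 200 nt record
  expect_equal(Biostrings::width(utrs)[3], 200L)

  bad <- ann
  GenomeInfoDb::seqlevels(bad) <- c("s1", "sX")
  bad2 <- c(bad, GenomicRanges::GRanges(
    "sX", IRanges::IRanges(1, 50), strand = "+",
    ftype = factor("gene", levels = levels(ann$ftype)), gene_id = "lost"))
  expect_error(extract3UTRs(bad2, g), "lost")
})

test_that("seed sites are found, classified, and match a naive scan", {
  set.seed(60)
  mir <- "TGAGGTAGTAGGTTGTATAGTT"
  # construct an 8mer site: revcomp of nt 2-8 plus an A opposite nt 1
  site8 <- paste0(revc(substr(mir, 2, 8)), "A")
  utr <- paste0(randomSeq(40), site8, randomSeq(40))
  s <- predictSeedSites(mir, utr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$site_type, "8mer")
  expect_true(s$p1_hit)
  expect_equal(s$seed_start, 42L)  # seed core starts after the m8 base

  # 6mer-only sites are reported but not positive
  utr6 <- paste0(strrep("A", 30), revc(substr(mir, 2, 7)), strrep("C", 30))
  s6 <- predictSeedSites(mir, utr6)
  expect_equal(s6$site_type, "6mer")
  expect_false(s6$p1_hit)

  # enumeration equals the brute-force offset scan on random UTRs
  set.seed(61)
  for (i in 1:20) {
    u <- randomSeq(300)
    expect_equal(predictSeedSites(mir, u)$seed_start, bruteSeedScan(mir, u))
  }
})

test_that("duplex scoring follows the stated weights and seed constraint", {
  # perfect all-GC 22-mer duplex scores 22 * 3 = 66 at the aligned register
  # (the GC repeat spawns shifted sites too, hence the max over sites)
  mir <- strrep("GC", 11)
  utr <- paste0(strrep("A", 20), revc(mir), strrep("A", 20))
  s <- predictSeedSites(mir, utr)
  d <- lapply(seq_len(nrow(s)), function(k) predictDuplex(mir, utr, s[k, ]))
  expect_equal(max(vapply(d, `[[`, numeric(1), "p2_score")), 66)
  expect_true(any(vapply(d, `[[`, logical(1), "p2_hit")))

  # a perfect complement of a generic miRNA scores every position
  mir2 <- "TGAGGTAGTAGGTTGTATAGTT"
  utr2 <- paste0(strrep("A", 20), revc(mir2), strrep("A", 20))
  t0 <- 36L  # register with miRNA nt m opposite UTR position t0 + 7 - m
  d2 <- predictDuplex(mir2, utr2, data.frame(seed_start = t0))
  gc <- sum(strsplit(mir2, "")[[1]] %in% c("G", "C"))
  expect_equal(d2$p2_score, 3 * gc + 2 * (22 - gc))
  expect_true(d2$p2_hit)

  # strong 3' pairing cannot rescue two seed mismatches
  utr3 <- utr2
  for (m in c(4L, 6L)) {
    u <- t0 + 7L - m
    cur <- substr(utr3, u, u)
    substr(utr3, u, u) <- if (cur == "A") "C" else "A"
  }
  d3 <- predictDuplex(mir2, utr3, data.frame(seed_start = t0))
  expect_gte(d3$p2_score, 25)
  expect_false(d3$p2_hit)
})

test_that("accessibility penalises structured sites", {
  # an all-G miRNA seeds into an all-C UTR: nothing in the window can pair,
  # so no structure is lost by opening the site
  mir <- paste0("T", strrep("G", 21))
  open <- strrep("C", 120)
  so <- predictSeedSites(mir, open)[20, ]
  d <- predictDuplex(mir, open, so)
  po <- predictAccessibility(open, so, d$p2_score)
  expect_equal(po$dg_open, 0)
  expect_equal(po$p3_ddg, -d$p2_score)
  expect_true(po$p3_hit)

  # the same site inside a saturated G/C stem is buried: every C in the
  # folding window is needed as a pairing partner, so opening the site
  # costs pairs (A flanks keep the whole stem inside one window)
  closed <- paste0(strrep("A", 20), strrep("G", 20), strrep("C", 20),
                   strrep("A", 20))
  sites <- predictSeedSites(mir, closed)
  sc <- sites[which.min(abs(sites$seed_start - 48L)), ]
  dc <- predictDuplex(mir, closed, sc)
  pc <- predictAccessibility(closed, sc, dc$p2_score)
  expect_gt(pc$dg_open, 0)
  expect_gt(pc$p3_ddg + dc$p2_score, po$p3_ddg + d$p2_score)
})

test_that("consensus is the strict intersection of the three predictors", {
  sites <- data.frame(
    mirna = "m", gene_id = c("g1", "g2", "g3", "g4"),
    seed_start = 1L, utr_pos = 5L, site_type = "8mer",
    p1_hit = c(TRUE, TRUE, FALSE, TRUE),
    p2_score = 30, p2_hit = c(TRUE, TRUE, TRUE, FALSE),
    p3_ddg = -20, p3_hit = c(TRUE, FALSE, TRUE, TRUE))
  res <- consensusTargets(sites)
  expect_equal(res$sites$consensus, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$target_genes, "g1")
  # consensus set is a subset of each predictor's positive set
  cs <- res$sites[res$sites$consensus, ]
  expect_true(all(cs$p1_hit) && all(cs$p2_hit) && all(cs$p3_hit))

  empty <- consensusTargets(sites[0, ])
  expect_length(empty$target_genes, 0L)
})

test_that("planted consensus sites are recalled, random UTRs stay quiet", {
  set.seed(62)
  mirs <- c(mA = paste0("T", randomSeq(21)), mB = paste0("T", randomSeq(21)))
  tu <- simulateTargetUtrs(mirs, nTargets = 12L, nDecoys = 25L, seed = 8L)
  res <- predictTargets(mirs, tu$utrs)
  planted <- tu$truth[tu$truth$is_target, ]
  hit <- vapply(seq_len(nrow(planted)), function(i)
    any(res$sites$consensus &
          res$sites$gene_id == planted$gene_id[i] &
          res$sites$mirna == planted$mirna[i]), logical(1))
  expect_gte(mean(hit), 0.9)
  fp <- mean(tu$truth$gene_id[!tu$truth$is_target] %in% res$target_genes)
  expect_lte(fp, 0.1)
})

test_that("GO summaries count terms and bucket unannotated genes", {
  g2g <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    go_term = c("metabolic process", "cell",
                                "metabolic process", "transport"))
  tab <- summarizeGo(c("g1", "g2", "g4"), g2g)
  expect_equal(tab$count[tab$go_term == "metabolic process"], 2L)
  expect_equal(tab$count[tab$go_term == "unannotated"], 1L)
  expect_equal(sum(tab$count), 4L)  # 3 annotations among targets + 1 bucket
  expect_equal(nrow(summarizeGo(character(), g2g)), 0L)
})
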