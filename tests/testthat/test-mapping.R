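test_that("k-mer index reports plus-strand occurrences per scaffold", {
  idx <- kmerIndex(c(s1 = "ACGTACGT"), k = 4L)
  hit <- get("ACGT", envir = idx$positions)
  expect_equal(hit$start, c(1L, 5L))
  expect_equal(hit$scaffold, c("s1", "s1"))
  expect_error(kmerIndex(c(s1 = "ACGTACGT"), k = 3L), ">= 4")
  # rebuilt index is identical
  idx2 <- kmerIndex(c(s1 = "ACGTACGT"), k = 4L)
  expect_equal(as.list(idx$positions), as.list(idx2$positions))
})

test_that("exact and reverse-complement reads map to the right locus", {
  set.seed(21)
  g <- c(chr = randomSeq(500))
  sub <- unname(substr(g, 101, 122))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  al <- mapReads(c(fwd = sub, rev = rc), g)
  expect_equal(length(al), 2L)
  expect_equal(unique(GenomicRanges::start(al)), 101L)
  expect_equal(unique(GenomicRanges::end(al)), 122L)
  expect_equal(as.character(BiocGenerics::strand(al))[al$read_id == "fwd"],
               "+")
  expect_equal(as.character(BiocGenerics::strand(al))[al$read_id == "rev"],
               "-")
  expect_equal(al$n_mismatch, c(0L, 0L))
})

test_that("every reported alignment reproduces the read within one mismatch", {
  set.seed(22)
  g <- Biostrings::DNAStringSet(c(s1 = randomSeq(3000), s2 = randomSeq(2000)))
  reads <- vapply(1:80, function(i) {
    sc <- sample(1:2, 1)
    len <- sample(15:30, 1)
    p <- sample(Biostrings::width(g)[sc] - len, 1)
    s <- as.character(Biostrings::subseq(g[[sc]], p, p + len - 1L))
    if (runif(1) < 0.5)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    if (runif(1) < 0.5) {  # inject one mismatch
      at <- sample(len, 1)
      substr(s, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, at, at)), 1)
    }
    s
  }, character(1))
  names(reads) <- paste0("r", seq_along(reads))
  al <- mapReads(reads, g)
  expect_gt(length(al), 0L)
  for (i in seq_along(al)) {
    slice <- Biostrings::subseq(
      g[[as.character(GenomeInfoDb::seqnames(al))[i]]],
      GenomicRanges::start(al)[i], GenomicRanges::end(al)[i])
    ref <- if (as.character(BiocGenerics::strand(al))[i] == "-")
      as.character(Biostrings::reverseComplement(slice))
    else as.character(slice)
    mm <- sum(strsplit(ref, "")[[1]] != strsplit(al$read_seq[i], "")[[1]])
    expect_lte(mm, 1L)
    expect_equal(mm, al$n_mismatch[i])
  }
})

test_that("mapping equals the naive all-positions oracle (incl. short reads)", {
  set.seed(23)
  g <- Biostrings::DNAStringSet(c(s1 = randomSeq(2000)))
  for (i in 1:60) {
    len <- sample(15:32, 1)
    p <- sample(2000 - len, 1)
    s <- as.character(Biostrings::subseq(g[[1]], p, p + len - 1L))
    if (runif(1) < 0.5)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    if (runif(1) < 0.5) {
      at <- sample(len, 1)
      substr(s, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, at, at)), 1)
    }
    oracle <- bruteMapOracle(s, g)
    al <- mapReads(stats::setNames(s, "q"), g)
    got <- data.frame(scaffold = as.character(GenomeInfoDb::seqnames(al)),
                      start = GenomicRanges::start(al),
                      end = GenomicRanges::end(al),
                      strand = as.character(BiocGenerics::strand(al)),
                      mm = al$n_mismatch)
    if (nrow(oracle) > 5L) {  # multi-mapper rule
      expect_equal(nrow(got), 0L)
      expect_equal(unname(attr(al, "status")["q"]), 2L)
    } else {
      o <- oracle[order(oracle$start, oracle$strand), ]
      gdf <- got[order(got$start, got$strand), ]
      rownames(o) <- rownames(gdf) <- NULL
      expect_equal(gdf, o)
    }
  }
})

test_that("mapping results are invariant to read order", {
  set.seed(24)
  g <- c(s1 = randomSeq(2000))
  reads <- vapply(1:20, function(i) {
    p <- sample(1970, 1)
    substr(g, p, p + sample(18:28, 1))
  }, character(1))
  names(reads) <- paste0("r", seq_along(reads))
  a1 <- mapReads(reads, g)
  perm <- sample(length(reads))
  a2 <- mapReads(reads[perm], g)
  k <- function(a) {
    d <- data.frame(id = a$read_id, s = GenomicRanges::start(a),
                    e = GenomicRanges::end(a),
                    st = as.character(BiocGenerics::strand(a)))
    d[order(d$id, d$s, d$st), ]
  }
  d1 <- k(a1); d2 <- k(a2)
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d1, d2)
})

test_that("multi-mappers beyond max_hits are discarded and flagged", {
  unit <- randomSeq(40)
  g <- c(s1 = strrep(unit, 8))  # a read matches 8 loci
  read <- substr(unit, 5, 28)
  al <- mapReads(stats::setNames(read, "m"), g)
  expect_equal(length(al), 0L)
  expect_equal(unname(attr(al, "status")["m"]), 2L)
  al2 <- mapReads(stats::setNames(read, "m"), g, maxHits = 10L)
  expect_equal(length(al2), 8L)
})

test_that("size profile counts each read once with its 5' base", {
  g <- c(s1 = paste0("TTT", randomSeq(60), "CCC"))
  r22 <- substr(g, 1, 22)   # starts with T
  al <- mapReads(c(a = r22, b = r22, c = r22), g)
  prof <- profileMapped(al)
  expect_equal(prof["22", "T"], 3L)
  expect_equal(sum(prof), 3L)
  expect_equal(sum(profileMapped(al[0])), 0L)
  expect_equal(dim(prof), c(21L, 4L))
})
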