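test_that("read stacks aggregate identical and separated loci correctly", {
  g <- c(s1 = randomSeq(1000))
  sub <- unname(substr(g, 201, 222))
  al <- mapReads(stats::setNames(rep(sub, 10), paste0("r", 1:10)), g)
  st <- callReadStacks(al, minReads = 5L)
  expect_length(st, 1L)
  expect_equal(st$n_reads, 10L)
  expect_length(st$five_prime[[1]], 1L)
  expect_equal(st$modal_seq, sub)
  expect_equal(st$mature_start, 201L)

  far <- unname(substr(g, 501, 522))
  al2 <- mapReads(stats::setNames(c(rep(sub, 5), rep(far, 5)),
                                  paste0("r", 1:10)), g)
  st2 <- callReadStacks(al2, minReads = 5L, mergeGap = 0L)
  expect_length(st2, 2L)

  # below min_reads no stack is called
  st3 <- callReadStacks(al[1:4], minReads = 5L)
  expect_length(st3, 0L)
})

test_that("stack spans equal a brute-force interval union", {
  set.seed(31)
  g <- c(s1 = randomSeq(1000))
  for (rep in 1:10) {
    starts <- sort(sample(900, 40, replace = TRUE))
    lens <- sample(18:25, 40, replace = TRUE)
    reads <- substr(rep(g, 40), starts, pmin(starts + lens - 1, 1000))
    names(reads) <- paste0("r", 1:40)
    al <- mapReads(reads, g, maxHits = 40L)
    st <- callReadStacks(al, minReads = 1L)
    # oracle: union of intervals via coverage
    cov <- rep(0L, 1000)
    for (i in seq_along(starts))
      cov[starts[i]:min(starts[i] + lens[i] - 1, 1000)] <- 1L
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    expect_equal(GenomicRanges::start(st), begs[r$values == 1L])
    expect_equal(GenomicRanges::end(st), ends[r$values == 1L])
  }
})

test_that("modal sequence ties break to the lexicographically smallest", {
  g <- c(s1 = paste0(randomSeq(100), "ACGTACGTACGTACGTACGTAA",
                     randomSeq(100)))
  a <- unname(substr(g, 101, 122))
  b <- unname(substr(g, 102, 123))  # same stack, other sequence, same count
  al <- mapReads(stats::setNames(c(rep(a, 3), rep(b, 3)),
                                 paste0("r", 1:6)), g)
  st <- callReadStacks(al, minReads = 5L)
  expect_equal(st$modal_seq, min(a, b))
})

test_that("the three-of-six verdict is monotone with inclusive boundary", {
  expect_equal(curationVerdict(c(rep(TRUE, 3), rep(FALSE, 3))), "kept")
  expect_equal(curationVerdict(c(rep(TRUE, 2), rep(FALSE, 4))), "discarded")
  expect_equal(curationVerdict(rep(NA, 6)), "discarded")
  # toggling any FALSE to TRUE never flips kept -> discarded
  for (i in 0:63) {
    flags <- as.logical(intToBits(i)[1:6])
    v <- curationVerdict(flags)
    for (j in which(!flags)) {
      f2 <- flags
      f2[j] <- TRUE
      if (v == "kept") expect_equal(curationVerdict(f2), "kept")
    }
  }
})

test_that("criteria evaluate with inclusive thresholds on boundary cases", {
  ann <- emptyAnnotation()
  al <- emptyAlignments()
  # c4 at exactly 70%: 7 of 10 reads share the modal 5' end
  cand <- makeCandidate(matureLen = 22L, loopLen = 16L)  # 60 nt precursor
  stack <- makeStack("s1", 1001L, 1026L, "+", 10L,
                     c("1001" = 7L, "1003" = 3L),
                     stats::setNames(c(rep(0L, 7), 10L, rep(0L, 13)), 15:35),
                     matureStart = 1001L, matureEnd = 1022L)
  ev <- evaluateCriteria(cand, stack, al, ann)
  expect_true(criteria(ev)[["c4"]])
  expect_true(criteria(ev)[["c2"]])  # length 60, inclusive
  expect_true(criteria(ev)[["c5"]])  # histogram peak at 22
  expect_true(criteria(ev)[["c1"]])
  expect_false(criteria(ev)[["c3"]])  # no star-supporting reads provided
  expect_true(criteria(ev)[["c6"]])  # no ncRNA/repeat annotation
  expect_equal(verdict(ev), "kept")

  # just under 70% fails c4
  stack69 <- makeStack("s1", 1001L, 1026L, "+", 13L,
                       c("1001" = 9L, "1003" = 4L),
                       stats::setNames(c(rep(0L, 7), 13L, rep(0L, 13)),
                                       15:35))
  expect_false(criteria(evaluateCriteria(cand, stack69, al, ann))[["c4"]])

  # precursor lengths 60 and 80 are in, 58 and 82 are out
  for (spec in list(c(22L, 16L, TRUE), c(22L, 36L, TRUE),
                    c(21L, 16L, FALSE), c(23L, 36L, FALSE))) {
    candL <- makeCandidate(matureLen = spec[[1]], loopLen = spec[[2]])
    evL <- evaluateCriteria(candL, stack, al, ann)
    expect_equal(unname(criteria(evL)[["c2"]]), as.logical(spec[[3]]),
                 info = sprintf("precursor %d nt", nchar(evL@seq)))
  }
})

test_that("star-supporting reads switch c3 on", {
  cand <- makeCandidate(matureLen = 22L, loopLen = 16L, seed = 6L)
  # star is predicted from the fold; place one read 5' end at the star 5'
  star <- mirforge:::.predictStar(cand@structure, cand@matureStart,
                                  cand@matureLength)
  expect_true(star$ok)
  star5g <- cand@start + star$starStart - 1L
  starRead <- GenomicRanges::GRanges(
    "s1", IRanges::IRanges(star5g, star5g + 21L), strand = "+",
    read_id = "star1", read_seq = randomSeq(22), n_mismatch = 0L)
  stack <- makeStack("s1", cand@start, cand@end, "+", 10L,
                     stats::setNames(10L, cand@start),
                     stats::setNames(c(rep(0L, 7), 10L, rep(0L, 13)), 15:35))
  ev <- evaluateCriteria(cand, stack, starRead, emptyAnnotation())
  expect_true(criteria(ev)[["c3"]])

  # a read 2 nt off the predicted star 5' end does not count
  offRead <- GenomicRanges::GRanges(
    "s1", IRanges::IRanges(star5g + 2L, star5g + 23L), strand = "+",
    read_id = "off", read_seq = randomSeq(22), n_mismatch = 0L)
  ev2 <- evaluateCriteria(cand, stack, offRead, emptyAnnotation())
  expect_false(criteria(ev2)[["c3"]])
})

test_that("overlap with ncRNA or repeat annotation fails c6", {
  cand <- makeCandidate()
  stack <- makeStack("s1", cand@start, cand@end, "+", 10L,
                     stats::setNames(10L, cand@start),
                     stats::setNames(c(rep(0L, 7), 10L, rep(0L, 13)), 15:35))
  ann <- GenomicRanges::GRanges(
    "s1", IRanges::IRanges(cand@end, cand@end + 100L),  # 1 nt overlap
    ftype = factor("repeat", levels = levels(emptyAnnotation()$ftype)),
    gene_id = NA_character_)
  ev <- evaluateCriteria(cand, stack, emptyAlignments(), ann)
  expect_false(criteria(ev)[["c6"]])
  ann2 <- GenomicRanges::GRanges(
    "s1", IRanges::IRanges(cand@end + 1L, cand@end + 100L),  # adjacent only
    ftype = factor("ncRNA", levels = levels(emptyAnnotation()$ftype)),
    gene_id = NA_character_)
  ev2 <- evaluateCriteria(cand, stack, emptyAlignments(), ann2)
  expect_true(criteria(ev2)[["c6"]])
})

test_that("excision picks a window containing mature and star, clipped at edges", {
  run <- smallRun()
  pl <- run$truth$planted
  mir <- run$report$mirnas
  # recovered planted loci get a candidate precursor containing both the
  # mature and the star (folding is heuristic, so near-universal rather
  # than universal)
  contained <- vapply(seq_len(nrow(pl)), function(i) {
    hit <- mir[mir$scaffold == pl$scaffold[i] &
                 mir$strand == pl$strand[i] &
                 mir$prec_start <= pl$mature_start[i] &
                 mir$prec_end >= pl$mature_end[i], ]
    if (!nrow(hit)) return(NA)
    any(hit$prec_start <= min(pl$mature_start[i], pl$star_start[i]) + 2 &
          hit$prec_end >= max(pl$mature_end[i], pl$star_end[i]) - 2)
  }, logical(1))
  expect_gte(mean(contained, na.rm = TRUE), 0.9)

  # a stack at the scaffold edge must not produce out-of-bounds windows
  g <- Biostrings::DNAStringSet(c(s1 = randomSeq(200)))
  stack <- makeStack("s1", 3L, 24L, "+", 6L, c("3" = 6L),
                     stats::setNames(c(rep(0L, 7), 6L, rep(0L, 13)), 15:35),
                     matureStart = 3L, matureEnd = 24L)
  cands <- exciseCandidates(stack, g)
  expect_gte(cands[[1]]@start, 1L)
  expect_lte(cands[[1]]@end, 200L)
  expect_equal(nchar(cands[[1]]@seq),
               cands[[1]]@end - cands[[1]]@start + 1L)
})

test_that("decoy-style stacks fail at least four criteria", {
  run <- smallRun()
  tab <- run$report$mirnas
  dec <- run$truth$decoys
  # no decoy gave rise to a kept miRNA from its own stack
  for (i in seq_len(nrow(dec))) {
    same <- tab[tab$scaffold == dec$scaffold[i] &
                  tab$strand == dec$strand[i], ]
    ov <- same$prec_start <= dec$prec_end[i] &
      same$prec_end >= dec$prec_start[i]
    expect_false(any(ov), info = dec$name[i])
  }
})

test_that("quantification assigns reads, normalises shares and rpm", {
  g <- c(s1 = randomSeq(600))
  m1 <- substr(g, 101, 122)
  m2 <- substr(g, 301, 322)
  al <- mapReads(stats::setNames(c(rep(m1, 30), rep(m2, 10)),
                                 paste0("r", 1:40)), g)
  mir <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(81, 281),
                                                       c(162, 362)),
                                strand = "+",
                                name = c("mir-1", "mir-2"),
                                mature_start = c(101L, 301L),
                                mature_end = c(122L, 322L))
  q <- quantifyMirnas(mir, al)
  expect_equal(q$read_count, c(30L, 10L))
  expect_equal(q$share, c(75, 25))
  expect_equal(sum(q$share), 100, tolerance = 1e-9)
  expect_equal(q$rpm, c(30, 10) * 1e6 / 40)

  # single miRNA holds 100% of assigned reads
  q1 <- quantifyMirnas(mir[1], al)
  expect_equal(q1$share, 100)
})

test_that("reads overlapping two matures go to the larger overlap", {
  g <- c(s1 = randomSeq(300))
  # two adjacent matures; read overlaps first fully, second partially
  read <- substr(g, 101, 122)
  al <- mapReads(stats::setNames(rep(read, 6), paste0("r", 1:6)), g)
  # both matures clear the (length - 2) overlap bar: 22 vs 20 nt
  mir <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(95, 99), c(130, 150)),
                                strand = "+", name = c("a", "b"),
                                mature_start = c(101L, 103L),
                                mature_end = c(122L, 124L))
  q <- quantifyMirnas(mir, al)
  expect_equal(q$read_count, c(6L, 0L))
})
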