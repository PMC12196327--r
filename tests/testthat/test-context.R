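mkMirs <- function(starts, ends, counts, scaffold = "s1",
                   names = NULL) {
  if (is.null(names)) names <- paste0("m", seq_along(starts))
  GenomicRanges::GRanges(scaffold, IRanges::IRanges(starts, ends),
                         strand = "+", name = names, read_count = counts)
}

test_that("overlap removal keeps the strongest of each overlapping set", {
  two <- mkMirs(c(100, 300), c(170, 370), c(10, 20))
  res <- dropOverlapping(two)
  expect_length(res$kept, 2L)
  expect_length(res$dropped, 0L)

  ov <- mkMirs(c(100, 160), c(170, 230), c(100, 7))
  res <- dropOverlapping(ov)
  expect_equal(res$kept$name, "m1")
  expect_equal(res$dropped$name, "m2")

  # a chain A-B, B-C with A and C disjoint resolves by descending count
  chain <- mkMirs(c(100, 150, 200), c(160, 210, 260), c(5, 50, 8))
  res <- dropOverlapping(chain)
  expect_equal(res$kept$name, "m2")  # top count kills both neighbours
  chain2 <- mkMirs(c(100, 150, 200), c(160, 210, 260), c(50, 5, 40))
  res2 <- dropOverlapping(chain2)
  expect_setequal(res2$kept$name, c("m1", "m3"))
})

test_that("overlap removal matches a per-component greedy oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 12L
    starts <- sample(1000, n)
    gr <- mkMirs(starts, starts + sample(60:90, n, replace = TRUE),
                 sample(1000, n))
    res <- dropOverlapping(gr)
    # oracle: repeatedly keep the highest-count miRNA (tie: smallest
    # start), discard everything overlapping it
    df <- data.frame(name = gr$name, start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr), count = gr$read_count)
    kept <- character()
    while (nrow(df)) {
      o <- order(-df$count, df$start)
      top <- df[o[1], ]
      kept <- c(kept, top$name)
      df <- df[!(df$start <= top$end & df$end >= top$start), ]
    }
    expect_setequal(res$kept$name, kept)
    # never removes a miRNA that overlaps nothing
    lone <- vapply(seq_along(gr), function(i)
      sum(IRanges::overlapsAny(gr[i], gr[-i])) == 0, logical(1))
    expect_true(all(gr$name[lone] %in% res$kept$name))
  }
})

test_that("context classification uses most-specific-first precedence", {
  ann <- GenomicRanges::GRanges(
    "s1",
    IRanges::IRanges(c(1000, 1000, 2000, 5000), c(3000, 1400, 2400, 5400)),
    strand = "+",
    ftype = factor(c("gene", "exon", "exon", "pseudogene"),
                   levels = c("gene", "exon", "ncRNA", "repeat",
                              "pseudogene")),
    gene_id = c("g1", "g1", "g1", NA))
  mir <- mkMirs(c(1600, 1380, 5100, 8000), c(1680, 1450, 5180, 8080),
                rep(1, 4))
  ctx <- classifyContext(mir, ann)
  expect_equal(as.character(ctx$context),
               c("intronic",    # fully inside the intron
                 "exonic",      # spans the exon/intron junction
                 "pseudogene",  # pseudogene wins over everything
                 "intergenic"))
  # fractions over all classified miRNAs always total 100%
  expect_equal(sum(table(ctx$context) / nrow(ctx)) * 100, 100)
})

test_that("clusters chain at gaps up to 5000 nt, exclusive above", {
  # six precursors with ~1 kb gaps form one cluster of six
  starts <- cumsum(c(1000, rep(1070, 5)))
  mir <- mkMirs(starts, starts + 69, rep(1, 6))
  cl <- findClusters(mir)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 6L)
  expect_equal(cl$members, paste(paste0("m", 1:6), collapse = ","))

  # boundary: gap of exactly 5000 joins, 5001 does not
  pair <- function(gap) mkMirs(c(1000, 1000 + 70 + gap),
                               c(1069, 1069 + 70 + gap), c(1, 1))
  expect_equal(nrow(findClusters(pair(5000L))), 1L)
  expect_equal(nrow(findClusters(pair(5001L))), 0L)
})

test_that("cluster membership matches the quadratic oracle and input order", {
  set.seed(43)
  for (rep in 1:15) {
    n <- 15L
    sc <- sample(c("s1", "s2"), n, replace = TRUE)
    starts <- sample(30000, n)
    gr <- GenomicRanges::GRanges(sc, IRanges::IRanges(starts, starts + 70),
                                 strand = "+",
                                 name = paste0("m", seq_len(n)),
                                 read_count = seq_len(n))
    cl <- findClusters(gr, maxGap = 3000L)
    got <- sort(vapply(strsplit(cl$members, ","), function(m)
      paste(sort(m), collapse = ","), character(1)))
    oracle <- bruteClusterOracle(
      data.frame(name = gr$name, scaffold = sc, start = starts,
                 end = starts + 70), maxGap = 3000L)
    expect_equal(got, oracle)
    # invariant to input order
    perm <- sample(n)
    cl2 <- findClusters(gr[perm], maxGap = 3000L)
    got2 <- sort(vapply(strsplit(cl2$members, ","), function(m)
      paste(sort(m), collapse = ","), character(1)))
    expect_equal(got2, oracle)
  }
})

test_that("per-scaffold counts are exact, sorted, and conserve totals", {
  mir <- GenomicRanges::GRanges(
    c("s1", "s1", "s1", "s2"),
    IRanges::IRanges(c(100, 300, 500, 100), width = 70),
    name = paste0("m", 1:4), read_count = 1:4)
  tab <- perScaffoldCounts(mir)
  expect_equal(tab$scaffold, c("s1", "s2"))
  expect_equal(tab$n_mirnas, c(3L, 1L))
  expect_equal(sum(tab$n_mirnas), length(mir))
  expect_equal(nrow(perScaffoldCounts(mir[0])), 0L)
})
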