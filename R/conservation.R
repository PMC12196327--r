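#' Match a mature miRNA against a reference catalog
#'
#' Deterministic ungapped shift-and-count matcher: the query is slid over
#' each catalog entry at offsets `-maxShift..maxShift` and the
#' minimum-mismatch overlap covering at least `length(query) - maxShift` nt
#' is taken. A query matches if the best alignment has at most `maxMm`
#' mismatches, or if the seed (query nt 2-8) is identical and the alignment
#' has at most 4 mismatches — mirroring "similar in full or within the seed
#' region" conservation calls. Ties are broken by fewest mismatches, then
#' smallest absolute offset, then first catalog entry. Orientation is not
#' searched: catalogs are assumed to store mature-sense 5'->3' sequences.
#'
#' @param query a DNA/RNA string, 15-35 nt.
#' @param catalog a named [Biostrings::DNAStringSet] or named character
#'   vector (T/U equivalent).
#' @param maxMm mismatch ceiling for a plain match.
#' @param maxShift largest |offset| tried, and the allowed overlap
#'   shortfall.
#' @return a one-row data.frame: `subject` (catalog name or NA),
#'   `n_mismatch`, `offset`, `seed_identical`, `matched`.
#' @export
matchMature <- function(query, catalog, maxMm = 2L, maxShift = 2L) {
  query <- toupper(chartr("U", "T", as.character(query)))
  L <- nchar(query)
  if (L < 15L || L > 35L) .stopf("query must be 15-35 nt, got %d", L)
  subj <- toupper(chartr("U", "T", .asDNAChar(catalog)))
  qv <- strsplit(query, "")[[1]]
  best <- list(subject = NA_character_, mm = Inf, offset = NA_integer_,
               seed = FALSE)
  minCover <- L - maxShift
  for (ci in seq_along(subj)) {
    sv <- strsplit(subj[ci], "")[[1]]
    for (off in -maxShift:maxShift) {
      # query position i aligns subject position i + off
      i1 <- max(1L, 1L - off)
      i2 <- min(L, length(sv) - off)
      if (i2 - i1 + 1L < minCover) next
      qs <- qv[i1:i2]
      ss <- sv[(i1 + off):(i2 + off)]
      mm <- sum(qs != ss)
      seedIn <- 2:8 >= i1 & 2:8 <= i2
      seedId <- all(seedIn) && all(qv[2:8] == sv[2:8 + off])
      better <- mm < best$mm ||
        (mm == best$mm && !is.na(best$offset) &&
           abs(off) < abs(best$offset))
      if (is.infinite(best$mm) || better) {
        best <- list(subject = names(subj)[ci], mm = mm,
                     offset = off, seed = seedId)
      }
    }
  }
  matched <- is.finite(best$mm) &&
    (best$mm <= maxMm || (best$seed && best$mm <= 4L))
  data.frame(subject = if (matched) best$subject else NA_character_,
             n_mismatch = if (is.finite(best$mm)) as.integer(best$mm)
                          else NA_integer_,
             offset = best$offset,
             seed_identical = isTRUE(best$seed),
             matched = matched)
}

#' Partition miRNAs into known and species-specific
#'
#' A miRNA is "known" iff [matchMature()] succeeds against any entry of the
#' combined catalog; otherwise it is called species-specific. The two sets
#' partition the input exactly.
#'
#' @param mirnas named character vector of mature sequences (names are
#'   miRNA ids), or a [GenomicRanges::GRanges] with `name` and
#'   `mature_seq` columns.
#' @param combinedCatalog a [Biostrings::DNAStringSet] or named character;
#'   union of all species catalogs.
#' @inheritParams matchMature
#' @return `list(known, specific)`: character vectors of miRNA names.
#' @export
callKnownNovel <- function(mirnas, combinedCatalog, maxMm = 2L,
                           maxShift = 2L) {
  seqs <- .mirnaSeqs(mirnas)
  if (!length(seqs)) return(list(known = character(), specific = character()))
  if (!length(combinedCatalog))
    return(list(known = character(), specific = names(seqs)))
  hit <- vapply(seqs, function(q)
    matchMature(q, combinedCatalog, maxMm, maxShift)$matched, logical(1))
  list(known = names(seqs)[hit], specific = names(seqs)[!hit])
}

# accept either a named character vector or a discovery GRanges
.mirnaSeqs <- function(mirnas) {
  if (methods::is(mirnas, "GRanges")) {
    stats::setNames(mirnas$mature_seq, mirnas$name)
  } else {
    x <- .asDNAChar(mirnas)
    if (is.null(names(x))) names(x) <- paste0("mir-", seq_along(x))
    x
  }
}

#' Cross-species sharing matrix
#'
#' Calls each miRNA against every species catalog and reports the
#' membership sets, UpSet-style intersection counts and per-species totals.
#' Every miRNA appears exactly once in the membership map; an empty set
#' means species-specific.
#'
#' @param mirnas as in [callKnownNovel()].
#' @param catalogsBySpecies named list of catalogs (one per species).
#' @inheritParams matchMature
#' @return a list: `membership` (named list: miRNA -> character vector of
#'   species), `perSpecies` (named integer totals), `intersections`
#'   (data.frame `combo`/`count`, combos sorted, `"none"` for
#'   species-specific miRNAs; counts sum to the miRNA total).
#' @export
sharingMatrix <- function(mirnas, catalogsBySpecies, maxMm = 2L,
                          maxShift = 2L) {
  seqs <- .mirnaSeqs(mirnas)
  if (!length(catalogsBySpecies)) .stopf("need at least one species catalog")
  hitMat <- vapply(names(catalogsBySpecies), function(sp) {
    vapply(seqs, function(q)
      matchMature(q, catalogsBySpecies[[sp]], maxMm, maxShift)$matched,
      logical(1))
  }, logical(length(seqs)))
  hitMat <- matrix(hitMat, nrow = length(seqs),
                   dimnames = list(names(seqs), names(catalogsBySpecies)))
  membership <- apply(hitMat, 1L, function(r) colnames(hitMat)[r],
                      simplify = FALSE)
  combo <- vapply(membership, function(m)
    if (length(m)) paste(sort(m), collapse = "+") else "none", character(1))
  tab <- sort(table(combo), decreasing = TRUE)
  list(membership = membership,
       perSpecies = colSums(hitMat),
       intersections = data.frame(combo = names(tab),
                                  count = as.integer(tab)))
}

#' Compare two miRNA prediction sets
#'
#' An entry of `setA` is shared iff it occurs as a substring (up to one
#' mismatch) of some `setB` entry — `setB` may hold precursors — or
#' [matchMature()] succeeds against `setB`. Returns the shared entries, the
#' entries exclusive to `setA`, and the `setB` entries never hit.
#'
#' @param setA,setB named [Biostrings::DNAStringSet] or named character
#'   vectors.
#' @inheritParams matchMature
#' @return `list(shared, only_a, only_b)`: character vectors of names;
#'   `length(shared) + length(only_a) == length(setA)`.
#' @export
comparePredictionSets <- function(setA, setB, maxMm = 2L, maxShift = 2L) {
  a <- toupper(chartr("U", "T", .asDNAChar(setA)))
  b <- toupper(chartr("U", "T", .asDNAChar(setB)))
  if (is.null(names(a))) names(a) <- paste0("a", seq_along(a))
  if (is.null(names(b))) names(b) <- paste0("b", seq_along(b))
  bSet <- Biostrings::DNAStringSet(b)
  hitB <- rep(FALSE, length(b))
  shared <- logical(length(a))
  for (i in seq_along(a)) {
    cnt <- Biostrings::vcountPattern(a[[i]], bSet, max.mismatch = 1,
                                     with.indels = FALSE)
    sub <- cnt > 0
    mm <- matchMature(a[[i]], b, maxMm, maxShift)
    shared[i] <- any(sub) || mm$matched
    hitB <- hitB | sub
    if (mm$matched) hitB[names(b) == mm$subject] <- TRUE
  }
  list(shared = names(a)[shared], only_a = names(a)[!shared],
       only_b = names(b)[!hitB])
}
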