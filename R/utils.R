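# Internal string/sequence helpers shared across modules.

# reverse complement of a plain character vector (DNA; T/U-insensitive input,
# DNA output)
.revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.complementBase <- function(b) chartr("ACGTU", "TGCAA", b)

# slice a scaffold and orient to transcript sense
.senseSeq <- function(genome, scaffold, start, end, strand) {
  s <- as.character(Biostrings::subseq(genome[[scaffold]], start, end))
  if (strand == "-") .revcomp(s) else s
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# stable seed derivation: distinct streams per stage, kept below 2^31
.subSeed <- function(seed, stage) {
  (as.integer(seed) + 7919L * as.integer(stage)) %% 2147483647L
}

.asDNAChar <- function(x) {
  if (methods::is(x, "XStringSet")) return(as.character(x))
  y <- as.character(x)
  names(y) <- names(x)
  y
}
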