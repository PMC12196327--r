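# The reference synthetic study (default SimConfig, seed 1) run once per
# session and shared by every test that needs the full pipeline.
defaultRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mirforge_default_run")
      cache <<- suppressWarnings(suppressMessages(
        simulateAndRun(simConfig(seed = 1L), dir = dir)))
    }
    cache
  }
})

# a small, fast study used where full scale is unnecessary
smallConfig <- function(seed = 5L) {
  simConfig(seed = seed, nScaffolds = 2L, scaffoldLen = 25000L,
            nTrueMirnas = 10L, nDecoys = 6L, nMirnaReads = 16000L,
            nBackgroundReads = 4000L, nClustered = 3L)
}

smallRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mirforge_small_run")
      cache <<- suppressWarnings(suppressMessages(
        simulateAndRun(smallConfig(), dir = dir)))
    }
    cache
  }
})
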