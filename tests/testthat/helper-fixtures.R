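# Shared, lazily built fixtures. The extractor and the end-to-end pipeline
# run are expensive, so each is built once per test session.

.fixtures <- new.env(parent = emptyenv())

# The ~1 GB extractor is cached only while a file opts in (acquire /
# release): holding it for the whole session would dominate the suite's
# memory peak, while rebuilding it for every block wastes minutes.
sharedExtractor <- function() {
  if (!is.null(.fixtures$extractor)) return(.fixtures$extractor)
  buildExtractor(extractorConfig(seed = 101L))
}

acquireExtractor <- function() {
  if (is.null(.fixtures$extractor))
    .fixtures$extractor <- buildExtractor(extractorConfig(seed = 101L))
  invisible(NULL)
}

releaseExtractor <- function() {
  .fixtures$extractor <- NULL
  gc(verbose = FALSE)
  invisible(NULL)
}

# One full pipeline run at the default study conditions (n = 60, size 256,
# contrast 0.25, seed 1); shared by the acceptance tests.
sharedPipelineReport <- function() {
  if (is.null(.fixtures$report)) {
    out <- file.path(tempdir(), "fundusHem-e2e")
    .fixtures$report <- runPipeline(defaultPipelineConfig(outDir = out,
                                                          seed = 1L))
    .fixtures$reportDir <- out
  }
  .fixtures$report
}

sharedPipelineDir <- function() {
  sharedPipelineReport()
  .fixtures$reportDir
}
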