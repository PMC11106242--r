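# Shared fixture bundle: generated once per test session into a tempdir.
fixtureEnv <- new.env(parent = emptyenv())

fixtureBundle <- function(seed = 1L) {
    key <- paste0("s", seed)
    if (!is.null(fixtureEnv[[key]])) return(fixtureEnv[[key]])
    dir <- file.path(tempdir(), paste0("m6adscan_fx_", seed))
    manifest <- makeFixtures(dir, seed = seed)
    bundle <- list(
        dir = dir,
        manifest = manifest,
        genome = readGenome(file.path(dir, "genome.fa")),
        transcripts = readTranscriptsBed12(file.path(dir, "tx.bed")),
        variants = readVariants(file.path(dir, "variants.vcf")),
        sites = readM6aSites(file.path(dir, "m6a.tsv"))
    )
    fixtureEnv[[key]] <- bundle
    bundle
}

pipelineResult <- function(engine = "builtin", seed = 1L, ...) {
    key <- paste0("run_", engine, "_", seed)
    if (!is.null(fixtureEnv[[key]])) return(fixtureEnv[[key]])
    fx <- fixtureBundle(seed)
    res <- suppressWarnings(runPipeline(fx$genome, fx$transcripts,
                                        fx$variants, fx$sites,
                                        runConfig(engine = engine, ...)))
    fixtureEnv[[key]] <- res
    res
}
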