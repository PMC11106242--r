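test_that("FASTA reading normalizes case, RNA alphabet and line wrapping", {
    p <- withr::local_tempfile(lines = c(">c1", "acgt"))
    g <- readGenome(p)
    expect_equal(as.character(g[["c1"]]), "ACGT")

    p2 <- withr::local_tempfile(lines = c(">c1", "ACG", "T", ">c2", "TTTT"))
    g2 <- readGenome(p2)
    expect_equal(length(g2), 2L)
    expect_equal(as.character(g2[["c1"]]), "ACGT")

    p3 <- withr::local_tempfile(lines = c(">c1", "ACGU"))
    expect_equal(as.character(readGenome(p3)[["c1"]]), "ACGT")
})

test_that("FASTA reading rejects duplicate names and empty files", {
    p <- withr::local_tempfile(lines = c(">a", "ACGT", ">a", "GGGG"))
    expect_error(readGenome(p), "duplicate")
    p2 <- withr::local_tempfile(lines = character())
    expect_error(readGenome(p2))
})

test_that("BED12 block offsets become absolute genomic intervals", {
    p <- withr::local_tempfile(lines = paste(
        "chr1", 100, 400, "TX1|G1", 0, "+", 120, 360, 0, 2,
        "50,60,", "0,100,", sep = "\t"))
    tx <- readTranscriptsBed12(p)[[1L]]
    # 0-based half-open (100,150)+(200,260) == 1-based inclusive 101-150, 201-260
    expect_equal(IRanges::start(tx@blocks), c(101L, 201L))
    expect_equal(IRanges::end(tx@blocks), c(150L, 260L))
    expect_equal(tx@geneSymbol, "G1")
    # sum of block sizes equals reconstructed exonic length
    expect_equal(sum(IRanges::width(tx@blocks)), 50L + 60L)
})

test_that("non-coding BED12 entries are rejected with reason, not an error", {
    p <- withr::local_tempfile(lines = paste(
        "chr1", 100, 200, "NC1", 0, "+", 150, 150, 0, 1, "100,", "0,",
        sep = "\t"))
    txs <- readTranscriptsBed12(p)
    expect_equal(length(txs), 0L)
    expect_equal(attr(txs, "rejected")$reason, "no CDS")
})

test_that("minus-strand BED12 blocks stay in ascending genomic order", {
    fx <- fixtureBundle()
    tx <- fx$transcripts[["SYNTSC2L.1"]]
    expect_equal(tx@strand, "-")
    expect_false(is.unsorted(IRanges::start(tx@blocks), strictly = TRUE))
})

test_that("VCF reading splits multi-allelics and rejects symbolic alleles", {
    p <- withr::local_tempfile(lines = c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=c1>",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              sep = "\t"),
        paste("c1", 101, "rs1", "C", "A", ".", ".", ".", sep = "\t"),
        paste("c1", 150, "rs2", "G", "A,T", ".", ".", ".", sep = "\t"),
        paste("c1", 180, "rs3", "T", "<DEL>", ".", ".", ".", sep = "\t")))
    v <- readVariants(p)
    expect_equal(nrow(v), 3L)
    expect_equal(v$pos[v$variantId == "rs1"], 101L)
    expect_equal(sort(v$alt[grepl("^rs2", v$variantId)]), c("A", "T"))
    expect_equal(attr(v, "rejected")$reason, "unsupported allele")
})

test_that("m6A sites load from TSV and from the VCF INFO dialect", {
    fx <- fixtureBundle()
    expect_true(all(c("siteId", "chrom", "pos", "strand", "transcriptId")
                    %in% names(fx$sites)))
    expect_true(all(fx$sites$strand %in% c("+", "-")))

    p <- withr::local_tempfile(lines = c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=c1>",
        '##INFO=<ID=M6A_POS,Number=1,Type=Integer,Description="m6A position">',
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              sep = "\t"),
        paste("c1", 101, "s1", "C", "A", ".", ".", "M6A_POS=140", sep = "\t")))
    s <- readM6aSites(p)
    expect_equal(s$pos, 140L)
    expect_equal(s$strand, "+")
})

test_that("variant-site join is a cartesian product within each transcript", {
    fx <- fixtureBundle()
    pairs <- joinVariantsToSites(fx$variants, fx$sites, fx$transcripts)
    # brute-force expected count from the planted design
    expect_equal(nrow(pairs), fx$manifest$summary$n_pairs)
    # one variant x three sites on the structure-switch transcript
    expect_equal(sum(pairs$transcriptId == "SYNEPRS1L.1"), 3L)
    # a transcript with no variants contributes no pairs
    expect_equal(sum(pairs$transcriptId == "SYNCENS.1"), 0L)
})

test_that("candidate table survives a write-read round trip", {
    res <- pipelineResult("builtin")
    p <- withr::local_tempfile()
    writeCandidateTable(res$records, p)
    back <- readCandidateTable(p)
    expect_equal(nrow(back), nrow(res$records))
    for (col in c("variant_id", "transitions", "m6a_site_pos",
                  "variant_class"))
        expect_equal(back[[col]], res$records[[col]])
    expect_equal(back$mfe_ref, res$records$mfe_ref)
    expect_equal(back$delta_mfe, res$records$delta_mfe)

    # empty record set -> header-only file with the full schema
    p2 <- withr::local_tempfile()
    writeCandidateTable(res$records[0, ], p2)
    expect_equal(length(readLines(p2)), 1L)
    expect_equal(ncol(readCandidateTable(p2)),
                 length(m6adscan:::CANDIDATE_COLUMNS))
})
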